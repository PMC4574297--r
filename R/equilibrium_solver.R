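#' Solver options
#'
#' Numerical controls for the equilibrium search. The solver works in
#' dimensionless variables internally (lengths in units of the tube radius
#' R, energies in units of the bending modulus kappa), which makes the
#' pressure-constriction relation depend only on the shape ratios L/R and
#' w/R, as the scale-free Helfrich energy dictates.
#'
#' @param n_nodes Meridian node count; odd and `>= 51` (default 201).
#' @param max_iter Iteration cap for one inner quasi-Newton solve.
#' @param grad_tol Relative stationarity tolerance: the projected energy
#'   gradient norm, normalized by the energy scale `kappa/R^2 * area`,
#'   below which an equilibrium counts as converged (default 1e-6).
#' @param balloon_cutoff Dimensionless `r_max/R` beyond which a relaxation
#'   is aborted as runaway ballooning (default 3).
#' @param continuation_step Initial pressure step of the continuation
#'   sweep, in units of the dimensionless pressure `Pi = P R^3 / (2 kappa)`
#'   (default 1).
#' @param seed Integer seed for any randomized restart (the default solver
#'   is fully deterministic and never draws random numbers).
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(n_nodes = 201L, max_iter = 2000L,
                           grad_tol = 1e-6, balloon_cutoff = 3,
                           continuation_step = 1, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 51L || n_nodes %% 2L == 0L)
    stop("`n_nodes` must be odd and at least 51")
  stopifnot(max_iter > 0, grad_tol > 0, balloon_cutoff > 1,
            continuation_step > 0)
  structure(list(n_nodes = n_nodes, max_iter = as.integer(max_iter),
                 grad_tol = grad_tol, balloon_cutoff = balloon_cutoff,
                 continuation_step = continuation_step,
                 seed = as.integer(seed)),
            class = "solver_options")
}

# --- internal: dimensionless core -----------------------------------------

# dimensionless problem data extracted from SI inputs; vfix is the
# enclosed-volume target in units of R^3 (-1 disables the constraint)
.dimless_problem <- function(params, geometry, load,
                             conserve_volume = FALSE) {
  R <- geometry$R
  L <- geometry$L / R
  list(L = L,
       wwin = load$strip_width / R,
       zc = load$strip_center / R,
       p = load$P * R^3 / params$kappa,
       sig = params$lateral_tension * R^2 / params$kappa,
       vfix = if (isTRUE(conserve_volume)) pi * L else -1)
}

# resample the tangent angle of a shape onto a uniform arc grid of n nodes
.psi_interior <- function(shape, n) {
  if (nrow(shape) == n) {
    ds <- diff(shape$s)
    if (max(ds) - min(ds) < 1e-9 * mean(ds)) return(shape$psi[2:(n - 1)])
  }
  u <- (shape$s - shape$s[1]) / (shape$s[nrow(shape)] - shape$s[1])
  f <- stats::splinefun(u, shape$psi, method = "natural")
  f(seq(0, 1, length.out = n))[2:(n - 1)]
}

# rebuild an SI axisym_shape from a relaxed interior tangent-angle vector
.shape_from_psi <- function(psi_int, dl, geometry) {
  psi <- c(0, psi_int, 0)
  ev <- helfrich_eval(psi, dl$L, dl$wwin, dl$zc, dl$p, dl$sig)
  if (!ev$feasible) stop("infeasible tangent-angle state")
  R <- geometry$R
  n <- length(psi)
  axisym_shape(s = seq(0, ev$S, length.out = n) * R, z = ev$z * R,
               r = ev$r * R, psi = psi, geometry = geometry,
               validate = FALSE)
}

# narrowest radius with subgrid parabolic refinement across the three
# nodes bracketing the nodal minimum
.refine_rmin <- function(s, r, z) {
  i <- which.min(r)
  n <- length(r)
  if (i == 1L || i == n) return(list(r_min = r[i], z = z[i]))
  h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
  d1 <- (r[i] - r[i - 1]) / h1
  d2 <- (r[i + 1] - r[i]) / h2
  a <- (d2 - d1) / (h1 + h2)            # half the second derivative
  if (a <= 0) return(list(r_min = r[i], z = z[i]))
  # vertex of the parabola through the three nodes
  b <- (d1 * h2 + d2 * h1) / (h1 + h2)  # first derivative at s[i]
  ds <- -b / (2 * a)
  ds <- max(min(ds, h2), -h1)
  r_min <- r[i] + b * ds + a * ds^2
  z_min <- stats::approx(s, z, xout = s[i] + ds)$y
  list(r_min = r_min, z = z_min)
}

# augmented-Lagrangian relaxation of the interior tangent angles at fixed
# dimensionless pressure; returns the relaxed state and diagnostics
.relax_core <- function(psi_int, dl, opts) {
  vfix <- if (is.null(dl$vfix)) -1 else dl$vfix
  lam <- 0; mu <- 1e3
  lam2 <- 0; mu2 <- if (vfix > 0) 1e2 else 0
  n_iter <- 0L
  g_prev <- Inf; gv_prev <- Inf
  ok <- FALSE
  message <- "ok"
  for (outer in 1:14) {
    fn <- function(x) helfrich_objective(x, dl$L, dl$wwin, dl$zc, dl$p,
                                         dl$sig, lam, mu, vfix, lam2, mu2)
    gr <- function(x) helfrich_objective_grad(x, dl$L, dl$wwin, dl$zc,
                                              dl$p, dl$sig, lam, mu,
                                              vfix, lam2, mu2)
    fit <- stats::optim(
      psi_int, fn = fn, gr = gr, method = "L-BFGS-B",
      control = list(maxit = opts$max_iter, factr = 1, pgtol = 1e-10))
    psi_int <- fit$par
    n_iter <- n_iter + fit$counts[["function"]]
    ev <- helfrich_eval(c(0, psi_int, 0), dl$L, dl$wwin, dl$zc, dl$p, dl$sig)
    if (!ev$feasible) {
      return(list(psi_int = psi_int, ev = ev, n_iter = n_iter,
                  ok = FALSE, message = "infeasible state reached"))
    }
    if (max(ev$r) > opts$balloon_cutoff) {
      return(list(psi_int = psi_int, ev = ev, n_iter = n_iter, ok = FALSE,
                  message = sprintf(
                    "runaway ballooning: r_max/R = %.2f exceeds cutoff %.2f",
                    max(ev$r), opts$balloon_cutoff)))
    }
    gv <- if (vfix > 0) ev$V_tot - vfix else 0
    if (abs(ev$g) < 1e-11 && abs(gv) < 1e-8 * max(1, vfix)) {
      ok <- TRUE; break
    }
    if (abs(ev$g) >= 1e-11) {
      lam <- lam + mu * ev$g
      if (abs(ev$g) > 0.25 * g_prev) mu <- mu * 10
      g_prev <- abs(ev$g)
    }
    if (vfix > 0 && abs(gv) >= 1e-8 * max(1, vfix)) {
      lam2 <- lam2 + mu2 * gv
      if (abs(gv) > 0.25 * gv_prev) mu2 <- mu2 * 10
      gv_prev <- abs(gv)
    }
  }
  if (!ok && abs(ev$g) < 1e-8 &&
      (vfix <= 0 || abs(ev$V_tot - vfix) < 1e-6 * vfix)) ok <- TRUE
  if (!ok) message <- "radial closure constraint not met"
  # exact radial-closure projection: scalar Newton along the closure
  # gradient direction (negligible energy change, machine-exact clamp)
  if (ok) {
    d <- cos(psi_int)
    for (k in 1:4) {
      ev <- helfrich_eval(c(0, psi_int, 0), dl$L, dl$wwin, dl$zc,
                          dl$p, dl$sig)
      if (abs(ev$g) < 1e-15) break
      eps <- 1e-7
      evp <- helfrich_eval(c(0, psi_int + eps * d, 0), dl$L, dl$wwin,
                           dl$zc, dl$p, dl$sig)
      dg <- (evp$g - ev$g) / eps
      if (!is.finite(dg) || abs(dg) < 1e-12) break
      psi_int <- psi_int - (ev$g / dg) * d
    }
    ev <- helfrich_eval(c(0, psi_int, 0), dl$L, dl$wwin, dl$zc, dl$p, dl$sig)
  }
  list(psi_int = psi_int, ev = ev, n_iter = n_iter, ok = ok,
       message = message)
}

# projected-gradient stationarity measure of an interior tangent-angle
# state, normalized by the energy scale kappa/R^2 times the surface area
.residual_core <- function(psi_int, dl) {
  vfix <- if (is.null(dl$vfix)) -1 else dl$vfix
  gE <- helfrich_objective_grad(psi_int, dl$L, dl$wwin, dl$zc, dl$p,
                                dl$sig, lam = 0, mu = 0)
  gC <- helfrich_objective_grad(psi_int, dl$L, dl$wwin, dl$zc, dl$p,
                                dl$sig, lam = 1, mu = 0) - gE
  basis <- list(gC)
  if (vfix > 0) {
    gV <- helfrich_objective_grad(psi_int, dl$L, dl$wwin, dl$zc, dl$p,
                                  dl$sig, lam = 0, mu = 0, vfix = vfix,
                                  lam2 = 1, mu2 = 0) - gE
    basis <- c(basis, list(gV))
  }
  # orthonormalize the constraint gradients, then project them out of gE
  proj <- gE
  ortho <- list()
  for (b in basis) {
    for (q in ortho) b <- b - sum(b * q) * q
    nb <- sqrt(sum(b^2))
    if (nb > 1e-300) ortho <- c(ortho, list(b / nb))
  }
  for (q in ortho) proj <- proj - sum(proj * q) * q
  ev <- helfrich_eval(c(0, psi_int, 0), dl$L, dl$wwin, dl$zc, dl$p, dl$sig)
  sqrt(sum(proj^2)) / ev$area
}

# --- exported operations ---------------------------------------------------

#' Relax a profile to a constrained local equilibrium
#'
#' Minimizes the total energy (bending + pressure work, at fixed lateral
#' tension) over axisymmetric profiles subject to the boundary conditions
#' of the constriction model: both ends clamped at the reference radius
#' with the meridian parallel to the axis, fixed axial span L, membrane
#' area free. The minimizer is a warm-startable quasi-Newton
#' (L-BFGS-B) descent on the interior tangent angles with the radial
#' closure handled by an augmented Lagrangian; it is fully deterministic.
#'
#' With zero tension an open tube could lower its bending energy
#' indefinitely by ballooning, so the physically meaningful solution is the
#' local equilibrium continuously connected to the cylinder; runaway
#' ballooning (`r_max/R` beyond `balloon_cutoff`) is detected and aborted.
#'
#' @param initial An [axisym_shape()] starting guess (resampled onto the
#'   solver's uniform arc grid if needed).
#' @param params A [membrane_params()].
#' @param geometry A [tube_geometry()].
#' @param load A [load_profile()].
#' @param opts A [solver_options()].
#' @param conserve_volume Hold the total enclosed volume at its
#'   undeformed value `pi R^2 L` (a model variant for an impermeable,
#'   osmotically clamped tube; default `FALSE`, the baseline model leaves
#'   the volume free).
#' @return An object of class `equilibrium_result`: list with `shape`,
#'   `energy` (an `energy_breakdown`), `r_min`, `r_min_z`, `residual`,
#'   `converged`, `n_iter`, `message`.
#' @examples
#' \donttest{
#' sc <- baseline_scenario()
#' cyl <- make_cylinder_profile(sc$geometry, 101)
#' load <- load_profile(100, 50e-9, geometry = sc$geometry)
#' eq <- relax_shape(cyl, sc$params, sc$geometry, load,
#'                   solver_options(n_nodes = 101))
#' eq$r_min
#' }
#' @export
relax_shape <- function(initial, params, geometry, load,
                        opts = solver_options(),
                        conserve_volume = FALSE) {
  stopifnot(inherits(initial, "axisym_shape"),
            inherits(params, "membrane_params"),
            inherits(geometry, "tube_geometry"),
            inherits(load, "load_profile"))
  dl <- .dimless_problem(params, geometry, load, conserve_volume)
  psi_int <- .psi_interior(initial, opts$n_nodes)
  res <- .relax_core(psi_int, dl, opts)
  .package_result(res, dl, params, geometry, load, opts)
}

# assemble an equilibrium_result from a relaxed core state
.package_result <- function(res, dl, params, geometry, load, opts) {
  if (!res$ok) {
    shape <- tryCatch(.shape_from_psi(res$psi_int, dl, geometry),
                      error = function(e) NULL)
    return(structure(list(shape = shape, energy = NULL, r_min = NA_real_,
                          r_min_z = NA_real_, residual = NA_real_,
                          converged = FALSE, n_iter = res$n_iter,
                          message = res$message),
                     class = "equilibrium_result"))
  }
  shape <- .shape_from_psi(res$psi_int, dl, geometry)
  energy <- total_energy(shape, params, load)
  rm <- .refine_rmin(shape$s, shape$r, shape$z)
  residual <- .residual_core(res$psi_int, dl)
  structure(list(shape = shape, energy = energy, r_min = rm$r_min,
                 r_min_z = rm$z, residual = residual,
                 converged = residual <= opts$grad_tol,
                 n_iter = res$n_iter, message = res$message),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_result> converged = %s, r_min = %.4g nm, residual = %.3g, iterations = %d\n",
    x$converged, x$r_min * 1e9, x$residual, x$n_iter))
  invisible(x)
}

#' Stationarity residual of a profile
#'
#' Norm of the discrete energy gradient with respect to admissible
#' (boundary-respecting) perturbations of the tangent angles, projected
#' onto the closure-constraint tangent space and normalized by the energy
#' scale `kappa/R^2` times the surface area. Zero for an exact constrained
#' equilibrium. Note that the undeformed cylinder at zero pressure and
#' zero tension is not an equilibrium of the Helfrich functional (the
#' shape equation leaves an unbalanced `kappa/(2 R^3)` pressure term), so
#' its residual is well above any convergence tolerance.
#'
#' @inheritParams relax_shape
#' @param shape An [axisym_shape()] (resampled onto a uniform arc grid of
#'   the same node count if necessary).
#' @inheritParams relax_shape
#' @return A dimensionless residual.
#' @export
stationarity_residual <- function(shape, params, geometry, load,
                                  conserve_volume = FALSE) {
  dl <- .dimless_problem(params, geometry, load, conserve_volume)
  psi_int <- .psi_interior(shape, nrow(shape))
  .residual_core(psi_int, dl)
}

#' Pressure continuation sweep
#'
#' Traces the equilibrium branch continuously connected to the undeformed
#' tube: starting from the cylinder at `P = 0`, the pressure is increased
#' in adaptive steps and each relaxation is warm-started from the previous
#' equilibrium. The curve is truncated (never extrapolated across) at a
#' limit point, i.e. when relaxation fails or the neck radius jumps.
#'
#' @inheritParams relax_shape
#' @param load_template A [load_profile()] carrying the strip geometry
#'   (its `P` is ignored).
#' @param P_max Sweep bound in Pa (alternatively give `Pi_max`).
#' @param Pi_max Sweep bound as dimensionless `P R^3 / (2 kappa)`.
#' @param keep_shapes Keep each equilibrium's profile in the result
#'   (memory-heavier; default `FALSE`).
#' @inheritParams relax_shape
#' @return An object of class `constriction_curve`: a data frame of points
#'   `(P, Pi, r_min, r_over_R, F_B, W_P, total, converged)` ordered by
#'   increasing pressure, with attributes `branch_monotone` (flag) and
#'   `limit_point_P` (Pa, or `NA` if the sweep completed).
#' @export
continuation_sweep <- function(params, geometry, load_template,
                               P_max = NULL, opts = solver_options(),
                               Pi_max = NULL, keep_shapes = FALSE,
                               conserve_volume = FALSE) {
  if (is.null(P_max) + is.null(Pi_max) != 1L)
    stop("exactly one of `P_max` and `Pi_max` must be given")
  R <- geometry$R; kappa <- params$kappa
  if (is.null(P_max)) P_max <- Pi_max * 2 * kappa / R^3
  if (P_max <= 0) stop("the sweep bound must be positive")
  load0 <- load_profile(0, load_template$strip_width,
                        load_template$strip_center, geometry)
  dl <- .dimless_problem(params, geometry, load0, conserve_volume)
  p_unit <- R^3 / kappa               # Pa -> dimensionless p = P R^3/kappa
  p_max <- P_max * p_unit
  pi_to_p <- 2                         # p = 2 * Pi

  psi_int <- .psi_interior(make_cylinder_profile(geometry, opts$n_nodes),
                           opts$n_nodes)
  rows <- list(); shapes <- list()
  limit_point_P <- NA_real_

  record <- function(res, dl_here) {
    eqr <- .package_result(res, dl_here, params, geometry,
                           load_profile(dl_here$p / p_unit,
                                        load_template$strip_width,
                                        load_template$strip_center,
                                        geometry),
                           opts)
    list(row = data.frame(
           P = dl_here$p / p_unit,
           Pi = dl_here$p / pi_to_p,
           r_min = eqr$r_min,
           r_over_R = eqr$r_min / R,
           F_B = eqr$energy$F_B, W_P = eqr$energy$W_P,
           total = eqr$energy$total,
           converged = eqr$converged),
         eq = eqr)
  }

  # first point: the zero-pressure equilibrium
  dl$p <- 0
  res <- .relax_core(psi_int, dl, opts)
  if (!res$ok) stop("relaxation failed at P = 0: ", res$message)
  psi_int <- res$psi_int
  rec <- record(res, dl)
  rows[[1]] <- rec$row
  if (keep_shapes) shapes[[1]] <- rec$eq$shape
  r_prev <- rec$row$r_over_R

  step <- opts$continuation_step * pi_to_p   # dimensionless p step
  min_step <- step / 256
  p_cur <- 0
  while (p_cur < p_max - 1e-12) {
    p_try <- min(p_cur + step, p_max)
    dl$p <- p_try
    res <- .relax_core(psi_int, dl, opts)
    jump <- res$ok && (r_prev - min(res$ev$r)) > 0.2
    if (!res$ok || jump) {
      step <- step / 2
      if (step < min_step) {
        limit_point_P <- p_cur / p_unit
        break
      }
      next
    }
    p_cur <- p_try
    psi_int <- res$psi_int
    rec <- record(res, dl)
    rows[[length(rows) + 1L]] <- rec$row
    if (keep_shapes) shapes[[length(rows)]] <- rec$eq$shape
    dr <- r_prev - rec$row$r_over_R
    r_prev <- rec$row$r_over_R
    # aim for ~0.04 R of neck travel per step
    step <- step * max(0.5, min(2, 0.04 / max(dr, 1e-6)))
  }
  curve <- do.call(rbind, rows)
  mono <- all(diff(curve$r_over_R) <= 1e-6)
  structure(curve,
            branch_monotone = mono,
            limit_point_P = limit_point_P,
            shapes = if (keep_shapes) shapes else NULL,
            geometry = geometry, params = params,
            class = c("constriction_curve", "data.frame"))
}

#' @export
print.constriction_curve <- function(x, ...) {
  lp <- attr(x, "limit_point_P")
  cat(sprintf(
    "<constriction_curve> %d points, P in [0, %.4g] Pa, r/R down to %.3f%s\n",
    nrow(x), max(x$P), min(x$r_over_R),
    if (is.na(lp)) "" else sprintf(", limit point near %.4g Pa", lp)))
  invisible(x)
}

#' Pressure required for a target neck radius
#'
#' Root-finds, along the continuation branch, the pressure whose
#' equilibrium has narrowest radius `r_target` (within 1 nm or 0.2% of R,
#' whichever is tighter in absolute terms is used as the stopping width).
#' Targets below the branch's reachable minimum (beyond a limit point)
#' raise an explicit error rather than extrapolating.
#'
#' @inheritParams continuation_sweep
#' @inheritParams relax_shape
#' @param r_target Target narrowest radius, m, in `(0, R]`.
#' @return A list with elements `P` (Pa) and `result` (the
#'   [relax_shape()] equilibrium at that pressure).
#' @export
pressure_for_radius <- function(params, geometry, load_template, r_target,
                                opts = solver_options(),
                                conserve_volume = FALSE) {
  R <- geometry$R
  if (!(r_target > 0 && r_target <= R))
    stop("`r_target` must lie in (0, R]")
  kappa <- params$kappa
  p_unit <- R^3 / kappa
  dl <- .dimless_problem(
    params, geometry,
    load_profile(0, load_template$strip_width, load_template$strip_center,
                 geometry),
    conserve_volume)
  tol_r <- min(1e-9, 2e-3 * R) / R     # dimensionless target tolerance
  target <- r_target / R

  psi_int <- .psi_interior(make_cylinder_profile(geometry, opts$n_nodes),
                           opts$n_nodes)
  relax_at <- function(p, start) {
    dl$p <- p
    .relax_core(start, dl, opts)
  }
  rmin_of <- function(res) {
    n <- length(res$ev$r)
    s <- seq(0, res$ev$S, length.out = n)
    .refine_rmin(s, res$ev$r, res$ev$z)$r_min
  }

  res0 <- relax_at(0, psi_int)
  if (!res0$ok) stop("relaxation failed at P = 0: ", res0$message)
  psi_int <- res0$psi_int
  r0 <- rmin_of(res0)
  if (abs(r0 - target) <= tol_r || target >= 1) {
    return(list(P = 0,
                result = .package_result(
                  res0, dl, params, geometry,
                  load_profile(0, load_template$strip_width,
                               load_template$strip_center, geometry),
                  opts)))
  }

  # march outward until the target is bracketed, warm-starting each step
  step <- 2 * opts$continuation_step   # dimensionless p
  min_step <- step / 256
  p_lo <- 0; r_lo <- r0
  p_cur <- 0; r_prev <- r0
  bracket <- NULL
  p_cap <- 1000                        # Pi = 500, far beyond any modeled neck
  while (is.null(bracket)) {
    p_try <- p_cur + step
    if (p_try > p_cap)
      stop("target radius unreachable on branch: pressure cap hit")
    res <- relax_at(p_try, psi_int)
    jump <- res$ok && (r_prev - min(res$ev$r)) > 0.2
    if (!res$ok || jump) {
      step <- step / 2
      if (step < min_step)
        stop("target radius unreachable on branch: ",
             "limit point near P = ", format(p_cur / p_unit, digits = 5),
             " Pa (r_min/R = ", format(r_prev, digits = 4), ")")
      next
    }
    p_cur <- p_try
    psi_int <- res$psi_int
    r_cur <- rmin_of(res)
    if (r_cur <= target) {
      bracket <- list(p_hi = p_cur, r_hi = r_cur, res_hi = res)
    } else {
      p_lo <- p_cur; r_lo <- r_cur
      dr <- r_prev - r_cur
      step <- step * max(0.5, min(2, 0.08 / max(dr, 1e-6)))
    }
    r_prev <- r_cur
  }

  # regula falsi (Illinois) on r_min(p) - target within the bracket
  p_hi <- bracket$p_hi; r_hi <- bracket$r_hi
  res_best <- bracket$res_hi
  f_lo <- r_lo - target; f_hi <- r_hi - target
  side <- 0L
  for (it in 1:60) {
    if (abs(f_hi) <= tol_r) break
    if (abs(f_lo) <= tol_r) { # converged on the shallow side
      res <- relax_at(p_lo, psi_int)
      if (res$ok) { res_best <- res; p_hi <- p_lo; f_hi <- f_lo }
      break
    }
    p_new <- (p_lo * f_hi - p_hi * f_lo) / (f_hi - f_lo)
    if (!is.finite(p_new) || p_new <= min(p_lo, p_hi) ||
        p_new >= max(p_lo, p_hi))
      p_new <- (p_lo + p_hi) / 2
    res <- relax_at(p_new, psi_int)
    if (!res$ok)
      stop("relaxation failed during root refinement at P = ",
           format(p_new / p_unit, digits = 5), " Pa: ", res$message)
    psi_int <- res$psi_int
    f_new <- rmin_of(res) - target
    if (f_new <= 0) {
      p_hi <- p_new; f_hi <- f_new; res_best <- res
      if (side == -1L) f_lo <- f_lo / 2
      side <- -1L
    } else {
      p_lo <- p_new; f_lo <- f_new
      if (side == 1L) f_hi <- f_hi / 2
      side <- 1L
    }
    if (abs(p_hi - p_lo) < 1e-9 * max(1, p_hi)) break
  }
  P <- p_hi / p_unit
  load <- load_profile(P, load_template$strip_width,
                       load_template$strip_center, geometry)
  dl$p <- p_hi
  list(P = P,
       result = .package_result(res_best, dl, params, geometry, load, opts))
}
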