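#' Actin force parameters
#'
#' The force developed by a single polymerizing actin filament, about 1 pN,
#' used to convert constriction pressures into filament counts.
#'
#' @param f1 Per-filament polymerization force in Newtons (default 1e-12).
#' @return An object of class `force_params`.
#' @export
force_params <- function(f1 = 1e-12) {
  stopifnot(is.numeric(f1), length(f1) == 1L, is.finite(f1))
  if (f1 <= 0) stop("per-filament force `f1` must be positive")
  structure(list(f1 = f1), class = "force_params")
}

#' Dimensionless pressure
#'
#' The universal dimensionless pressure `Pi = P R^3 / (2 kappa)` that,
#' together with `r/R`, collapses all geometrically similar
#' pressure-constriction curves onto one.
#'
#' @param P Pressure in Pa.
#' @param R Tube radius in m.
#' @param kappa Bending modulus in J.
#' @return The dimensionless pressure.
#' @examples
#' nondimensionalize_pressure(13.15, 230e-9, 8e-20) # ~1.000
#' @export
nondimensionalize_pressure <- function(P, R, kappa) {
  if (!all(R > 0)) stop("`R` must be positive")
  if (!all(kappa > 0)) stop("`kappa` must be positive")
  P * R^3 / (2 * kappa)
}

#' Number of polymerizing actin filaments required
#'
#' Converts an equilibrium constriction pressure into the number of actin
#' filaments, each developing force `f1`, needed to supply the total
#' normal force on the pressure strip: `N_f = P * A_strip / f1`, with
#' `A_strip` the deformed membrane area inside the strip window
#' ([strip_area()]). Returned as a real number, not rounded.
#'
#' @param P Pressure in Pa.
#' @param equilibrium A converged [relax_shape()] result at that pressure.
#' @param load The [load_profile()] defining the strip.
#' @param fp A [force_params()].
#' @return Filament count (dimensionless, `>= 0`).
#' @examples
#' # a 980 Pa load on a cylindrical strip of radius 65 nm and width 50 nm
#' # needs 980 * 2*pi*65e-9*50e-9 / 1e-12 ~ 20 filaments
#' @export
filaments_required <- function(P, equilibrium, load, fp = force_params()) {
  .check_converged(equilibrium)
  A <- strip_area(equilibrium$shape, load)
  P * A / fp$f1
}

#' Actomyosin ring tension required
#'
#' Converts an equilibrium constriction pressure into the line tension of
#' a contractile actomyosin ring that is mechanically equivalent to the
#' strip pressure, via the hoop (Laplace) force balance: a ring of line
#' tension `gamma_m` at radius `r` exerts an inward force per unit
#' circumference of `gamma_m / r`; distributed over the strip width `w`
#' this balances the pressure when `gamma_m = P * r_strip * w`. The ring
#' radius `r_strip = A_strip / (2 pi w)` is the mean radius of the
#' deformed membrane inside the strip (area-equivalent cylinder radius),
#' which makes the identity `N_f * f1 = 2 pi * gamma_m` exact.
#'
#' @inheritParams filaments_required
#' @return Ring line tension in Newtons.
#' @export
ring_tension_required <- function(P, equilibrium, load) {
  .check_converged(equilibrium)
  A <- strip_area(equilibrium$shape, load)
  r_strip <- A / (2 * pi * load$strip_width)
  P * r_strip * load$strip_width
}

.check_converged <- function(equilibrium) {
  if (!inherits(equilibrium, "equilibrium_result"))
    stop("`equilibrium` must be an equilibrium_result")
  if (!isTRUE(equilibrium$converged))
    stop("force conversion requires a converged equilibrium")
  invisible(TRUE)
}

#' Constriction report for a set of target radii
#'
#' For each target narrowest radius, root-finds the required pressure
#' ([pressure_for_radius()]) and converts it into the two mechanistic
#' readouts: actin filament count `N_f` and actomyosin ring tension
#' `gamma_m`. Unreachable targets (beyond a limit point of the branch) are
#' flagged rather than failing the whole report. As a sensitivity to the
#' ring-radius convention, the tension is also reported with the narrowest
#' radius in place of the strip-mean radius (`gamma_m_rmin`).
#'
#' @inheritParams pressure_for_radius
#' @inheritParams relax_shape
#' @param fp A [force_params()].
#' @param r_targets Target narrowest radii in m, each in `(0, R]`.
#' @param keep_results Keep the per-target equilibrium objects as an
#'   attribute (default `TRUE`).
#' @return An object of class `constriction_report`: a data frame with one
#'   row per target (ordered by decreasing radius) and columns `r_target`,
#'   `r_over_R`, `P`, `Pi`, `A_strip`, `N_f`, `gamma_m`, `gamma_m_rmin`,
#'   `reachable`.
#' @examples
#' \donttest{
#' sc <- baseline_scenario()
#' rep <- constriction_report(sc$params, sc$geometry, sc$load_template,
#'                            sc$force_params, sc$r_targets,
#'                            solver_options(n_nodes = 101))
#' }
#' @export
constriction_report <- function(params, geometry, load_template,
                                fp = force_params(), r_targets,
                                opts = solver_options(),
                                conserve_volume = FALSE,
                                keep_results = TRUE) {
  stopifnot(length(r_targets) >= 1L, all(r_targets > 0),
            all(r_targets <= geometry$R))
  r_targets <- sort(r_targets, decreasing = TRUE)
  rows <- vector("list", length(r_targets))
  results <- vector("list", length(r_targets))
  for (i in seq_along(r_targets)) {
    rt <- r_targets[i]
    ans <- tryCatch(
      pressure_for_radius(params, geometry, load_template, rt, opts,
                          conserve_volume = conserve_volume),
      error = function(e) e)
    if (inherits(ans, "error")) {
      rows[[i]] <- data.frame(
        r_target = rt, r_over_R = rt / geometry$R, P = NA_real_,
        Pi = NA_real_, A_strip = NA_real_, N_f = NA_real_,
        gamma_m = NA_real_, gamma_m_rmin = NA_real_, reachable = FALSE)
      attr(rows[[i]], "error") <- conditionMessage(ans)
      next
    }
    load <- load_profile(ans$P, load_template$strip_width,
                         load_template$strip_center, geometry)
    A <- strip_area(ans$result$shape, load)
    rows[[i]] <- data.frame(
      r_target = rt,
      r_over_R = rt / geometry$R,
      P = ans$P,
      Pi = nondimensionalize_pressure(ans$P, geometry$R, params$kappa),
      A_strip = A,
      N_f = filaments_required(ans$P, ans$result, load, fp),
      gamma_m = ring_tension_required(ans$P, ans$result, load),
      gamma_m_rmin = ans$P * ans$result$r_min * load$strip_width,
      reachable = TRUE)
    results[[i]] <- ans$result
  }
  structure(do.call(rbind, rows),
            params = params, geometry = geometry,
            load_template = load_template, force_params = fp,
            results = if (keep_results) results else NULL,
            class = c("constriction_report", "data.frame"))
}

#' @export
print.constriction_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

#' Write a constriction report as CSV (+ JSON sidecar)
#'
#' The CSV carries `r_target_nm,r_over_R,P_Pa,Pi,A_strip_nm2,N_f,
#' gamma_m_pN,gamma_m_rmin_pN,reachable`; the JSON sidecar records the
#' scenario parameters and solver provenance.
#'
#' @param report A [constriction_report()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param opts The [solver_options()] used (recorded in the sidecar).
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, opts = NULL) {
  df <- data.frame(
    r_target_nm = fmt_num(report$r_target * 1e9),
    r_over_R = fmt_num(report$r_over_R),
    P_Pa = fmt_num(report$P),
    Pi = fmt_num(report$Pi),
    A_strip_nm2 = fmt_num(report$A_strip * 1e18),
    N_f = fmt_num(report$N_f),
    gamma_m_pN = fmt_num(report$gamma_m * 1e12),
    gamma_m_rmin_pN = fmt_num(report$gamma_m_rmin * 1e12),
    reachable = report$reachable)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  geom <- attr(report, "geometry")
  params <- attr(report, "params")
  loadT <- attr(report, "load_template")
  fp <- attr(report, "force_params")
  sidecar <- list(
    package = "mitoconstrict",
    version = as.character(utils::packageVersion("mitoconstrict")),
    kappa_J = params$kappa,
    lateral_tension_N_per_m = params$lateral_tension,
    R_nm = geom$R * 1e9, L_nm = geom$L * 1e9,
    strip_width_nm = loadT$strip_width * 1e9,
    strip_center_nm = loadT$strip_center * 1e9,
    f1_pN = fp$f1 * 1e12,
    solver = if (is.null(opts)) NULL else unclass(opts))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
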