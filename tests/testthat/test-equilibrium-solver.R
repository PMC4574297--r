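test_that("solver options validate their invariants", {
  expect_error(solver_options(n_nodes = 100), "odd")
  expect_error(solver_options(n_nodes = 31), "odd|51")
  expect_error(solver_options(grad_tol = 0))
  expect_s3_class(solver_options(), "solver_options")
})

test_that("zero-pressure relaxation stays near the cylinder", {
  geom <- baseline_geometry()
  params <- baseline_params()
  cyl <- make_cylinder_profile(geom, 101)
  eq <- relax_shape(cyl, params, geom, baseline_load(P = 0), fast_opts())
  expect_true(eq$converged)
  expect_lte(eq$residual, solver_options()$grad_tol)
  # total energy can only go down from the starting cylinder
  expect_lte(eq$energy$total, pi * params$kappa * geom$L / geom$R)
  # narrowest radius stays at the clamped ends
  expect_equal(eq$r_min / geom$R, 1, tolerance = 0.01)
  # boundary clamps hold exactly
  sh <- eq$shape
  expect_equal(sh$r[c(1, nrow(sh))] / geom$R, c(1, 1), tolerance = 1e-12)
  expect_identical(sh$psi[c(1, nrow(sh))], c(0, 0))
  expect_equal(sh$z[nrow(sh)], geom$L, tolerance = 1e-12)
})

test_that("relaxed energy matches a derivative-free direct search over a
           six-parameter clamped profile family", {
  # independent oracle: r(z) = R + sum_k c_k sin(pi z/L) sin(k pi z/L),
  # curvature from the graph formula, Nelder-Mead direct search
  kappa <- 8e-20; R <- 230e-9; L <- 680e-9; w <- 50e-9; zc <- L / 2
  Pi <- 3
  P <- Pi * 2 * kappa / R^3
  K <- 6; nq <- 1501
  z <- seq(0, L, length.out = nq); a <- pi / L
  B <- B1 <- B2 <- matrix(0, nq, K)
  for (k in seq_len(K)) {
    b <- k * pi / L
    B[, k] <- sin(a * z) * sin(b * z)
    B1[, k] <- a * cos(a * z) * sin(b * z) + b * sin(a * z) * cos(b * z)
    B2[, k] <- -(a^2 + b^2) * B[, k] + 2 * a * b * cos(a * z) * cos(b * z)
  }
  win <- z >= zc - w / 2 & z <= zc + w / 2
  dz <- z[2] - z[1]
  oracle_energy <- function(cc) {       # cc in nm; returns Joules
    ccm <- cc * 1e-9
    r <- R + drop(B %*% ccm)
    r1 <- drop(B1 %*% ccm)
    r2 <- drop(B2 %*% ccm)
    if (any(r <= 5e-9)) return(1)
    g <- sqrt(1 + r1^2)
    J <- 1 / (r * g) - r2 / g^3
    f <- 0.5 * kappa * J^2 * 2 * pi * r * g
    FB <- sum((f[-1] + f[-nq]) / 2) * dz
    ri <- r[win]
    Vw <- pi * sum((ri[-1]^2 + ri[-length(ri)]^2) / 2) * dz
    FB + P * Vw
  }
  fit <- stats::optim(rep(0, K), oracle_energy, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-12))
  fit <- stats::optim(fit$par, oracle_energy, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-12))

  geom <- tube_geometry(R, L)
  eq <- relax_shape(make_cylinder_profile(geom, 51), baseline_params(),
                    geom, load_profile(P, w, geometry = geom),
                    solver_options(n_nodes = 51))
  expect_true(eq$converged)
  expect_equal(eq$energy$total, fit$value, tolerance = 0.02)
})

test_that("a converged equilibrium is a fixed point and reproduces its
           stored energy", {
  sc <- baseline_scenario()
  opts <- fast_opts()
  ans <- pressure_for_radius(sc$params, sc$geometry, sc$load_template,
                             145e-9, opts)
  expect_true(ans$result$converged)
  expect_equal(ans$result$r_min, 145e-9, tolerance = 1e-9 / 145e-9)
  load <- load_profile(ans$P, 50e-9, geometry = sc$geometry)
  # idempotence: re-relaxing its own output changes nothing material
  eq2 <- relax_shape(ans$result$shape, sc$params, sc$geometry, load, opts)
  expect_lt(abs(eq2$r_min - ans$result$r_min), 0.5e-9)
  # stored energy is exactly what total_energy reports for the shape
  eb <- total_energy(ans$result$shape, sc$params, load)
  expect_identical(ans$result$energy$total, eb$total)
  expect_identical(ans$result$energy$F_B, eb$F_B)
})

test_that("the stationarity residual separates equilibria from
           non-equilibria", {
  geom <- baseline_geometry()
  params <- baseline_params()
  load0 <- baseline_load(P = 0)
  # the zero-tension cylinder is NOT an equilibrium of the Helfrich
  # functional (unbalanced kappa/(2R^3) shape-equation term)
  cyl <- make_cylinder_profile(geom, 101)
  expect_gt(stationarity_residual(cyl, params, geom, load0),
            solver_options()$grad_tol)
  # a relaxed shape is
  eq <- relax_shape(cyl, params, geom, load0, fast_opts())
  expect_lte(stationarity_residual(eq$shape, params, geom, load0),
             solver_options()$grad_tol)
})

test_that("continuation tracks a monotone branch with consistent
           dimensionless pressure", {
  sc <- baseline_scenario()
  curve <- continuation_sweep(sc$params, sc$geometry, sc$load_template,
                              Pi_max = 12, opts = fast_opts())
  expect_s3_class(curve, "constriction_curve")
  expect_equal(curve$r_over_R[1], 1, tolerance = 0.01)
  expect_true(all(diff(curve$P) > 0))
  expect_true(all(diff(curve$r_over_R) <= 1e-6))
  expect_true(attr(curve, "branch_monotone"))
  expect_true(all(curve$converged))
  # stored Pi is exactly P R^3/(2 kappa)
  expect_equal(curve$Pi,
               nondimensionalize_pressure(curve$P, sc$geometry$R,
                                          sc$params$kappa),
               tolerance = 1e-12)
  expect_true(all(curve$r_over_R <= 1 + 1e-6))
})

test_that("pressure root-finding brackets targets and refuses
           unreachable ones", {
  sc <- baseline_scenario()
  opts <- fast_opts()
  # the undeformed radius needs no pressure
  at_R <- pressure_for_radius(sc$params, sc$geometry, sc$load_template,
                              230e-9, opts)
  expect_equal(at_R$P, 0)
  expect_error(
    pressure_for_radius(sc$params, sc$geometry, sc$load_template,
                        -5e-9, opts),
    "(0, R]", fixed = TRUE)
  # pressures increase with constriction depth
  Ps <- vapply(c(180e-9, 145e-9, 110e-9), function(rt)
    pressure_for_radius(sc$params, sc$geometry, sc$load_template, rt,
                        opts)$P, numeric(1))
  expect_true(all(diff(Ps) > 0))
})

test_that("deep targets beyond a volume-conserving limit point raise an
           explicit error", {
  # with the enclosed volume held fixed the pressure-controlled branch
  # terminates at a limit point well above r/R = 0.5
  sc <- baseline_scenario()
  expect_error(
    pressure_for_radius(sc$params, sc$geometry, sc$load_template, 65e-9,
                        fast_opts(), conserve_volume = TRUE),
    "unreachable")
})

test_that("the required pressure is mesh-independent at the percent
           level", {
  sc <- baseline_scenario()
  P1 <- pressure_for_radius(sc$params, sc$geometry, sc$load_template,
                            145e-9, solver_options(n_nodes = 101))$P
  P2 <- pressure_for_radius(sc$params, sc$geometry, sc$load_template,
                            145e-9, solver_options(n_nodes = 201))$P
  expect_lt(abs(P2 - P1) / P1, 0.02)
})
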