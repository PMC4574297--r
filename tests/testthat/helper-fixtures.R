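# Shared fixtures: canonical analytic profiles and a memoized baseline
# report so the expensive root-finds run once per test session.

baseline_geometry <- function() tube_geometry(R = 230e-9, L = 680e-9)
baseline_params <- function() membrane_params(kappa = 8e-20)
baseline_load <- function(P = 0, w = 50e-9)
  load_profile(P, w, geometry = baseline_geometry())

# spherical cap of radius rho spanning polar angle +/- theta_max, built in
# the package's sign convention (psi equals the polar angle)
sphere_cap_shape <- function(rho, theta_max = 0.6, n = 401) {
  theta <- seq(-theta_max, theta_max, length.out = n)
  r <- rho * cos(theta)
  z <- rho * sin(theta)
  s <- rho * (theta - theta[1])
  geom <- tube_geometry(R = r[1], L = z[n] - z[1])
  axisym_shape(s = s, z = z - z[1], r = r, psi = theta, geometry = geom,
               validate = FALSE)
}

# catenoid r(z) = a cosh((z - z0)/a): the minimal surface, J == 0
catenoid_shape <- function(a, half_span = 0.8, n = 401) {
  u <- seq(-half_span, half_span, length.out = n)   # u = (z - z0)/a
  r <- a * cosh(u)
  z <- a * u
  s <- a * (sinh(u) - sinh(u[1]))
  psi <- -atan(sinh(u))
  geom <- tube_geometry(R = r[1], L = z[n] - z[1])
  axisym_shape(s = s, z = z - z[1], r = r, psi = psi, geometry = geom,
               validate = FALSE)
}

# fast solver options for tests that do not need the production mesh
fast_opts <- function(n_nodes = 101L) solver_options(n_nodes = n_nodes)

# memoized baseline constriction report at the production mesh
.cache <- new.env(parent = emptyenv())
baseline_report <- function() {
  if (is.null(.cache$report)) {
    sc <- baseline_scenario()
    .cache$report <- constriction_report(
      sc$params, sc$geometry, sc$load_template, sc$force_params,
      sc$r_targets, solver_options(n_nodes = 201))
  }
  .cache$report
}
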