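test_that("cylinder profile construction matches its definition", {
  geom <- baseline_geometry()
  cyl <- make_cylinder_profile(geom, 201)
  expect_equal(nrow(cyl), 201L)
  expect_true(all(cyl$r == 230e-9))
  expect_true(all(cyl$psi == 0))
  expect_equal(cyl$z[201], 680e-9)
  # psi == 0 means the arc coordinate coincides with z
  expect_equal(max(cyl$s) - min(cyl$s), 680e-9)

  unit <- make_cylinder_profile(tube_geometry(1, 1), 11)
  expect_equal(unit$r[c(1, 11)], c(1, 1))
  expect_true(all(unit$psi == 0))

  expect_error(make_cylinder_profile(geom, 200), "odd")
  expect_error(make_cylinder_profile(geom, 9), "at least 11")
})

test_that("type constructors enforce their invariants", {
  expect_error(membrane_params(-1e-20), "positive")
  expect_error(membrane_params(8e-20, lateral_tension = 1e-5),
               "sensitivity")
  expect_s3_class(membrane_params(8e-20, 1e-5, sensitivity = TRUE),
                  "membrane_params")
  expect_error(tube_geometry(-1, 1), "positive")
  expect_error(load_profile(-5, 50e-9, 100e-9), "inward")
  expect_error(load_profile(0, 700e-9, geometry = baseline_geometry()),
               "exceeds")
  expect_error(load_profile(0, 50e-9, 10e-9, baseline_geometry()),
               "inside")
  geom <- baseline_geometry()
  expect_error(
    axisym_shape(c(0, 1e-9, 2e-9), c(0, 1e-9, 2e-9),
                 c(230e-9, -1e-9, 230e-9), c(0, 0, 0), geom),
    "positive")
})

test_that("curvature matches the cylinder, sphere and catenoid oracles", {
  cyl <- make_cylinder_profile(baseline_geometry(), 201)
  cf <- curvature_profile(cyl)
  expect_equal(cf$c_m, rep(0, 201))
  expect_equal(cf$J, rep(1 / 230e-9, 201), tolerance = 1e-12)
  expect_equal(cf$J[100], 4.348e6, tolerance = 1e-3)

  rho <- 150e-9
  cap <- sphere_cap_shape(rho, n = 401)
  Jin <- curvature_profile(cap)$J[5:397]
  expect_equal(Jin, rep(2 / rho, length(Jin)), tolerance = 1e-4)

  a <- 100e-9
  cat <- catenoid_shape(a, n = 401)
  Jin <- curvature_profile(cat)$J[2:400]
  expect_lt(max(abs(Jin)), 1e-3 / a)

  bad <- cyl
  bad$r[5] <- NaN
  expect_error(curvature_profile(bad), "finite|positive")
})

test_that("area elements integrate to the analytic surface area", {
  geom <- baseline_geometry()
  cyl <- make_cylinder_profile(geom, 201)
  expect_equal(sum(curvature_profile(cyl)$dA), 2 * pi * geom$R * geom$L,
               tolerance = 1e-12)
  # spherical zone: area = 2*pi*rho*h with h the axial extent
  rho <- 150e-9
  cap <- sphere_cap_shape(rho, theta_max = 0.6, n = 801)
  h <- max(cap$z) - min(cap$z)
  expect_equal(sum(curvature_profile(cap)$dA), 2 * pi * rho * h,
               tolerance = 1e-4)
})

test_that("bending energy reproduces closed forms and scalings", {
  geom <- baseline_geometry()
  params <- baseline_params()
  cyl <- make_cylinder_profile(geom, 201)
  E0 <- pi * params$kappa * geom$L / geom$R     # 7.43e-19 J
  expect_equal(bending_energy(cyl, params), E0, tolerance = 0.005)
  expect_equal(E0, 7.43e-19, tolerance = 1e-3)

  half <- make_cylinder_profile(tube_geometry(115e-9, 680e-9), 201)
  expect_equal(bending_energy(half, params), 2 * E0, tolerance = 1e-10)

  a <- 100e-9
  cat <- catenoid_shape(a, n = 801)
  L_cat <- attr(cat, "geometry")$L
  expect_lt(bending_energy(cat, params),
            1e-3 * pi * params$kappa * L_cat / a)
})

test_that("bending energy is scale-free and second-order in the mesh", {
  params <- baseline_params()
  # invariance under rescaling all lengths at fixed kappa
  for (lam in c(0.5, 3)) {
    cap1 <- sphere_cap_shape(150e-9, n = 401)
    cap2 <- sphere_cap_shape(150e-9 * lam, n = 401)
    expect_equal(bending_energy(cap2, params),
                 bending_energy(cap1, params), tolerance = 1e-10)
  }
  # O(h^2) convergence on a curved shape: quadrupling n divides the
  # quadrature error by ~16
  rho <- 150e-9
  exact <- 0.5 * params$kappa * (2 / rho)^2 * 2 * pi * rho *
    (max(sphere_cap_shape(rho)$z) - min(sphere_cap_shape(rho)$z))
  err <- function(n) {
    cap <- sphere_cap_shape(rho, n = n)
    h <- max(cap$z) - min(cap$z)
    abs(bending_energy(cap, params) -
          0.5 * params$kappa * (2 / rho)^2 * 2 * pi * rho * h)
  }
  expect_gt(err(101) / err(401), 10)
})

test_that("strip volume follows the cylinder slice and its scalings", {
  geom <- baseline_geometry()
  cyl <- make_cylinder_profile(geom, 201)
  w <- 50e-9
  expect_equal(strip_volume(cyl, baseline_load(w = w)),
               pi * geom$R^2 * w, tolerance = 1e-12)
  expect_equal(pi * geom$R^2 * w, 8.31e-21, tolerance = 1e-3)
  # window covering the whole domain gives the full enclosed volume
  expect_equal(strip_volume(cyl, load_profile(0, geom$L, geom$L / 2, geom)),
               pi * geom$R^2 * geom$L, tolerance = 1e-12)
  # r scaled by 1/2 scales the strip volume by 1/4
  halfr <- make_cylinder_profile(tube_geometry(geom$R / 2, geom$L), 201)
  expect_equal(strip_volume(halfr, baseline_load(w = w)),
               pi * geom$R^2 * w / 4, tolerance = 1e-12)
  expect_error(strip_volume(cyl, load_profile(0, 50e-9, 5e-9)), "outside")
})

test_that("total energy assembles bending + pressure work", {
  geom <- baseline_geometry()
  params <- baseline_params()
  cyl <- make_cylinder_profile(geom, 201)

  e0 <- total_energy(cyl, params, baseline_load(P = 0))
  expect_identical(e0$total, e0$F_B + e0$W_P)
  expect_identical(e0$W_P, 0)

  e100 <- total_energy(cyl, params, baseline_load(P = 100))
  expect_equal(e100$total, 7.43e-19 + 100 * 8.31e-21, tolerance = 1e-3)

  e200 <- total_energy(cyl, params, baseline_load(P = 200))
  expect_equal(e200$W_P, 2 * e100$W_P, tolerance = 1e-14)
  expect_identical(e200$F_B, e100$F_B)
})

test_that("bending energy is invariant under rigid axial translation", {
  params <- baseline_params()
  cap <- sphere_cap_shape(150e-9, n = 201)
  shifted <- axisym_shape(cap$s, cap$z + 17e-9, cap$r, cap$psi,
                          attr(cap, "geometry"), validate = FALSE)
  expect_identical(bending_energy(shifted, params),
                   bending_energy(cap, params))
})

test_that("profile CSV round-trips through the documented format", {
  geom <- baseline_geometry()
  cyl <- make_cylinder_profile(geom, 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_shape_csv(cyl, path)
  header <- readLines(path, n = 1)
  expect_identical(
    header,
    "s_nm,z_nm,r_nm,psi_rad,c_m_per_um,c_c_per_um,J_per_um,dA_nm2")
  back <- read_shape_csv(path)
  expect_equal(back$r, cyl$r, tolerance = 1e-9)
  expect_equal(back$z, cyl$z, tolerance = 1e-9)
  expect_equal(attr(back, "geometry")$R, geom$R, tolerance = 1e-9)
})
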