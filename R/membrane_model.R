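#' Membrane material parameters
#'
#' Material constants of the lipid bilayer: the bending modulus `kappa`
#' (Joules) and the lateral tension `lateral_tension` (N/m). The baseline
#' mitochondrial model uses kappa = 8e-20 J, a value typical for a lipid
#' bilayer, and zero tension, so that the membrane area is free to change
#' and bending is the sole elastic contribution. Nonzero tension is
#' permitted only for explicitly flagged sensitivity scenarios.
#'
#' @param kappa Bending modulus in Joules; must be positive.
#' @param lateral_tension Lateral membrane tension in N/m (default 0).
#' @param sensitivity Set `TRUE` to allow a nonzero tension.
#' @return An object of class `membrane_params`.
#' @examples
#' membrane_params(kappa = 8e-20)
#' @export
membrane_params <- function(kappa, lateral_tension = 0, sensitivity = FALSE) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  if (kappa <= 0) stop("bending modulus `kappa` must be positive")
  stopifnot(is.numeric(lateral_tension), length(lateral_tension) == 1L,
            is.finite(lateral_tension))
  if (lateral_tension != 0 && !isTRUE(sensitivity)) {
    stop("nonzero `lateral_tension` is only allowed in sensitivity ",
         "scenarios; pass sensitivity = TRUE to opt in")
  }
  structure(list(kappa = kappa, lateral_tension = lateral_tension,
                 sensitivity = isTRUE(sensitivity)),
            class = "membrane_params")
}

#' Tube geometry
#'
#' Reference geometry of the modeled membrane segment: the undeformed tube
#' radius `R` and the fixed axial span `L`, both in meters. The baseline
#' mitochondrial constriction site is a tube of R = 230 nm and L = 680 nm
#' (L/R about 3).
#'
#' @param R Initial tube radius, m.
#' @param L Axial span of the modeled segment, m.
#' @return An object of class `tube_geometry`.
#' @examples
#' tube_geometry(R = 230e-9, L = 680e-9)
#' @export
tube_geometry <- function(R, L) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R),
            is.numeric(L), length(L) == 1L, is.finite(L))
  if (R <= 0) stop("tube radius `R` must be positive")
  if (L <= 0) stop("axial span `L` must be positive")
  structure(list(R = R, L = L), class = "tube_geometry")
}

#' Localized pressure load
#'
#' An inward pressure `P` (Pa) applied on a fixed axial window (the "strip")
#' of width `strip_width` centered at `strip_center`. The strip models the
#' zone where an ER tubule wraps the mitochondrion; its baseline width is
#' 50 nm, the thickness of a typical ER tubule. `P > 0` is inward,
#' i.e. constriction-favoring.
#'
#' @param P Pressure magnitude in Pa, `>= 0`.
#' @param strip_width Axial extent of the pressure window, m.
#' @param strip_center Axial coordinate of the window midpoint, m
#'   (default `L/2`).
#' @param geometry A [tube_geometry()] used to validate the window and to
#'   default the center.
#' @return An object of class `load_profile`.
#' @examples
#' geom <- tube_geometry(230e-9, 680e-9)
#' load_profile(P = 100, strip_width = 50e-9, geometry = geom)
#' @export
load_profile <- function(P, strip_width, strip_center = NULL,
                         geometry = NULL) {
  stopifnot(is.numeric(P), length(P) == 1L, is.finite(P))
  if (P < 0) stop("pressure `P` must be >= 0 (P > 0 means inward)")
  stopifnot(is.numeric(strip_width), length(strip_width) == 1L,
            is.finite(strip_width))
  if (strip_width <= 0) stop("`strip_width` must be positive")
  if (is.null(strip_center)) {
    if (is.null(geometry)) stop("either `strip_center` or `geometry` ",
                                "(for the default L/2) must be given")
    strip_center <- geometry$L / 2
  }
  if (!is.null(geometry)) {
    if (strip_width > geometry$L)
      stop("`strip_width` exceeds the axial span L")
    if (strip_center - strip_width / 2 < 0 ||
        strip_center + strip_width / 2 > geometry$L)
      stop("the pressure strip must lie fully inside [0, L]")
  }
  structure(list(P = P, strip_width = strip_width,
                 strip_center = strip_center),
            class = "load_profile")
}

#' Discretized axisymmetric meridian profile
#'
#' An ordered set of meridian samples (arc coordinate `s`, axial `z`,
#' radial `r`, tangent angle `psi`), all in SI units, whose revolution
#' about the z-axis generates the tube surface. Sign conventions:
#' `dz/ds = cos(psi)`, `dr/ds = -sin(psi)`, so a straight cylinder has
#' `psi == 0` everywhere and positive `psi` means the profile is heading
#' inward (constricting) with increasing `s`. Both ends are clamped to the
#' reference radius with the meridian parallel to the axis
#' (radius `R`, `psi = 0`).
#'
#' @param s,z,r,psi Numeric vectors of equal length: arc coordinate, axial
#'   coordinate, radius, tangent angle (radians).
#' @param geometry The owning [tube_geometry()].
#' @param validate Check the boundary clamps and discrete consistency.
#' @return An object of class `axisym_shape`: a data frame of nodes with
#'   the geometry attached as an attribute.
#' @seealso [make_cylinder_profile()], [curvature_profile()]
#' @export
axisym_shape <- function(s, z, r, psi, geometry, validate = TRUE) {
  n <- length(s)
  stopifnot(n >= 3L, length(z) == n, length(r) == n, length(psi) == n)
  if (!all(is.finite(s)) || !all(is.finite(z)) || !all(is.finite(r)) ||
      !all(is.finite(psi)))
    stop("shape coordinates must all be finite")
  if (any(r <= 0)) stop("radial coordinate must be positive at every node")
  if (is.unsorted(s, strictly = TRUE))
    stop("arc coordinate `s` must be strictly increasing")
  obj <- structure(
    data.frame(s = s, z = z, r = r, psi = psi),
    geometry = geometry,
    class = c("axisym_shape", "data.frame"))
  if (validate) validate_axisym_shape(obj)
  obj
}

#' @rdname axisym_shape
#' @param shape An `axisym_shape`.
#' @param tol Relative tolerance for the discrete consistency checks.
#' @export
validate_axisym_shape <- function(shape, tol = 1e-2) {
  geom <- attr(shape, "geometry")
  n <- nrow(shape)
  R <- geom$R
  if (abs(shape$r[1] - R) > 1e-9 * R || abs(shape$r[n] - R) > 1e-9 * R)
    stop("boundary clamp violated: r(first) and r(last) must equal R")
  if (abs(shape$psi[1]) > 1e-9 || abs(shape$psi[n]) > 1e-9)
    stop("boundary clamp violated: psi must vanish at both ends")
  if (abs(shape$z[1]) > 1e-9 * geom$L ||
      abs(shape$z[n] - geom$L) > 1e-6 * geom$L)
    stop("axial closure violated: z must run from 0 to L")
  # discrete consistency dz/ds = cos(psi), dr/ds = -sin(psi) at midpoints
  ds <- diff(shape$s)
  mid_psi <- (shape$psi[-1] + shape$psi[-n]) / 2
  err_z <- max(abs(diff(shape$z) / ds - cos(mid_psi)))
  err_r <- max(abs(diff(shape$r) / ds + sin(mid_psi)))
  h <- max(ds) / R
  if (err_z > tol + 10 * h^2 || err_r > tol + 10 * h^2)
    stop("discrete tangent consistency (dz/ds = cos psi, dr/ds = -sin psi)",
         " violated beyond the discretization tolerance")
  invisible(shape)
}

#' @export
print.axisym_shape <- function(x, ...) {
  geom <- attr(x, "geometry")
  cat(sprintf(
    "<axisym_shape> %d nodes, R = %.4g nm, L = %.4g nm, r_min = %.4g nm\n",
    nrow(x), geom$R * 1e9, geom$L * 1e9, min(x$r) * 1e9))
  invisible(x)
}

#' Undeformed cylinder profile
#'
#' The reference configuration: a straight cylinder of radius `R` spanning
#' `[0, L]`, sampled at `n_nodes` uniformly spaced nodes (`psi == 0`, so the
#' arc coordinate coincides with `z`).
#'
#' @param geometry A [tube_geometry()].
#' @param n_nodes Number of meridian nodes; odd and at least 11, so that a
#'   node sits exactly at the strip center when the strip is centered.
#' @return An [axisym_shape()].
#' @examples
#' cyl <- make_cylinder_profile(tube_geometry(230e-9, 680e-9), 201)
#' range(cyl$r)
#' @export
make_cylinder_profile <- function(geometry, n_nodes = 201L) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 11L)
    stop("`n_nodes` must be at least 11 to resolve the strip region")
  if (n_nodes %% 2L == 0L)
    stop("`n_nodes` must be odd so that a node sits at the strip center")
  z <- seq(0, geometry$L, length.out = n_nodes)
  axisym_shape(s = z, z = z, r = rep(geometry$R, n_nodes),
               psi = rep(0, n_nodes), geometry = geometry,
               validate = FALSE)
}

#' Principal curvatures and area elements of a profile
#'
#' Computes, per node, the meridional principal curvature `c_m = dpsi/ds`
#' (three-point finite differences, one-sided at the clamped ends), the
#' circumferential curvature `c_c = cos(psi)/r` of the surface of
#' revolution, the total curvature `J = c_m + c_c`, and the trapezoidal
#' area element `dA = 2*pi*r*ds` of the surface ring attached to the node.
#' Second-order accurate in the node spacing on smooth shapes. Under the
#' package's sign convention a cylinder of radius R has `J = 1/R`, a sphere
#' of radius rho has `J = 2/rho`, and a catenoid has `J = 0`.
#'
#' @param shape An [axisym_shape()].
#' @return A data frame with columns `c_m`, `c_c`, `J` (1/m) and `dA` (m^2),
#'   one row per node.
#' @examples
#' cyl <- make_cylinder_profile(tube_geometry(230e-9, 680e-9), 201)
#' head(curvature_profile(cyl)$J) # == 1/230e-9
#' @export
curvature_profile <- function(shape) {
  if (!inherits(shape, "axisym_shape")) stop("`shape` must be an axisym_shape")
  if (!all(is.finite(unlist(shape[c("s", "z", "r", "psi")]))))
    stop("non-finite coordinates in shape")
  if (any(shape$r <= 0)) stop("radial coordinate must be positive")
  s <- shape$s; r <- shape$r; psi <- shape$psi
  n <- length(s)
  c_m <- numeric(n)
  # second-order non-uniform three-point stencil for dpsi/ds
  for (i in 2:(n - 1)) {
    h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
    c_m[i] <- (-h2 / (h1 * (h1 + h2))) * psi[i - 1] +
      ((h2 - h1) / (h1 * h2)) * psi[i] +
      (h1 / (h2 * (h1 + h2))) * psi[i + 1]
  }
  c_m[1] <- (psi[2] - psi[1]) / (s[2] - s[1])
  c_m[n] <- (psi[n] - psi[n - 1]) / (s[n] - s[n - 1])
  c_c <- cos(psi) / r
  ds <- diff(s)
  w <- c(ds[1] / 2, (ds[-1] + ds[-(n - 1)]) / 2, ds[n - 1] / 2)
  data.frame(c_m = c_m, c_c = c_c, J = c_m + c_c, dA = 2 * pi * r * w)
}

#' Helfrich bending energy of a profile
#'
#' Discrete quadrature of the bending energy `F_B = integral of
#' (kappa/2) J^2 dA` over the surface of revolution, with `J` the total
#' curvature from [curvature_profile()]. For the undeformed cylinder the
#' closed form is `pi * kappa * L / R`.
#'
#' @param shape An [axisym_shape()].
#' @param params A [membrane_params()].
#' @return Bending energy in Joules (non-negative).
#' @examples
#' cyl <- make_cylinder_profile(tube_geometry(230e-9, 680e-9), 201)
#' bending_energy(cyl, membrane_params(8e-20)) # pi*kappa*L/R = 7.43e-19 J
#' @export
bending_energy <- function(shape, params) {
  cf <- curvature_profile(shape)
  sum(0.5 * params$kappa * cf$J^2 * cf$dA)
}

#' Volume enclosed under the pressure strip
#'
#' The work-conjugate volume of the strip load: `V = pi * integral of
#' r(z)^2 dz` over the fixed axial window `[center - w/2, center + w/2]`,
#' evaluated as a signed line integral along the meridian so overhanging
#' profiles are handled. For a cylinder this is `pi R^2 w`.
#'
#' @param shape An [axisym_shape()].
#' @param load A [load_profile()].
#' @return Volume in m^3.
#' @examples
#' geom <- tube_geometry(230e-9, 680e-9)
#' cyl <- make_cylinder_profile(geom, 201)
#' strip_volume(cyl, load_profile(0, 50e-9, geometry = geom))
#' @export
strip_volume <- function(shape, load) {
  geom <- attr(shape, "geometry")
  za <- load$strip_center - load$strip_width / 2
  zb <- load$strip_center + load$strip_width / 2
  if (za < -1e-12 * geom$L || zb > geom$L * (1 + 1e-12))
    stop("the pressure strip lies outside the modeled axial span [0, L]")
  z <- shape$z; r <- shape$r
  n <- length(z)
  v <- 0
  for (i in seq_len(n - 1)) {
    z0 <- z[i]; z1 <- z[i + 1]; r0 <- r[i]; dr <- r[i + 1] - r[i]
    dz <- z1 - z0
    if (dz == 0) next
    tt <- sort(c((za - z0) / dz, (zb - z0) / dz))
    t0 <- max(0, tt[1]); t1 <- min(1, tt[2])
    if (t1 <= t0) next
    q2 <- r0^2 * (t1 - t0) + r0 * dr * (t1^2 - t0^2) +
      dr^2 * (t1^3 - t0^3) / 3
    v <- v + dz * q2
  }
  pi * v
}

#' Deformed membrane area within the pressure strip
#'
#' Meridian-arc integral `A = integral of 2*pi*r ds` restricted to nodes
#' whose axial position lies inside the strip window; the area actually
#' pushed on by the load. For a cylinder this is `2 pi R w`.
#'
#' @inheritParams strip_volume
#' @return Area in m^2.
#' @export
strip_area <- function(shape, load) {
  za <- load$strip_center - load$strip_width / 2
  zb <- load$strip_center + load$strip_width / 2
  z <- shape$z; r <- shape$r; s <- shape$s
  n <- length(z)
  a <- 0
  for (i in seq_len(n - 1)) {
    z0 <- z[i]; z1 <- z[i + 1]; r0 <- r[i]; dr <- r[i + 1] - r[i]
    ds <- s[i + 1] - s[i]
    dz <- z1 - z0
    if (dz == 0) {
      if (z0 > za && z0 < zb) a <- a + (r0 + dr / 2) * ds
      next
    }
    tt <- sort(c((za - z0) / dz, (zb - z0) / dz))
    t0 <- max(0, tt[1]); t1 <- min(1, tt[2])
    if (t1 <= t0) next
    a <- a + ds * (r0 * (t1 - t0) + 0.5 * dr * (t1^2 - t0^2))
  }
  2 * pi * a
}

#' Total energy under a localized pressure load
#'
#' The functional the equilibrium solver minimizes: bending energy plus the
#' pressure work term `W_P = P * V_strip` (plus a lateral-tension term
#' `sigma * A` when a sensitivity scenario sets a nonzero tension).
#' Minimizing the total at `P > 0` drives the strip region inward.
#'
#' @param shape An [axisym_shape()].
#' @param params A [membrane_params()].
#' @param load A [load_profile()].
#' @return An object of class `energy_breakdown`: list with `F_B`, `W_P`,
#'   `F_T` (tension term, 0 at zero tension) and `total`, all in Joules.
#' @export
total_energy <- function(shape, params, load) {
  F_B <- bending_energy(shape, params)
  W_P <- load$P * strip_volume(shape, load)
  F_T <- if (params$lateral_tension != 0) {
    cf <- curvature_profile(shape)
    params$lateral_tension * sum(cf$dA)
  } else 0
  structure(list(F_B = F_B, W_P = W_P, F_T = F_T,
                 total = F_B + W_P + F_T),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> F_B = %.4g J, W_P = %.4g J, total = %.4g J\n",
              x$F_B, x$W_P, x$total))
  invisible(x)
}

#' Write / read a meridian profile as CSV
#'
#' The profile file carries one row per node with lengths in nm, curvatures
#' in 1/um and ring areas in nm^2, header
#' `s_nm,z_nm,r_nm,psi_rad,c_m_per_um,c_c_per_um,J_per_um,dA_nm2`.
#'
#' @param shape An [axisym_shape()].
#' @param path Output file path.
#' @return `write_shape_csv` returns `path` invisibly; `read_shape_csv`
#'   returns the [axisym_shape()] (curvature columns are recomputed, not
#'   trusted).
#' @export
write_shape_csv <- function(shape, path) {
  cf <- curvature_profile(shape)
  df <- data.frame(
    s_nm = fmt_num(shape$s * 1e9),
    z_nm = fmt_num(shape$z * 1e9),
    r_nm = fmt_num(shape$r * 1e9),
    psi_rad = fmt_num(shape$psi),
    c_m_per_um = fmt_num(cf$c_m * 1e-6),
    c_c_per_um = fmt_num(cf$c_c * 1e-6),
    J_per_um = fmt_num(cf$J * 1e-6),
    dA_nm2 = fmt_num(cf$dA * 1e18))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shape_csv
#' @param geometry The owning [tube_geometry()]; if `NULL` it is inferred
#'   from the boundary radius and axial span of the file.
#' @export
read_shape_csv <- function(path, geometry = NULL) {
  df <- utils::read.csv(path)
  need <- c("s_nm", "z_nm", "r_nm", "psi_rad")
  if (!all(need %in% names(df)))
    stop("profile CSV must carry columns ", paste(need, collapse = ", "))
  if (is.null(geometry))
    geometry <- tube_geometry(R = df$r_nm[1] * 1e-9,
                              L = df$z_nm[nrow(df)] * 1e-9)
  axisym_shape(s = df$s_nm * 1e-9, z = df$z_nm * 1e-9, r = df$r_nm * 1e-9,
               psi = df$psi_rad, geometry = geometry)
}

# deterministic, locale-independent number formatting for file output
fmt_num <- function(x) {
  sprintf("%.10g", x)
}
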