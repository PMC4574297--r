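# run fn with a locally seeded, explicitly specified RNG (Mersenne-Twister
# + inversion), restoring the caller's RNG state afterwards
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  fn()
}

#' Simulation scenario
#'
#' Bundles everything a constriction run needs: membrane parameters, tube
#' geometry, the strip load template (pressure unset), the per-filament
#' force, the target narrowest radii, and a seed.
#'
#' @param label Free-text scenario name.
#' @param params A [membrane_params()].
#' @param geometry A [tube_geometry()].
#' @param load_template A [load_profile()] whose `P` is ignored.
#' @param force_params A [force_params()].
#' @param r_targets Target narrowest radii, m, each in `(0, R]`.
#' @param seed Integer seed.
#' @return An object of class `scenario`.
#' @seealso [baseline_scenario()], [random_scenario()],
#'   [dimensionless_twin()]
#' @export
scenario <- function(label, params, geometry, load_template, force_params,
                     r_targets, seed = 1L) {
  stopifnot(inherits(params, "membrane_params"),
            inherits(geometry, "tube_geometry"),
            inherits(load_template, "load_profile"),
            inherits(force_params, "force_params"))
  if (!all(r_targets > 0 & r_targets <= geometry$R))
    stop("all `r_targets` must lie in (0, R]")
  # revalidate the strip against this geometry
  load_template <- load_profile(0, load_template$strip_width,
                                load_template$strip_center, geometry)
  structure(list(label = as.character(label), params = params,
                 geometry = geometry, load_template = load_template,
                 force_params = force_params,
                 r_targets = sort(r_targets, decreasing = TRUE),
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    paste0("<scenario> \"%s\": R = %.4g nm, L = %.4g nm, w = %.4g nm, ",
           "kappa = %.3g J, targets = %s nm\n"),
    x$label, x$geometry$R * 1e9, x$geometry$L * 1e9,
    x$load_template$strip_width * 1e9, x$params$kappa,
    paste(signif(x$r_targets * 1e9, 4), collapse = "/")))
  invisible(x)
}

#' The baseline mitochondrial constriction scenario
#'
#' The parameter set of the mitochondrial constriction-site model: bending
#' modulus 8e-20 J (typical for a lipid bilayer) at zero lateral tension,
#' a tube of initial radius 230 nm and length 680 nm, a centered 50-nm
#' pressure strip (the width of a typical ER tubule), 1 pN per
#' polymerizing actin filament, and the three observed constriction
#' depths: narrowest radii 145, 110 and 65 nm.
#'
#' @return A [scenario()].
#' @examples
#' baseline_scenario()
#' @export
baseline_scenario <- function() {
  geom <- tube_geometry(R = 230e-9, L = 680e-9)
  scenario(
    label = "baseline",
    params = membrane_params(kappa = 8e-20, lateral_tension = 0),
    geometry = geom,
    load_template = load_profile(0, strip_width = 50e-9, geometry = geom),
    force_params = force_params(f1 = 1e-12),
    r_targets = c(145e-9, 110e-9, 65e-9),
    seed = 20230815L)
}

#' Default parameter ranges for randomized scenarios
#'
#' Uniform sampling bounds bracketing the baseline values: R in
#' `[100, 400]` nm, L/R in `[2, 5]`, strip width in `[25, 100]` nm, kappa
#' in `[2, 20] x 1e-20` J, and target radii as fractions of R in
#' `[0.3, 0.9]`.
#'
#' @return A named list of `c(lo, hi)` ranges.
#' @export
default_scenario_ranges <- function() {
  list(R_nm = c(100, 400),
       L_over_R = c(2, 5),
       w_nm = c(25, 100),
       kappa_J = c(2e-20, 20e-20),
       target_frac = c(0.3, 0.9),
       n_targets = 3L)
}

#' Randomized scenario
#'
#' Draws a physically valid scenario uniformly within the given ranges.
#' Deterministic in `seed`: the same seed always yields the identical
#' scenario (Mersenne-Twister, inversion sampling; the caller's RNG state
#' is untouched).
#'
#' @param seed Integer seed.
#' @param ranges A list as from [default_scenario_ranges()].
#' @return A [scenario()].
#' @examples
#' identical(random_scenario(7), random_scenario(7))
#' @export
random_scenario <- function(seed, ranges = default_scenario_ranges()) {
  need <- names(default_scenario_ranges())
  if (!all(need %in% names(ranges)))
    stop("`ranges` must carry ", paste(need, collapse = ", "))
  bad <- function(rg) length(rg) != 2 || any(!is.finite(rg)) ||
    rg[1] > rg[2] || rg[1] <= 0
  for (nm in setdiff(need, "n_targets"))
    if (bad(ranges[[nm]])) stop("invalid range for `", nm, "`")
  if (ranges$target_frac[2] > 1)
    stop("`target_frac` must stay within (0, 1]")
  .with_seed(seed, function() {
    R <- runif(1, ranges$R_nm[1], ranges$R_nm[2]) * 1e-9
    L <- R * runif(1, ranges$L_over_R[1], ranges$L_over_R[2])
    w <- runif(1, ranges$w_nm[1], ranges$w_nm[2]) * 1e-9
    w <- min(w, 0.9 * L)  # keep the strip inside the tube for short tubes
    kappa <- runif(1, ranges$kappa_J[1], ranges$kappa_J[2])
    fr <- sort(runif(ranges$n_targets, ranges$target_frac[1],
                     ranges$target_frac[2]), decreasing = TRUE)
    geom <- tube_geometry(R, L)
    scenario(
      label = sprintf("random (seed %d)", as.integer(seed)),
      params = membrane_params(kappa),
      geometry = geom,
      load_template = load_profile(0, w, geometry = geom),
      force_params = force_params(1e-12),
      r_targets = fr * R,
      seed = as.integer(seed))
  })
}

#' Rescaled dimensionless twin of a scenario
#'
#' Multiplies every length by `length_scale` and the bending modulus by
#' `kappa_scale`, preserving the shape ratios L/R, w/R and r_targets/R
#' exactly. Twins trace identical `r/R` versus `P R^3/(2 kappa)` curves:
#' the Helfrich energy is scale-free, so the dimensionless
#' pressure-constriction relation depends only on the shape ratios.
#'
#' @param base A [scenario()].
#' @param length_scale Positive factor applied to all lengths.
#' @param kappa_scale Positive factor applied to the bending modulus.
#' @return A [scenario()].
#' @examples
#' tw <- dimensionless_twin(baseline_scenario(), 2, 1)
#' tw$geometry$R  # 460 nm
#' @export
dimensionless_twin <- function(base, length_scale, kappa_scale = 1) {
  stopifnot(inherits(base, "scenario"),
            length_scale > 0, kappa_scale > 0)
  geom <- tube_geometry(base$geometry$R * length_scale,
                        base$geometry$L * length_scale)
  scenario(
    label = sprintf("%s [x%g lengths, x%g kappa]", base$label,
                    length_scale, kappa_scale),
    params = membrane_params(base$params$kappa * kappa_scale,
                             base$params$lateral_tension /
                               length_scale^2 * kappa_scale,
                             sensitivity = base$params$sensitivity),
    geometry = geom,
    load_template = load_profile(
      0, base$load_template$strip_width * length_scale,
      base$load_template$strip_center * length_scale, geom),
    force_params = base$force_params,
    r_targets = base$r_targets * length_scale,
    seed = base$seed)
}

#' Smooth seeded perturbation of a profile
#'
#' Adds a random radial perturbation built from a truncated sine series
#' (axial modes 1-5, each windowed by `sin(pi z / L)` so both the radial
#' clamp and the parallel-to-axis clamp at the tube ends are preserved
#' exactly). Used to probe the robustness of the relaxation basin.
#' Deterministic in `seed`.
#'
#' @param shape An [axisym_shape()].
#' @param amplitude Peak radial perturbation as a fraction of R; must be
#'   `< 0.2`.
#' @param seed Integer seed.
#' @return A perturbed [axisym_shape()].
#' @export
perturb_profile <- function(shape, amplitude, seed = 1L) {
  stopifnot(inherits(shape, "axisym_shape"), amplitude >= 0)
  if (amplitude >= 0.2)
    stop("`amplitude` must be below 0.2 (fraction of R)")
  if (amplitude == 0) return(shape)
  geom <- attr(shape, "geometry")
  L <- geom$L; R <- geom$R
  coef <- .with_seed(seed, function() runif(5, -1, 1))
  z <- shape$z
  base <- sin(pi * z / L)
  dbase <- (pi / L) * cos(pi * z / L)
  dr <- numeric(length(z)); ddr_dz <- numeric(length(z))
  for (k in 1:5) {
    dr <- dr + coef[k] * base * sin(k * pi * z / L)
    ddr_dz <- ddr_dz + coef[k] * (dbase * sin(k * pi * z / L) +
                                    base * (k * pi / L) * cos(k * pi * z / L))
  }
  scale <- amplitude * R / max(abs(dr), .Machine$double.eps)
  r_new <- shape$r + scale * dr
  if (any(r_new <= 0))
    stop("perturbation would drive the radius non-positive")
  # slope of the perturbed meridian against z, then rebuild (s, psi)
  dr_dz_old <- -tan(shape$psi)
  dr_dz <- dr_dz_old + scale * ddr_dz
  psi_new <- -atan(dr_dz)
  ds <- sqrt(diff(z)^2 + diff(r_new)^2)
  s_new <- c(0, cumsum(ds)) + shape$s[1]
  axisym_shape(s = s_new, z = z, r = r_new, psi = psi_new,
               geometry = geom, validate = FALSE)
}

#' Serialize / deserialize a scenario as JSON
#'
#' The document mirrors the scenario fields in interface units (nm, pN,
#' Joule) and carries a `schema_version` field.
#'
#' @param x A [scenario()].
#' @param path JSON file path.
#' @return `scenario_to_json` returns `path` invisibly;
#'   `scenario_from_json` returns the [scenario()].
#' @export
scenario_to_json <- function(x, path) {
  stopifnot(inherits(x, "scenario"))
  doc <- list(
    schema_version = 1L,
    label = x$label,
    kappa_J = x$params$kappa,
    lateral_tension_N_per_m = x$params$lateral_tension,
    R_nm = x$geometry$R * 1e9,
    L_nm = x$geometry$L * 1e9,
    strip_width_nm = x$load_template$strip_width * 1e9,
    strip_center_nm = x$load_template$strip_center * 1e9,
    f1_pN = x$force_params$f1 * 1e12,
    r_targets_nm = x$r_targets * 1e9,
    seed = x$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname scenario_to_json
#' @export
scenario_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("schema_version", "label", "kappa_J", "R_nm", "L_nm",
            "strip_width_nm", "f1_pN", "r_targets_nm", "seed")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("scenario JSON is missing fields: ", paste(miss, collapse = ", "))
  if (doc$schema_version != 1L)
    stop("unsupported scenario schema_version: ", doc$schema_version)
  geom <- tube_geometry(doc$R_nm * 1e-9, doc$L_nm * 1e-9)
  tension <- if (is.null(doc$lateral_tension_N_per_m)) 0 else
    doc$lateral_tension_N_per_m
  center <- if (is.null(doc$strip_center_nm)) NULL else
    doc$strip_center_nm * 1e-9
  scenario(
    label = doc$label,
    params = membrane_params(doc$kappa_J, tension,
                             sensitivity = tension != 0),
    geometry = geom,
    load_template = load_profile(0, doc$strip_width_nm * 1e-9, center,
                                 geom),
    force_params = force_params(doc$f1_pN * 1e-12),
    r_targets = doc$r_targets_nm * 1e-9,
    seed = doc$seed)
}
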