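#' Simulation configuration
#'
#' Collects every parameter of the forward simulator: the radial HFL
#' thickness model, the thickness-to-retardance coupling, the residual
#' corneal retarder, noise levels, and the imaging geometry of both
#' instruments. Defaults describe a healthy adult macula imaged with a
#' 20x40-degree SLP raster and 30-degree OCT b-scans; see the package
#' vignette for the provenance of each default.
#'
#' @param t_max Peak HFL thickness (um).
#' @param r_peak Eccentricity of the thickness peak (deg).
#' @param shape Radial-profile shape exponent (dimensionless); the profile
#'   is `t_max * (r/r_peak)^shape * exp(shape * (1 - r/r_peak))`.
#' @param meridian_mod Fractional thickness modulation for the temporal,
#'   superior, nasal, inferior meridians (4 values).
#' @param coupling Single-pass retardance per unit thickness (nm/um).
#' @param corneal_residual_nm Mean residual corneal retardance after fixed
#'   compensation (nm, single pass). The fixed compensator is a 60-nm
#'   element with slow axis 15 degrees nasally downward, so the residual
#'   defaults to that magnitude and axis.
#' @param corneal_axis_deg Residual corneal slow axis (deg, nasally
#'   downward positive).
#' @param corneal_between_subject_sd SD of the residual magnitude across
#'   subjects (nm); the mechanism behind the larger between-subject
#'   variability of fixed-compensation imaging.
#' @param noise_sd Additive per-pixel Gaussian intensity noise SD.
#' @param baseline_sd SD of a per-subject additive intensity offset
#'   (detector/illumination baseline differences between sessions).
#' @param thickness_cv Between-subject coefficient of variation of peak
#'   thickness (fraction).
#' @param gain Intensity units per nm of net retardance.
#' @param fov_deg SLP field of view, c(vertical, horizontal) degrees.
#' @param deg_per_px SLP angular pixel pitch (deg).
#' @param trace_jitter_px SD of Gaussian depth jitter on simulated OCT
#'   boundary traces (px); stands in for manual-segmentation error.
#' @param center_jitter_px Maximum fixation offset of the true foveal
#'   center from the image center (px, uniform).
#' @param oct_fov_deg Lateral extent of an OCT b-scan (deg).
#' @param oct_n_cols A-scans per b-scan.
#' @param axial_um_per_px OCT axial scale (um/px).
#' @param seed Default integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_max = 45,
                       r_peak = 2,
                       shape = 2,
                       meridian_mod = c(0, 0, 0, 0),
                       coupling = 0.45,
                       corneal_residual_nm = 60,
                       corneal_axis_deg = 15,
                       corneal_between_subject_sd = 28,
                       noise_sd = 2,
                       baseline_sd = 1,
                       thickness_cv = 0.10,
                       gain = 2,
                       fov_deg = c(20, 40),
                       deg_per_px = 20 / 256,
                       trace_jitter_px = 0.5,
                       center_jitter_px = 5,
                       oct_fov_deg = 30,
                       oct_n_cols = 1536,
                       axial_um_per_px = 3.87,
                       seed = 1L) {
  cfg <- list(
    t_max = t_max, r_peak = r_peak, shape = shape,
    meridian_mod = meridian_mod, coupling = coupling,
    corneal_residual_nm = corneal_residual_nm,
    corneal_axis_deg = corneal_axis_deg,
    corneal_between_subject_sd = corneal_between_subject_sd,
    noise_sd = noise_sd, baseline_sd = baseline_sd,
    thickness_cv = thickness_cv, gain = gain,
    fov_deg = fov_deg, deg_per_px = deg_per_px,
    trace_jitter_px = trace_jitter_px,
    center_jitter_px = center_jitter_px,
    oct_fov_deg = oct_fov_deg, oct_n_cols = as.integer(oct_n_cols),
    axial_um_per_px = axial_um_per_px,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$t_max > 0, cfg$r_peak > 0, cfg$shape > 0,
    length(cfg$meridian_mod) == 4, all(is.finite(cfg$meridian_mod)),
    cfg$coupling >= 0, cfg$corneal_residual_nm >= 0,
    cfg$corneal_between_subject_sd >= 0,
    cfg$noise_sd >= 0, cfg$baseline_sd >= 0, cfg$thickness_cv >= 0,
    cfg$gain > 0, length(cfg$fov_deg) == 2, all(cfg$fov_deg > 0),
    cfg$deg_per_px > 0, cfg$trace_jitter_px >= 0,
    cfg$center_jitter_px >= 0, cfg$oct_fov_deg > 0, cfg$oct_n_cols >= 16,
    cfg$axial_um_per_px > 0)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Forward-simulation configuration\n")
  cat(sprintf("  thickness: peak %.1f um at %.2f deg (shape %.1f)\n",
              x$t_max, x$r_peak, x$shape))
  cat(sprintf("  coupling %.3f nm/um; corneal residual %.1f nm @ %.1f deg (SD %.1f nm)\n",
              x$coupling, x$corneal_residual_nm, x$corneal_axis_deg,
              x$corneal_between_subject_sd))
  cat(sprintf("  SLP %gx%g deg, %.4f deg/px, gain %.2f, noise SD %.2f\n",
              x$fov_deg[1], x$fov_deg[2], x$deg_per_px, x$gain, x$noise_sd))
  cat(sprintf("  OCT %g deg, %d a-scans, axial %.2f um/px, jitter SD %.2f px\n",
              x$oct_fov_deg, x$oct_n_cols, x$axial_um_per_px,
              x$trace_jitter_px))
  invisible(x)
}

## Map dimensions implied by the SLP geometry.
map_dims <- function(cfg) {
  c(round(cfg$fov_deg[1] / cfg$deg_per_px),
    round(cfg$fov_deg[2] / cfg$deg_per_px))
}

## OCT lateral scale (um/px) implied by the scan geometry.
lateral_um_per_px <- function(cfg) {
  cfg$oct_fov_deg * UM_PER_DEG / cfg$oct_n_cols
}
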