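## Forward simulator: SLP retardation maps and directional-OCT boundary
## traces for virtual subjects with known ground truth.

## Azimuth convention (right eye, en-face): 0 = nasal (+x, image right),
## pi/2 = superior (+y, image up), pi = temporal, 3*pi/2 = inferior.
## meridian_mod is ordered (temporal, superior, nasal, inferior).
MERIDIANS <- c("temporal", "superior", "nasal", "inferior")
MERIDIAN_AZ <- c(temporal = pi, superior = pi / 2, nasal = 0,
                 inferior = 3 * pi / 2)

#' Radial HFL thickness model
#'
#' Gamma-shaped radial profile: zero at the foveal center, rising to a
#' unique maximum `t_max` at `r_peak` (2 degrees by default, where both HFL
#' thickness and macular retardance peak in healthy adults), then falling.
#'
#' @param config A [sim_config()].
#' @param r Eccentricity in degrees (vector, >= 0).
#' @param meridian_index Optional meridian 0..3 (temporal, superior, nasal,
#'   inferior); applies that meridian's fractional modulation.
#' @return Thickness in um.
#' @export
#' @examples
#' cfg <- sim_config()
#' hfl_thickness_profile(cfg, c(0, 1, 2, 3))
hfl_thickness_profile <- function(config, r, meridian_index = NULL) {
  if (any(r < 0)) stop("eccentricity must be non-negative")
  t <- radial_thickness(config, r)
  if (!is.null(meridian_index)) {
    stopifnot(length(meridian_index) == 1, meridian_index %in% 0:3)
    t <- t * (1 + config$meridian_mod[meridian_index + 1])
  }
  t
}

radial_thickness <- function(cfg, r) {
  u <- r / cfg$r_peak
  cfg$t_max * u^cfg$shape * exp(cfg$shape * (1 - u))
}

## Periodic linear interpolation of the per-meridian modulation over
## azimuth; identically zero modulation short-circuits.
meridian_mod_at <- function(cfg, az) {
  if (all(cfg$meridian_mod == 0)) return(0)
  m <- cfg$meridian_mod # (t, s, n, i)
  nodes_x <- c(0, pi / 2, pi, 3 * pi / 2, 2 * pi)
  nodes_y <- c(m[3], m[2], m[1], m[4], m[3])
  stats::approx(nodes_x, nodes_y, xout = az %% (2 * pi))$y
}

## Deterministic derived seed for independent noise streams.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 12345 + 1) %%
               2147483629)
}

## Per-subject latent parameters, drawn reproducibly from the subject seed.
## The SLP map and all four OCT scans of one subject derive from the same
## draws, so thickness is consistent across modalities.
subject_params <- function(cfg, subject_seed) {
  set.seed(as.integer(subject_seed %% 2147483629))
  list(
    t_scale = max(0.2, 1 + cfg$thickness_cv * stats::rnorm(1)),
    corneal_nm = max(0, stats::rnorm(1, cfg$corneal_residual_nm,
                                     cfg$corneal_between_subject_sd)),
    baseline = stats::rnorm(1, 0, cfg$baseline_sd),
    center_jitter = stats::runif(2, -cfg$center_jitter_px,
                                 cfg$center_jitter_px),
    oct_col_jitter = as.integer(round(stats::runif(
      1, -cfg$center_jitter_px, cfg$center_jitter_px))),
    slp_quality = round(stats::rnorm(1, 9, 0.4), 1),
    oct_quality = round(stats::rnorm(4, 30, 2), 1))
}

#' Simulate an SLP phase-retardation map
#'
#' Per pixel, the HFL contributes a single-pass retardance
#' `coupling * thickness` with slow axis along the radial azimuth. Under
#' fixed corneal compensation the HFL retarder is composed (two-retarder
#' Jones composition) with the subject's residual corneal retarder, which
#' produces the macular cross; under variable compensation the residual is
#' zero and the map is an annulus. Intensity is
#' `clip(gain * retardance_nm + baseline + noise, 0, 255)` quantized to
#' 8 bits.
#'
#' @param config A [sim_config()].
#' @param mode `"fixed"` or `"variable"` corneal compensation.
#' @param subject_seed Integer seed identifying the virtual subject.
#' @return A list with `map` (a [retardation_map()]) and `truth` (list with
#'   the true center, the noise-free retardance map in nm, per-meridian
#'   ground-truth thickness on a dense radial grid, and the subject draws).
#' @export
simulate_retardation_map <- function(config, mode = c("fixed", "variable"),
                                     subject_seed = config$seed) {
  mode <- match.arg(mode)
  cfg <- config
  sp <- subject_params(cfg, subject_seed)
  dims <- map_dims(cfg)
  nr <- dims[1]
  nc <- dims[2]
  center <- c((nr + 1) / 2, (nc + 1) / 2) + sp$center_jitter
  margin_deg <- (min(center[1] - 1, nr - center[1],
                     center[2] - 1, nc - center[2])) * cfg$deg_per_px
  if (margin_deg < 3.2) {
    stop("field of view too small for the 3-degree analysis radius")
  }

  x <- matrix((seq_len(nc) - center[2]) * cfg$deg_per_px, nr, nc,
              byrow = TRUE)
  y <- matrix((center[1] - seq_len(nr)) * cfg$deg_per_px, nr, nc)
  r <- sqrt(x^2 + y^2)
  az <- atan2(y, x)

  t_um <- radial_thickness(cfg, r) * sp$t_scale *
    (1 + meridian_mod_at(cfg, az))
  hfl_nm <- cfg$coupling * t_um
  if (mode == "fixed") {
    net_rad <- closed_form_retardance(
      nm_to_rad(hfl_nm), az,
      nm_to_rad(sp$corneal_nm), -cfg$corneal_axis_deg * pi / 180)
  } else {
    net_rad <- nm_to_rad(hfl_nm)
  }
  net_nm <- matrix(rad_to_nm(net_rad), nr, nc)

  set.seed(derive_seed(subject_seed, 1))
  noise <- if (cfg$noise_sd > 0) {
    matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  } else 0
  intensity <- cfg$gain * net_nm + sp$baseline + noise
  pixels <- matrix(round(pmin(255, pmax(0, intensity))), nr, nc)
  storage.mode(pixels) <- "integer"

  dense_r <- seq(0, 3.25, by = 0.01)
  thickness_by_meridian <- vapply(0:3, function(m) {
    hfl_thickness_profile(cfg, dense_r, m) * sp$t_scale
  }, numeric(length(dense_r)))
  colnames(thickness_by_meridian) <- MERIDIANS

  map <- retardation_map(pixels, deg_per_px = cfg$deg_per_px, mode = mode,
                         quality_score = sp$slp_quality,
                         fov_deg = cfg$fov_deg)
  truth <- list(
    foveal_center_px = center,
    retardance_map_nm = net_nm,
    thickness_r = dense_r,
    thickness_by_meridian = thickness_by_meridian,
    t_scale = sp$t_scale,
    corneal_nm = if (mode == "fixed") sp$corneal_nm else 0,
    corneal_axis_deg = cfg$corneal_axis_deg,
    baseline = sp$baseline)
  list(map = map, truth = truth)
}

#' Simulate directional-OCT boundary traces for one meridian pair scan
#'
#' Returns per-column anterior and posterior HFL boundary depths plus an
#' outer-segment-length band. Directional visibility is encoded in the
#' validity masks: with the beam entry offset 3 mm to one side of the
#' pupil, the posterior HFL border is delineated on the distal side of the
#' offset and the anterior border on the proximal side, so opposite-offset
#' scan pairs are complementary.
#'
#' @param config A [sim_config()].
#' @param meridian `"horizontal"` (temporal/nasal) or `"vertical"`
#'   (inferior/superior).
#' @param offset_sign +1 or -1; which side of the pupil the beam enters.
#' @param subject_seed Integer subject seed (shared with the SLP map).
#' @return A list with `anterior`, `posterior`, `os_band` (each a
#'   [boundary_trace()]), `meta` (scan metadata list) and `truth`
#'   (true foveal column and per-column thickness in px and um).
#' @export
simulate_oct_boundaries <- function(config,
                                    meridian = c("horizontal", "vertical"),
                                    offset_sign = 1,
                                    subject_seed = config$seed) {
  meridian <- match.arg(meridian)
  stopifnot(offset_sign %in% c(-1, 1))
  cfg <- config
  sp <- subject_params(cfg, subject_seed)
  nc <- cfg$oct_n_cols
  lat <- lateral_um_per_px(cfg)
  fovea_col <- as.integer(round(nc / 2)) + sp$oct_col_jitter
  ## Manual segmentation covers the central macula where the HFL is
  ## delineated (+/- 4.5 deg about the fovea), not the full b-scan.
  half_win <- round(4.5 * UM_PER_DEG / lat)
  cols <- max(1, fovea_col - half_win):min(nc, fovea_col + half_win)
  ecc <- (cols - fovea_col) * lat / UM_PER_DEG # signed degrees

  az <- if (meridian == "horizontal") {
    ifelse(ecc >= 0, MERIDIAN_AZ[["nasal"]], MERIDIAN_AZ[["temporal"]])
  } else {
    ifelse(ecc >= 0, MERIDIAN_AZ[["superior"]], MERIDIAN_AZ[["inferior"]])
  }
  t_um <- radial_thickness(cfg, abs(ecc)) * sp$t_scale *
    (1 + meridian_mod_at(cfg, az))
  t_px <- t_um / cfg$axial_um_per_px

  scan_index <- match(paste(meridian, offset_sign),
                      c("horizontal 1", "horizontal -1",
                        "vertical 1", "vertical -1"))
  set.seed(derive_seed(subject_seed, 10 + scan_index))
  ## Manual-segmentation error is smooth along the scan, not per-column
  ## white noise: spline through sparse Gaussian knots with SD trace_jitter.
  jit <- function(n) {
    if (cfg$trace_jitter_px == 0) return(rep(0, n))
    knots <- seq(1, n, length.out = max(4, round(n / 128)))
    stats::spline(knots, stats::rnorm(length(knots), 0, cfg$trace_jitter_px),
                  xout = seq_len(n))$y
  }
  nw <- length(cols)
  posterior_depth <- 250 + jit(nw)
  ## graders never cross the boundaries: anterior stays at or above posterior
  anterior_depth <- pmin(250 - t_px + jit(nw), posterior_depth)
  os_px <- 14 * exp(-(ecc / 1.5)^2) + 8 + jit(nw)

  ## Posterior border visible on the distal side (opposite the offset),
  ## anterior on the proximal side; both include the foveal column.
  distal <- offset_sign * (cols - fovea_col) <= 0
  proximal <- offset_sign * (cols - fovea_col) >= 0
  anterior <- boundary_trace(cols, ifelse(proximal, anterior_depth, NA_real_),
                             proximal, "anterior")
  posterior <- boundary_trace(cols, ifelse(distal, posterior_depth, NA_real_),
                              distal, "posterior")
  os_band <- boundary_trace(cols, os_px, rep(TRUE, nw), "os_band")

  meta <- list(meridian = meridian, offset_mm = 3 * offset_sign,
               axial_um_per_px = cfg$axial_um_per_px,
               lateral_um_per_px = lat,
               quality_db = sp$oct_quality[scan_index], eye = "OD")
  truth <- list(fovea_col = fovea_col, thickness_px = t_px,
                thickness_um = t_um)
  list(anterior = anterior, posterior = posterior, os_band = os_band,
       meta = meta, truth = truth)
}

#' Simulate a cohort and write it in the external interchange formats
#'
#' Draws per-subject corneal residuals and thickness perturbations, then
#' writes, for each virtual subject, one SLP map (8-bit grayscale PNG +
#' JSON sidecar), four directional boundary-trace sets (three CSVs + one
#' metadata JSON per scan), and a synthetic ground-truth JSON, all indexed
#' by a cohort manifest. Byte-identical for identical seeds.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of virtual subjects (>= 1).
#' @param mode `"fixed"` or `"variable"` corneal compensation.
#' @param seed Integer cohort seed.
#' @param out_dir Output directory (created if needed).
#' @param cohort_label Label recorded in the manifest.
#' @return Invisibly, the manifest path; the manifest list is attached as
#'   attribute `"manifest"`.
#' @export
simulate_cohort <- function(config, n_subjects, mode = c("fixed", "variable"),
                            seed = config$seed, out_dir,
                            cohort_label = paste0("cohort_", mode[1])) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(2147483600L, n_subjects)

  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("subject_%02d", i)
    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    ss <- subject_seeds[i]

    sim <- simulate_retardation_map(config, mode, ss)
    write_retardation_map(sim$map, file.path(sdir, "slp.png"),
                          center_hint = (dim(sim$map$pixels) + 1) / 2)

    scans <- list()
    k <- 1
    for (mer in c("horizontal", "vertical")) {
      for (sg in c(1, -1)) {
        sc <- simulate_oct_boundaries(config, mer, sg, ss)
        tag <- sprintf("oct_%s_%s", substr(mer, 1, 1),
                       if (sg > 0) "p" else "m")
        for (b in c("anterior", "posterior", "os_band")) {
          write_boundary_trace(sc[[b]],
                               file.path(sdir, sprintf("%s_%s.csv", tag, b)))
        }
        write_json_file(sc$meta, file.path(sdir, paste0(tag, ".json")))
        scans[[k]] <- list(
          meridian = mer, offset_sign = sg,
          meta = file.path(id, paste0(tag, ".json")),
          anterior = file.path(id, sprintf("%s_anterior.csv", tag)),
          posterior = file.path(id, sprintf("%s_posterior.csv", tag)),
          os_band = file.path(id, sprintf("%s_os_band.csv", tag)))
        k <- k + 1
      }
    }

    truth_file <- list(
      synthetic = TRUE,
      foveal_center_px = sim$truth$foveal_center_px,
      t_scale = sim$truth$t_scale,
      corneal_nm = sim$truth$corneal_nm,
      thickness_um_grid = as.numeric(
        radial_thickness(config, canonical_grid()) * sim$truth$t_scale))
    write_json_file(truth_file, file.path(sdir, "truth.json"))

    subjects[[i]] <- list(
      id = id, seed = ss,
      slp = list(image = file.path(id, "slp.png"),
                 meta = file.path(id, "slp.json")),
      scans = scans,
      truth = file.path(id, "truth.json"))
  }

  manifest <- list(cohort_label = cohort_label, mode = mode,
                   n_subjects = n_subjects, subjects = subjects)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_json_file(manifest, manifest_path)
  structure(invisible(manifest_path), manifest = manifest)
}
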