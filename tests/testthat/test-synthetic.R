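test_that("thickness model vanishes at the fovea and peaks at r_peak", {
  cfg <- sim_config(t_max = 30, r_peak = 2, shape = 2)
  expect_identical(hfl_thickness_profile(cfg, 0), 0)
  expect_equal(hfl_thickness_profile(cfg, 2), 30, tolerance = 1e-12)
  # closed form at twice the peak eccentricity: 30 * 4 * exp(-2)
  expect_equal(hfl_thickness_profile(cfg, 4), 30 * 4 * exp(-2),
               tolerance = 1e-12)
  expect_error(hfl_thickness_profile(cfg, -0.5), "non-negative")
  # unique maximum at r_peak, unimodal, non-negative
  r <- seq(0, 6, by = 0.01)
  t <- hfl_thickness_profile(cfg, r)
  expect_true(all(t >= 0))
  expect_equal(r[which.max(t)], 2)
  expect_true(all(diff(t[r < 2]) > 0) && all(diff(t[r > 2]) < 0))
  # meridian modulation scales the profile
  cfg2 <- sim_config(meridian_mod = c(0.1, -0.1, 0.2, 0))
  expect_equal(hfl_thickness_profile(cfg2, 1.5, 2),
               1.2 * hfl_thickness_profile(cfg2, 1.5, 1) / 0.9,
               tolerance = 1e-12)
})

test_that("variable-mode noiseless rings are flat, fixed-mode rings are second-harmonic", {
  cfg <- noiseless_config()
  sv <- simulate_retardation_map(cfg, "variable", 42)
  ctr <- sv$truth$foveal_center_px
  for (e in c(0.5, 1, 2)) {
    pr <- ring_profile(sv$map, ctr, e)
    expect_lt(sd(pr$intensity), 1.0) # quantization + interpolation scale
  }
  sf <- simulate_retardation_map(cfg, "fixed", 42)
  ctrf <- sf$truth$foveal_center_px
  for (e in c(1, 2)) {
    fit <- cross_amplitude(ring_profile(sf$map, ctrf, e))
    expect_gt(fit$r_squared, 0.99)
    # fitted phase aligns with the residual corneal slow axis (mod pi)
    dphi <- (fit$phase - (-cfg$corneal_axis_deg * pi / 180)) %% pi
    expect_lt(min(dphi, pi - dphi), 2 * pi / 180)
  }
})

test_that("coupling = 0 leaves only the corneal retarder", {
  cfg <- noiseless_config(coupling = 0)
  sim <- simulate_retardation_map(cfg, "fixed", 3)
  expect_equal(diff(range(sim$map$pixels)), 0L)
  expect_equal(sim$map$pixels[1, 1],
               as.integer(round(cfg$gain * cfg$corneal_residual_nm)))
})

test_that("ground truth is non-negative, zero at center, unimodal", {
  cfg <- sim_config(meridian_mod = c(0.05, -0.05, 0.05, -0.05))
  sim <- simulate_retardation_map(cfg, "fixed", 11)
  tb <- sim$truth$thickness_by_meridian
  expect_true(all(tb >= 0))
  expect_true(all(tb[1, ] == 0))
  for (m in 1:4) {
    peak <- which.max(tb[, m])
    expect_true(all(diff(tb[seq_len(peak), m]) >= 0))
    expect_true(all(diff(tb[peak:nrow(tb), m]) <= 0))
  }
  expect_error(
    simulate_retardation_map(sim_config(fov_deg = c(5, 5), center_jitter_px = 0),
                             "fixed", 1),
    "field of view too small")
})

test_that("boundary traces encode directional visibility and exact thickness", {
  cfg <- noiseless_config()
  sc_p <- simulate_oct_boundaries(cfg, "horizontal", 1, 5)
  sc_m <- simulate_oct_boundaries(cfg, "horizontal", -1, 5)
  # jitter 0: posterior - anterior = true thickness wherever both defined
  both <- sc_p$anterior$valid & sc_p$posterior$valid
  expect_true(any(both)) # foveal column at least
  expect_equal(sc_p$posterior$depths[both] - sc_p$anterior$depths[both],
               sc_p$truth$thickness_px[both], tolerance = 1e-9)
  merged_ant <- sc_p$anterior$valid | sc_m$anterior$valid
  expect_true(all(merged_ant)) # opposite offsets are complementary
  # flipping the offset sign swaps which half of each trace is valid
  expect_identical(sc_p$anterior$valid, sc_m$posterior$valid)
  expect_identical(sc_p$posterior$valid, sc_m$anterior$valid)
  # outer-segment band peaks at the true foveal column
  expect_equal(sc_p$os_band$columns[which.max(sc_p$os_band$depths)],
               as.numeric(sc_p$truth$fovea_col))
  expect_error(simulate_oct_boundaries(cfg, "diagonal", 1, 5))
})

test_that("simulate_cohort is byte-identical under a repeated seed", {
  cfg <- sim_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, 2, "fixed", seed = 9, out_dir = d1)
  simulate_cohort(cfg, 2, "fixed", seed = 9, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})

test_that("disabling all between-subject variation makes subjects identical", {
  cfg <- noiseless_config()
  maps <- lapply(c(101, 202, 303), function(ss) {
    simulate_retardation_map(cfg, "fixed", ss)$map$pixels
  })
  expect_identical(maps[[1]], maps[[2]])
  expect_identical(maps[[1]], maps[[3]])
})
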