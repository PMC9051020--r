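test_that("SLP quality filter is inclusive at 8", {
  expect_identical(qc_filter_slp(c(8, 7.9, 10)), c(TRUE, FALSE, TRUE))
})

test_that("ring_profile samples analytic fields faithfully", {
  # constant field
  fm <- field_map(function(x, y) matrix(77, nrow(x), ncol(x)))
  pr <- ring_profile(fm$map, fm$center, 2)
  expect_equal(pr$intensity, rep(77, 360))
  expect_error(ring_profile(fm$map, fm$center, 10), "outside image bounds")

  # pure second harmonic about the center
  fm2 <- field_map(function(x, y) round(100 + 50 * cos(2 * atan2(y, x))))
  pr2 <- ring_profile(fm2$map, fm2$center, 2)
  expect_lt(max(abs(pr2$intensity - (100 + 50 * cos(2 * pr2$azimuth)))), 1.2)
  # thin-circle mean of a pure second harmonic is the constant term
  expect_equal(ring_mean(pr2), 100, tolerance = 0.1)

  # rotating the map 90 deg CCW shifts the profile by a quarter turn
  rot_map <- retardation_map(rot90_ccw(fm2$map$pixels), fm2$map$deg_per_px,
                             "fixed", 10)
  pr_rot <- ring_profile(rot_map, fm2$center, 2)
  shifted <- pr2$intensity[((seq_len(360) - 1 - 90) %% 360) + 1]
  expect_equal(pr_rot$intensity, shifted, tolerance = 1e-9)
})

test_that("annulus_mean matches brute-force pixel enumeration", {
  a <- 40; b <- 15
  fm <- field_map(function(x, y) round(a + b * sqrt(x^2 + y^2)))
  for (e in c(0.5, 1.5, 3)) {
    got <- annulus_mean(fm$map, fm$center, e)
    # independent enumeration over the full pixel grid
    n <- nrow(fm$map$pixels)
    rd <- outer(seq_len(n), seq_len(n), function(r, cc) {
      sqrt((r - fm$center[1])^2 + (cc - fm$center[2])^2) * fm$map$deg_per_px
    })
    want <- mean(fm$map$pixels[rd >= e - 0.125 & rd < e + 0.125])
    expect_equal(got, want, tolerance = 1e-12)
    # pixel-weighted mean radius of a radially linear map
    ebar <- mean(rd[rd >= e - 0.125 & rd < e + 0.125])
    expect_equal(got, a + b * ebar, tolerance = 0.5) # quantization
  }
  expect_error(annulus_mean(fm$map, c(-500, -500), 0.25))
})

test_that("cross_amplitude recovers programmed sinusoids", {
  az <- seq(0, 2 * pi, length.out = 361)[1:360]
  mk <- function(y) structure(list(azimuth = az, intensity = y,
                                   eccentricity = 1), class = "ring_profile")
  # constant profile: no modulation
  expect_equal(cross_amplitude(mk(rep(5, 360)))$amplitude, 0, tolerance = 1e-12)
  # exact recovery of amplitude and phase: 50 + 10 cos(2 phi - 0.6)
  fit <- cross_amplitude(mk(50 + 10 * cos(2 * az - 0.6)))
  expect_equal(fit$amplitude, 10, tolerance = 1e-9)
  expect_equal(fit$phase, 0.3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # invariance of amplitude / equivariance of phase under cyclic shift
  y <- 50 + 10 * cos(2 * az - 0.6)
  y_shift <- y[((seq_len(360) - 1 - 45) %% 360) + 1] # shift by 45 deg
  fit_s <- cross_amplitude(mk(y_shift))
  expect_equal(fit_s$amplitude, 10, tolerance = 1e-9)
  expect_equal((fit_s$phase - (0.3 + pi / 4)) %% pi, 0, tolerance = 1e-9)
  # noisy recovery within the least-squares standard error
  set.seed(42)
  fit_n <- cross_amplitude(mk(50 + 10 * cos(2 * az) + rnorm(360)))
  expect_lt(abs(fit_n$amplitude - 10), 0.25)
  expect_error(cross_amplitude(structure(list(azimuth = az[1:4],
                                              intensity = 1:4),
                                         class = "ring_profile")),
               "at least 8")
})

test_that("macular center is localized to sub-pixel accuracy in both modes", {
  cfg <- noiseless_config()
  sf <- simulate_retardation_map(cfg, "fixed", 42)
  cf <- locate_macular_center(sf$map)
  expect_lt(max(abs(cf - sf$truth$foveal_center_px)), 0.5)
  sv <- simulate_retardation_map(cfg, "variable", 42)
  cv <- locate_macular_center(sv$map)
  expect_lt(max(abs(cv - sv$truth$foveal_center_px)), 0.5)
  # off-center truth, noise and subject variation: still within a pixel
  cfgn <- sim_config()
  sn <- simulate_retardation_map(cfgn, "variable", 99)
  cn <- locate_macular_center(sn$map)
  expect_lt(max(abs(cn - sn$truth$foveal_center_px)), 1)
  # uniform map has no structure
  flat <- retardation_map(matrix(120L, 256, 512), 20 / 256, "fixed", 10)
  expect_error(locate_macular_center(flat), "degenerate|structure|floor")
  flat_v <- retardation_map(matrix(120L, 256, 512), 20 / 256, "variable", 10)
  expect_error(locate_macular_center(flat_v), "degenerate|structure")
})

test_that("eccentricity_profile tracks ground-truth thickness", {
  cfg <- noiseless_config()
  sv <- simulate_retardation_map(cfg, "variable", 42)
  prof <- eccentricity_profile(sv$map, sv$truth$foveal_center_px)
  truth <- hfl_thickness_profile(cfg, canonical_grid())
  expect_gt(pearson_r(prof$values, truth), 0.99)
  # profile peaks at the grid point nearest r_peak
  expect_equal(canonical_grid()[which.max(prof$values)], cfg$r_peak)
  sf <- simulate_retardation_map(cfg, "fixed", 42)
  proff <- eccentricity_profile(sf$map, sf$truth$foveal_center_px)
  expect_equal(canonical_grid()[which.max(proff$values)], cfg$r_peak)
  # constant map gives a constant profile
  fm <- field_map(function(x, y) matrix(64, nrow(x), ncol(x)), n = 121)
  expect_equal(eccentricity_profile(fm$map, fm$center)$values, rep(64, 12))
})

test_that("eccentricity_profile is invariant to joint integer translation", {
  cfg <- noiseless_config()
  sv <- simulate_retardation_map(cfg, "variable", 42)
  px <- sv$map$pixels
  ctr <- sv$truth$foveal_center_px
  crop1 <- retardation_map(px[1:250, 1:500], sv$map$deg_per_px, "variable", 10)
  crop2 <- retardation_map(px[4:253, 3:502], sv$map$deg_per_px, "variable", 10)
  p1 <- eccentricity_profile(crop1, ctr)
  p2 <- eccentricity_profile(crop2, ctr - c(3, 2))
  expect_equal(p2$values, p1$values, tolerance = 1e-12)
})

test_that("slp_subject_profile exposes both per-ring statistics", {
  cfg <- noiseless_config()
  sf <- simulate_retardation_map(cfg, "fixed", 8)
  tab <- slp_subject_profile(sf$map, sf$truth$foveal_center_px)
  expect_identical(names(tab), c("eccentricity_deg", "ring_mean",
                                 "cross_amplitude", "fit_r2", "mode"))
  expect_equal(tab$eccentricity_deg, canonical_grid())
  expect_true(all(tab$mode == "fixed"))
  # macular-cross amplitude grows from the center out to the thickness peak
  expect_gt(tab$cross_amplitude[8], tab$cross_amplitude[1])
})
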