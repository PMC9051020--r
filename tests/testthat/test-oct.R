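meta_h <- list(meridian = "horizontal", axial_um_per_px = 3.87,
               lateral_um_per_px = 10, quality_db = 30)

test_that("OCT quality filter uses a strict 20 dB threshold", {
  expect_identical(qc_filter_oct(c(25, 20, 19.9)), c(TRUE, FALSE, FALSE))
  expect_error(qc_filter_oct(NA_real_))
})

test_that("combine_boundaries subtracts boundaries and merges offsets", {
  cols <- 1:100
  # constant separation k
  ant <- line_trace(cols, rep(200, 100), "anterior")
  post <- line_trace(cols, rep(212.5, 100), "posterior")
  prof <- combine_boundaries(ant, post, meta_h)
  expect_equal(prof$thickness_px, rep(12.5, 100))
  expect_equal(prof$thickness_um, rep(12.5 * 3.87, 100))

  # complementary validity from two opposite offsets
  left <- cols <= 50
  a1 <- line_trace(cols, ifelse(left, 200, NA), "anterior", left)
  a2 <- line_trace(cols, ifelse(!left, 201, NA), "anterior", !left)
  p1 <- line_trace(cols, ifelse(!left, 210, NA), "posterior", !left)
  p2 <- line_trace(cols, ifelse(left, 208, NA), "posterior", left)
  prof2 <- combine_boundaries(list(a1, a2), list(p1, p2), meta_h)
  expect_equal(prof2$thickness_px, ifelse(left, 8, 9))

  # column axes must agree
  expect_error(combine_boundaries(line_trace(2:101, rep(200, 100), "anterior"),
                                  post, meta_h),
               "column axes")
  # missing coverage on >10% of columns is an error
  gap <- cols > 80
  a3 <- line_trace(cols, ifelse(gap, NA, 200), "anterior", !gap)
  expect_error(combine_boundaries(a3, post, meta_h), ">10%")
})

test_that("negative thickness is floored with a warning, crossing is an error", {
  cols <- 1:100
  post <- line_trace(cols, rep(210, 100), "posterior")
  dip <- c(rep(205, 95), rep(211, 5)) # 5% of columns cross slightly
  expect_warning(
    prof <- combine_boundaries(line_trace(cols, dip, "anterior"), post, meta_h),
    "floored 5")
  expect_equal(prof$n_floored, 5L)
  expect_true(all(prof$thickness_px >= 0))
  cross <- c(rep(205, 80), rep(215, 20)) # 20% cross
  expect_error(
    combine_boundaries(line_trace(cols, cross, "anterior"), post, meta_h),
    "cross")
})

test_that("fovea localization smooths, then breaks ties toward the center", {
  cols <- 1:1536
  # unimodal band peaking at column 768
  os <- line_trace(cols, 30 - abs(cols - 768) * 0.01, "os_band")
  expect_equal(locate_fovea_oct(os), 768)
  # plateau of equal maxima at 700-710: the width-11 moving average leaves a
  # unique maximum at the plateau midpoint 705
  plateau <- ifelse(cols >= 700 & cols <= 710, 30, 30 - abs(cols - 705) * 0.01)
  expect_equal(locate_fovea_oct(line_trace(cols, plateau, "os_band")), 705)
  # exact tie after smoothing resolves toward the image center
  flat <- rep(10, 1536)
  expect_equal(locate_fovea_oct(line_trace(cols, flat, "os_band")), 768)
  expect_error(
    locate_fovea_oct(boundary_trace(1:10, rep(NA_real_, 10),
                                    rep(FALSE, 10), "os_band")),
    "3 valid")
})

test_that("sample_thickness converts degrees at 320 um/deg and interpolates", {
  cols <- 1:1000
  fovea <- 500
  # constant profile: every grid value equals the constant
  prof_c <- combine_boundaries(line_trace(cols, rep(200, 1000), "anterior"),
                               line_trace(cols, rep(207, 1000), "posterior"),
                               meta_h)
  halves <- sample_thickness(prof_c, fovea, meta_h)
  expect_named(halves, c("temporal", "nasal"))
  expect_equal(halves$temporal$values, rep(7, 12))
  expect_equal(halves$nasal$values, rep(7, 12))

  # linear ramp a + b*col samples exactly at fovea +/- e*320/lat px
  a <- 50; b <- 0.02
  prof_l <- combine_boundaries(
    line_trace(cols, rep(300, 1000) - (a + b * cols), "anterior"),
    line_trace(cols, rep(300, 1000), "posterior"), meta_h)
  halves_l <- sample_thickness(prof_l, fovea, meta_h)
  off <- canonical_grid() * 320 / 10 # 32 px per degree at 10 um/px
  expect_equal(halves_l$nasal$values, a + b * (fovea + off), tolerance = 1e-12)
  expect_equal(halves_l$temporal$values, a + b * (fovea - off),
               tolerance = 1e-12)

  # grid point beyond the scan extent
  expect_error(sample_thickness(prof_l, 980, meta_h), "span 3 degrees")

  # translation equivariance: shifting profile and fovea together is a no-op
  prof_s <- combine_boundaries(
    line_trace(cols + 37, rep(300, 1000) - (a + b * cols), "anterior"),
    line_trace(cols + 37, rep(300, 1000), "posterior"), meta_h)
  halves_s <- sample_thickness(prof_s, fovea + 37, meta_h)
  expect_equal(halves_s$nasal$values, halves_l$nasal$values, tolerance = 1e-12)
})

test_that("average_meridians is the pointwise mean and rejects missing meridians", {
  mk <- function(v, m) ecc_profile(rep(v, 12), "thickness", meridian = m)
  four <- list(mk(8, "temporal"), mk(10, "superior"), mk(12, "nasal"),
               mk(14, "inferior"))
  avg <- average_meridians(four)
  expect_equal(avg$values, rep(11, 12))
  # permutation invariance
  expect_equal(average_meridians(four[c(3, 1, 4, 2)])$values, avg$values)
  expect_error(average_meridians(four[1:3]), "incomplete")
  expect_error(average_meridians(c(four[1:3], list(mk(1, "temporal")))),
               "incomplete")
})

test_that("balanced meridian modulations cancel in the four-meridian average", {
  cfg0 <- noiseless_config()
  cfgm <- noiseless_config(meridian_mod = c(0.1, -0.1, 0.1, -0.1))
  t0 <- oct_subject_thickness(subject_scans(cfg0, 7))
  tm <- oct_subject_thickness(subject_scans(cfgm, 7))
  expect_equal(tm$values, t0$values, tolerance = 1e-9)
})

test_that("noiseless end-to-end OCT stage recovers ground truth within 1%", {
  cfg <- noiseless_config()
  scans <- subject_scans(cfg, 7)
  prof <- oct_subject_thickness(scans)
  truth_px <- hfl_thickness_profile(cfg, canonical_grid()) / cfg$axial_um_per_px
  expect_true(all(abs(prof$values - truth_px) / truth_px < 0.01))
  for (sc in scans) {
    expect_lte(abs(locate_fovea_oct(sc$os_band) - sc$truth$fovea_col), 1)
  }
  # a low-quality scan drops the subject
  scans[[2]]$meta$quality_db <- 19
  drop <- oct_subject_thickness(scans)
  expect_s3_class(drop, "qc_drop")
  expect_match(drop$reason, "20 dB")
})
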