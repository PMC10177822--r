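test_that("profile stations and geometry follow the border marking", {
  ph <- test_phantom(noise_sd_hu = 0)
  pr <- extract_profiles(ph$image, phantom_border(ph$truth, length_mm = 9))
  # ten stations 1 mm apart along the vertical border; horizontal profiles
  st <- dplyr::distinct(pr, profile, station_x_mm, station_y_mm)
  expect_equal(nrow(st), 10)
  expect_equal(diff(st$station_y_mm), rep(1, 9))
  expect_equal(unique(st$station_x_mm), ph$truth$border_center_x_mm)
  pos <- pr$position_mm[pr$profile == 1]
  expect_equal(range(pos), c(-4.5, 4.5))
  expect_true(all(abs(diff(diff(pos))) < 1e-12))
  # brighter tissue at negative positions
  expect_gt(mean(pr$value_hu[pr$position_mm < 0]),
            mean(pr$value_hu[pr$position_mm > 0]))
})

test_that("noiseless axis-aligned profiles equal the analytic template", {
  ph <- test_phantom(noise_sd_hu = 0, slope = -150)
  pr <- extract_profiles(ph$image, phantom_border(ph$truth))
  expect_equal(pr$value_hu, analytic_template(pr$position_mm), tolerance = 1e-9)
})

test_that("rotated-edge profiles match the template within bilinear error", {
  ph <- test_phantom(noise_sd_hu = 0, angle = 30, spacing = 0.25)
  pr <- extract_profiles(ph$image, phantom_border(ph$truth, length_mm = 6))
  err <- abs(pr$value_hu - analytic_template(pr$position_mm))
  # bilinear interpolation reproduces the template exactly except in cells
  # crossed by the two template knots (|d| = w/2 = 0.5 mm), where the field
  # is only C0; exclude a one-cell-diagonal band around each knot
  near_knot <- abs(abs(pr$position_mm) - 0.5) < 0.25 * sqrt(2)
  expect_lt(max(err[!near_knot]), 0.5)
  # near the knots the error is bounded by one pixel of ramp excursion
  expect_lt(max(err), 150 * 0.25)
})

test_that("sample points outside the raster are rejected with the station", {
  ph <- test_phantom(noise_sd_hu = 0)
  wild <- border_spec(c(1, 1), c(1, 10), half_range_mm = 20)
  expect_error(extract_profiles(ph$image, wild), class = "ctiq_out_of_bounds")
  expect_error(extract_profiles(ph$image, wild), "outside the raster")
})

test_that("baselines recover the plateaus and flag degenerate profiles", {
  ph <- test_phantom(noise_sd_hu = 0)
  pr <- extract_profiles(ph$image, phantom_border(ph$truth))
  b <- estimate_baselines(dplyr::filter(pr, profile == 1))
  expect_equal(b$upper_baseline_hu, 50)
  expect_equal(b$lower_baseline_hu, -100)
  expect_true(is.na(b$flag))

  flat <- tibble::tibble(position_mm = seq(-4.5, 4.5, by = 0.1), value_hu = 7)
  bf <- estimate_baselines(flat)
  expect_identical(bf$flag, "inverted_or_flat")
  expect_true(is.na(bf$upper_baseline_hu))

  short <- tibble::tibble(position_mm = seq(-1, 1, by = 0.25), value_hu = 1:9)
  expect_error(estimate_baselines(short), "fewer than 3 samples")
})

test_that("noisy baselines stay within the plateau-mean standard error", {
  # 0.1 mm sampling, fraction 0.25: plateau means average m samples each,
  # so |error| < 3 * sd/sqrt(m) in virtually every run
  ph <- test_phantom(noise_sd_hu = 5, spacing = 0.2, seed = 9)
  pr <- extract_profiles(ph$image, phantom_border(ph$truth), step_mm = 0.1)
  n_side <- sum(pr$position_mm[pr$profile == 1] < 0)
  m <- floor(0.25 * n_side)
  bounds <- 3 * 5 / sqrt(m)
  an <- analyze_profiles(pr)
  expect_true(all(abs(an$upper_baseline_hu - 50) < bounds))
  expect_true(all(abs(an$lower_baseline_hu + 100) < bounds))
})

test_that("steepest slope is exact on a noiseless ramp", {
  ph <- test_phantom(noise_sd_hu = 0, slope = -150)
  pr <- extract_profiles(ph$image, phantom_border(ph$truth), step_mm = 0.1)
  s <- steepest_slope(dplyr::filter(pr, profile == 1))
  expect_equal(s$steepest_slope_hu_per_mm, -150, tolerance = 1e-6)
  expect_equal(s$distance_mm, -0.2)
  expect_lt(abs(s$slope_window_center_mm), 0.45)
})

test_that("constant and non-uniform profiles are flagged or rejected", {
  flat <- tibble::tibble(position_mm = seq(-2, 2, by = 0.5), value_hu = 3)
  s <- steepest_slope(flat)
  expect_equal(s$steepest_slope_hu_per_mm, 0)
  expect_identical(s$flag, "no_transition")
  expect_true(is.na(s$distance_mm))

  jag <- tibble::tibble(position_mm = c(-1, 0, 0.3, 1), value_hu = c(1, 2, 3, 4))
  expect_error(steepest_slope(jag), "uniform")
})

test_that("noisy slope estimates are biased steeper than truth by under 15%", {
  meds <- vapply(1:100, function(s) {
    estimated_median_slope(-150, 0.5, 5, seed = s)
  }, numeric(1))
  centre <- median(meds)
  expect_lt(centre, -150)         # three-point windows over noise bias steep
  expect_gt(centre, -150 * 1.15)  # ... but by less than 15%
})

test_that("sharpness summary is the component-wise median and permutation-invariant", {
  an <- tibble::tibble(
    profile = 1:10,
    upper_baseline_hu = 50 + (1:10) / 10,
    lower_baseline_hu = -100 - (1:10) / 10,
    steepest_slope_hu_per_mm = -(1:10),
    slope_window_center_mm = 0,
    distance_mm = -0.2,
    flag = NA_character_
  )
  smry <- summarize_sharpness(an)
  expect_equal(smry$median_slope_hu_per_mm, -5.5)
  expect_equal(smry$median_upper_hu, 50.55)
  perm <- withr::with_seed(1, an[sample(10), ])
  expect_equal(summarize_sharpness(perm), smry)

  # ten identical analyses: summary equals the replicate
  rep10 <- an[rep(1, 10), ]
  smry1 <- summarize_sharpness(rep10)
  expect_equal(smry1$median_slope_hu_per_mm, -1)
  expect_equal(smry1$median_upper_hu, 50.1)
  expect_error(summarize_sharpness(an[0, ]), "empty")
})

test_that("noiseless slope recovery holds across slopes and spacings", {
  # exact whenever the pixel lattice resolves the ramp; when the ramp is
  # narrower than two pixels the recoverable slope saturates at the
  # finite-difference limit contrast / (2 * spacing)
  for (slope in c(-50, -100, -168.4, -300)) {
    for (spacing in c(0.234, 0.469)) {
      est <- estimated_median_slope(slope, spacing, 0, seed = 1)
      expected <- max(slope, -150 / (2 * spacing))
      expect_lt(abs(est - expected), 0.02 * abs(expected) + 1e-9)
    }
  }
})

test_that("steeper true edges never yield shallower estimated slopes", {
  for (s in 1:20) {
    steep <- estimated_median_slope(-168.4, 0.234, 5, seed = s)
    shallow <- estimated_median_slope(-94.5, 0.469, 5, seed = s + 1000)
    expect_lt(steep, shallow)
  }
})
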