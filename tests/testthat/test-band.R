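depth_grid <- function(n = 100) seq(0, 1, length.out = n)

test_that("profile averaging is a pointwise mean with validation", {
  base <- 100 - 10 * exp(-(depth_grid() - 0.5)^2 / (2 * 0.08^2))
  ps <- profile_set_from_matrix(matrix(rep(base, each = 10), nrow = 10))
  expect_equal(average_profiles(ps), base)
  two <- profile_set_from_matrix(rbind(base, -base))
  expect_equal(average_profiles(two), rep(0, 100))
  expect_error(average_profiles(matrix(numeric(0), nrow = 0, ncol = 100)))
  expect_error(average_profiles(matrix(c(1, NA), 1)), "non-finite")
})

test_that("noisy phantom-profile means converge at the CLT rate", {
  spec <- phantom_spec()
  truth <- radial_ground_truth_profile(spec, 100)
  sd <- 5
  ps <- noisy_profile_set(truth, n = 30, sd = sd, seed = 3)
  mp <- average_profiles(ps)
  expect_true(all(abs(mp - truth) < 3 * sd / sqrt(30)))
})

test_that("spline smoothing reproduces straight lines exactly", {
  d <- depth_grid()
  for (spar in c(0.1, 0.55, 0.9)) {
    sm <- smooth_profile(3 + 2 * d, spar)
    expect_equal(sm$smoothed, 3 + 2 * d, tolerance = 1e-8)
    expect_equal(sm$derivative, rep(2, 100), tolerance = 1e-6)
  }
})

test_that("spar near 0 approaches interpolation of smooth data", {
  d <- depth_grid()
  y <- sin(2 * pi * d)
  sm <- smooth_profile(y, spar = 0)
  expect_equal(sm$smoothed, y, tolerance = 1e-4)
})

test_that("the smoothed dip derivative keeps the analytic sign pattern", {
  spec <- phantom_spec(gm_slope = 0)
  y <- radial_ground_truth_profile(spec, 100)
  sm <- smooth_profile(y, 0.55)
  d <- depth_grid()
  # analytic derivative of the Gaussian dip: -,0,+ around the centre
  analytic <- spec$band_amplitude * (d - spec$band_depth) /
    spec$band_width^2 *
    exp(-(d - spec$band_depth)^2 / (2 * spec$band_width^2))
  core <- abs(d - 0.5) < 0.25 & abs(analytic) > 1
  expect_equal(sign(sm$derivative[core]), sign(analytic[core]))
  expect_error(smooth_profile(c(1, NA, 3, 4, 5)), "non-finite")
})

test_that("monotone profiles yield no band", {
  d <- depth_grid()
  sm <- smooth_profile(100 - 20 * d, 0.55)
  fb <- find_band(sm$smoothed, sm$derivative)
  expect_false(fb$found)
  expect_true(is.na(fb$min_depth))
})

test_that("cos(2*pi*depth) has its minimum crossing at depth 0.5", {
  d <- depth_grid()
  y <- cos(2 * pi * d)
  sm <- smooth_profile(y, 0.55)
  fb <- find_band(sm$smoothed, sm$derivative)
  expect_true(fb$found)
  expect_lt(abs(fb$min_depth - 0.5), 0.02)
  # derivative -2*pi*sin starts negative: no positive-to-negative crossing
  # can precede the minimum
  expect_true(fb$start_absent)
  expect_true(is.na(fb$start_depth))
  # oracle: dense root-finding on the fitted spline derivative
  fit <- stats::smooth.spline(d, y, spar = 0.55)
  root <- uniroot(function(x) predict(fit, x, deriv = 1)$y, c(0.3, 0.7))
  expect_lt(abs(fb$min_depth - root$root), 0.005)
})

test_that("a band on a rising shoulder has start before minimum", {
  d <- depth_grid()
  y <- 100 + 10 * d - 8 * exp(-(d - 0.6)^2 / (2 * 0.07^2))
  sm <- smooth_profile(y, 0.55)
  fb <- find_band(sm$smoothed, sm$derivative)
  expect_true(fb$found)
  expect_false(fb$start_absent)
  expect_lt(fb$start_depth, fb$min_depth)
  expect_gte(fb$start_intensity, fb$min_intensity)
})

test_that("derivative plateaus belong to the preceding sign regime", {
  n <- 100
  smoothed <- rep(1, n)
  deriv <- c(rep(-1, 40), rep(0, 20), rep(1, 40))
  fb <- find_band(smoothed, deriv)
  expect_true(fb$found)
  # single crossing where the zero plateau (carrying the negative regime)
  # meets the positive samples
  d <- depth_grid(n)
  expect_gt(fb$min_depth, d[59])
  expect_lte(fb$min_depth, d[61])
})

test_that("noiseless band phantom minima land within 0.02 of the truth", {
  # oracle: dense root-finding on the spline fitted to the analytic profile
  spec <- phantom_spec(band_depth = 0.5)
  y <- radial_ground_truth_profile(spec, 100)
  sm <- smooth_profile(y, 0.55)
  fb <- find_band(sm$smoothed, sm$derivative)
  fit <- stats::smooth.spline(depth_grid(), y, spar = 0.55)
  root <- uniroot(function(x) predict(fit, x, deriv = 1)$y, c(0.3, 0.7))
  # sub-step localisation is linear between samples: agreement to half a step
  expect_lt(abs(fb$min_depth - root$root), 0.005)
  expect_lt(abs(fb$min_depth - 0.5), 0.02)
})

test_that("bootstrap on identical band profiles is degenerate", {
  base <- 100 + 15 * (0.5 - depth_grid()) -
    10 * exp(-(depth_grid() - 0.5)^2 / (2 * 0.08^2))
  ps <- profile_set_from_matrix(matrix(rep(base, each = 12), nrow = 12))
  res <- bootstrap_band(ps, band_config(n_boot = 200, rng_seed = 4))
  expect_equal(res$boot_proportion, 1.0)
  expect_equal(diff(res$min_depth_ci), 0)
  expect_equal(res$min_depth_median, res$features_mean$min_depth)
})

test_that("bootstrap on identical monotone profiles finds nothing", {
  base <- 100 - 20 * depth_grid()
  ps <- profile_set_from_matrix(matrix(rep(base, each = 12), nrow = 12))
  res <- bootstrap_band(ps, band_config(n_boot = 100, rng_seed = 4))
  expect_equal(res$boot_proportion, 0)
  expect_true(is.na(res$min_depth_median))
  expect_true(all(is.na(res$min_depth_ci)))
})

test_that("bootstrap is deterministic given the seed", {
  spec <- phantom_spec()
  truth <- radial_ground_truth_profile(spec, 100)
  ps <- noisy_profile_set(truth, n = 20, sd = 3, seed = 9)
  cfg <- band_config(n_boot = 150, rng_seed = 21)
  a <- bootstrap_band(ps, cfg)
  b <- bootstrap_band(ps, cfg)
  expect_identical(tidy(a), tidy(b))
  expect_equal(glance(a), glance(b))
  c <- bootstrap_band(ps, band_config(n_boot = 150, rng_seed = 22))
  expect_false(identical(tidy(a), tidy(c)))
})

test_that("boot_proportion is monotone in injected band amplitude", {
  d <- depth_grid()
  props <- vapply(c(0, 2, 5, 10, 20), function(amp) {
    base <- 100 + 15 * (0.5 - d) - amp * exp(-(d - 0.5)^2 / (2 * 0.08^2))
    ps <- noisy_profile_set(base, n = 30, sd = 5, seed = 12)
    bootstrap_band(ps, band_config(n_boot = 150,
                                   rng_seed = 31))$boot_proportion
  }, numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("the proportion test matches prop.test behaviour at the null", {
  expect_gte(proportion_test(1500, 2000, 0.75), 0.5)
  expect_lt(proportion_test(2000, 2000, 0.75), 1e-6)
  p <- proportion_test(1800, 2000, 0.75)
  expect_lt(p, 0.05 / 12)
  expect_error(proportion_test(10, 5))
})

test_that("proportion-test decisions agree with exact binomial tails", {
  # oracle: exact binomial tail sum, Bonferroni-corrected alpha
  alpha <- 0.05 / 12
  trials <- 200
  for (k in 0:trials) {
    approx_p <- proportion_test(k, trials, 0.75)
    exact_p <- sum(dbinom(k:trials, trials, 0.75))
    expect_identical(approx_p < alpha, exact_p < alpha)
  }
})

test_that("zero bootstrap successes cannot be significant", {
  base <- 100 - 20 * depth_grid()
  ps <- profile_set_from_matrix(matrix(rep(base, each = 10), nrow = 10))
  res <- analyze_location(ps, band_config(n_boot = 100, rng_seed = 2,
                                          n_tests = 12))
  expect_equal(res$boot_proportion, 0)
  expect_gte(res$prop_p_value, 0.999)
  expect_false(res$significant)
})

test_that("a clear band on a phantom location is called reliable", {
  spec <- phantom_spec()
  truth <- radial_ground_truth_profile(spec, 100)
  ps <- noisy_profile_set(truth, n = 30, sd = 5, seed = 6)
  res <- analyze_location(ps, band_config(n_boot = 300, rng_seed = 8,
                                          n_tests = 12))
  expect_gt(res$boot_proportion, 0.9)
  expect_true(res$significant)
  expect_true(res$min_depth_ci[1] <= 0.5 && res$min_depth_ci[2] >= 0.5)
  g <- glance(res)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1)
  expect_equal(g$boot_proportion, res$boot_proportion)
  td <- tidy(res)
  expect_equal(nrow(td), 300)
  expect_named(td, c("replicate", "found", "min_depth", "start_depth"))
})

test_that("bootstrap CI bounds bracket the median", {
  spec <- phantom_spec()
  truth <- radial_ground_truth_profile(spec, 100)
  ps <- noisy_profile_set(truth, n = 25, sd = 4, seed = 14)
  res <- bootstrap_band(ps, band_config(n_boot = 200, rng_seed = 3))
  expect_lte(res$min_depth_ci[1], res$min_depth_median)
  expect_gte(res$min_depth_ci[2], res$min_depth_median)
  expect_gte(res$amplitude, 0)
})
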