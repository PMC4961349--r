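#' Band detection configuration
#'
#' Parameters of the hypo-intense band detector: cubic smoothing-spline
#' parameter, bootstrap size, and the reliability test. Defaults are the
#' reference analysis settings (spar 0.55, 2000 bootstrap repetitions,
#' null proportion 75%, 95% CI).
#'
#' @param spar smoothing parameter of [stats::smooth.spline()] in \[0, 1\]
#'   (0 is near interpolation, 1 heavy smoothing).
#' @param n_boot bootstrap repetitions (resampling profiles with
#'   replacement).
#' @param null_prop null proportion for the test of given proportions: a
#'   band is reliable when the proportion of bootstrap replicates showing it
#'   statistically exceeds this value.
#' @param alpha significance level before multiplicity correction.
#' @param n_tests Bonferroni family size (e.g. the number of locations
#'   analysed together).
#' @param ci_level coverage of the bootstrap percentile CI.
#' @param correct use the Yates continuity correction in the proportion
#'   test?
#' @param rng_seed bootstrap RNG seed.
#' @return A list of class `band_config`.
#' @export
band_config <- function(spar = 0.55, n_boot = 2000L, null_prop = 0.75,
                        alpha = 0.05, n_tests = 1L, ci_level = 0.95,
                        correct = TRUE, rng_seed = 1L) {
  stopifnot(spar >= 0, spar <= 1, n_boot >= 1, null_prop > 0,
            null_prop < 1, alpha > 0, alpha < 1, n_tests >= 1,
            ci_level > 0, ci_level < 1)
  structure(list(spar = spar, n_boot = as.integer(n_boot),
                 null_prop = null_prop, alpha = alpha,
                 n_tests = as.integer(n_tests), ci_level = ci_level,
                 correct = isTRUE(correct), rng_seed = as.integer(rng_seed)),
            class = "band_config")
}

#' Average the profiles of a location
#'
#' @param ps a `profile_set` (or a profiles-by-depths matrix).
#' @return Numeric mean profile, one value per depth step.
#' @export
average_profiles <- function(ps) {
  m <- if (is.matrix(ps)) ps else profile_matrix(ps)
  if (is.null(m) || nrow(m) == 0) stop("empty profile set")
  if (any(!is.finite(m))) stop("non-finite profile values")
  colMeans(m)
}

#' Smooth a mean profile with a cubic smoothing spline
#'
#' Fits [stats::smooth.spline()] over the uniform depth grid \[0, 1\] with
#' the given `spar` and returns the fitted values together with the
#' analytic first derivative of the spline on the same grid. Smoothing
#' low-passes the profile so the derivative's zero crossings are stable.
#'
#' @param mean_profile numeric vector (length >= 4).
#' @param spar smoothing parameter in \[0, 1\].
#' @return A list with `depths`, `smoothed` and `derivative`.
#' @export
smooth_profile <- function(mean_profile, spar = 0.55) {
  n <- length(mean_profile)
  stopifnot(n >= 4)
  if (any(!is.finite(mean_profile))) stop("non-finite profile values")
  depths <- seq(0, 1, length.out = n)
  fit <- stats::smooth.spline(depths, mean_profile, spar = spar,
                              cv = NA, keep.data = FALSE)
  list(depths = depths,
       smoothed = stats::predict(fit, depths)$y,
       derivative = stats::predict(fit, depths, deriv = 1)$y)
}

#' Locate the hypo-intense band from derivative zero crossings
#'
#' Scans the smoothed profile's first derivative from the WM border (depth
#' 0) toward CSF (depth 1). The band minimum is the first negative-to-
#' positive zero crossing; the band start is the first positive-to-negative
#' crossing occurring before it (absent if none, in which case the
#' depth-0 profile value serves as the amplitude reference). Crossings are
#' localised by linear interpolation of the derivative between the two
#' bracketing samples, and count only when both bracketing samples lie at
#' interior depths (strictly inside (0, 1)). Exact-zero derivative samples
#' are treated as part of the preceding sign regime, so plateaus cannot
#' create duplicate crossings.
#'
#' @param smoothed fitted profile values on the uniform depth grid.
#' @param derivative spline first derivative on the same grid.
#' @return A list of class `band_features`: `found`, `start_depth` (may be
#'   `NA`), `min_depth`, `start_intensity`, `min_intensity`,
#'   `start_absent`.
#' @export
find_band <- function(smoothed, derivative) {
  n <- length(derivative)
  stopifnot(length(smoothed) == n, n >= 4)
  depths <- seq(0, 1, length.out = n)
  s <- sign(derivative)
  for (i in 2:n) if (s[i] == 0) s[i] <- s[i - 1]
  none <- list(found = FALSE, start_depth = NA_real_, min_depth = NA_real_,
               start_intensity = NA_real_, min_intensity = NA_real_,
               start_absent = NA)
  class(none) <- "band_features"
  # candidate crossings between samples i, i+1 with both interior
  interior <- function(i) i >= 2 && (i + 1) <= (n - 1)
  cross_at <- function(i) {
    # linear interpolation of the derivative to its zero
    depths[i] + (0 - derivative[i]) /
      (derivative[i + 1] - derivative[i]) * (depths[i + 1] - depths[i])
  }
  value_at <- function(d) stats::approx(depths, smoothed, xout = d)$y
  min_i <- NA_integer_
  for (i in 2:(n - 2)) {
    if (s[i] < 0 && s[i + 1] > 0 && interior(i)) { min_i <- i; break }
  }
  if (is.na(min_i)) return(none)
  min_depth <- cross_at(min_i)
  start_i <- NA_integer_
  if (min_i > 2) {
    for (i in 2:(min_i - 1)) {
      if (s[i] > 0 && s[i + 1] < 0 && interior(i)) { start_i <- i; break }
    }
  }
  if (!is.na(start_i)) {
    start_depth <- cross_at(start_i)
    start_intensity <- value_at(start_depth)
    start_absent <- FALSE
  } else {
    start_depth <- NA_real_
    start_intensity <- smoothed[1]  # reference at depth 0
    start_absent <- TRUE
  }
  out <- list(found = TRUE, start_depth = start_depth,
              min_depth = min_depth,
              start_intensity = start_intensity,
              min_intensity = value_at(min_depth),
              start_absent = start_absent)
  class(out) <- "band_features"
  out
}

# average + smooth + find, the per-replicate unit of work
band_features_of <- function(m, spar) {
  sp <- smooth_profile(colMeans(m), spar)
  find_band(sp$smoothed, sp$derivative)
}

#' Bootstrap the band detection over profiles
#'
#' Resamples profiles (not depth points) with replacement to the original
#' count; each replicate is averaged, spline-smoothed and scanned for the
#' band. Reports the proportion of replicates in which a band was found,
#' and the median and percentile CI of the band-minimum depth among
#' replicates where it was. Features of the non-resampled mean profile give
#' the headline band location and amplitude (start intensity minus minimum
#' intensity). Deterministic given `cfg$rng_seed`.
#'
#' @param ps a `profile_set`.
#' @param cfg a [band_config()].
#' @return A list of class `band_result`.
#' @export
bootstrap_band <- function(ps, cfg = band_config()) {
  m <- if (is.matrix(ps)) ps else profile_matrix(ps)
  if (is.null(m) || nrow(m) == 0) stop("empty profile set")
  np <- nrow(m)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$rng_seed)
  draw <- matrix(sample.int(np, np * cfg$n_boot, replace = TRUE),
                 nrow = cfg$n_boot)
  reps <- purrr::map(seq_len(cfg$n_boot), function(b) {
    ft <- band_features_of(m[draw[b, ], , drop = FALSE], cfg$spar)
    tibble::tibble(replicate = b, found = ft$found,
                   min_depth = ft$min_depth, start_depth = ft$start_depth)
  })
  boot <- dplyr::bind_rows(reps)
  found <- boot$found
  boot_proportion <- mean(found)
  if (any(found)) {
    md <- boot$min_depth[found]
    qs <- stats::quantile(md, probs = c((1 - cfg$ci_level) / 2, 0.5,
                                        (1 + cfg$ci_level) / 2),
                          names = FALSE, type = 7)
    min_depth_median <- qs[2]
    min_depth_ci <- c(qs[1], qs[3])
  } else {
    min_depth_median <- NA_real_
    min_depth_ci <- c(NA_real_, NA_real_)
  }
  fm <- band_features_of(m, cfg$spar)
  amplitude <- if (fm$found) fm$start_intensity - fm$min_intensity
               else NA_real_
  structure(list(
    location_id = if (!is.matrix(ps) && nrow(ps) > 0)
      ps$location_id[1] else "loc",
    n_profiles = np,
    features_mean = fm,
    boot = boot,
    boot_proportion = boot_proportion,
    min_depth_median = min_depth_median,
    min_depth_ci = min_depth_ci,
    amplitude = amplitude,
    prop_p_value = NA_real_,
    significant = NA,
    config = cfg
  ), class = "band_result")
}

#' Test of given proportions
#'
#' One-sided (greater) test of H0: p <= `null_prop` for `successes` out of
#' `trials`, via the chi-square test of given proportions
#' ([stats::prop.test()]), with the Yates continuity correction by default.
#'
#' @param successes,trials counts.
#' @param null_prop null proportion.
#' @param correct apply the continuity correction?
#' @return The p-value.
#' @export
proportion_test <- function(successes, trials, null_prop = 0.75,
                            correct = TRUE) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials)
  stats::prop.test(successes, trials, p = null_prop,
                   alternative = "greater", correct = correct)$p.value
}

#' Full band analysis for one location
#'
#' Runs [bootstrap_band()], then tests whether the proportion of bootstrap
#' replicates showing a band exceeds `cfg$null_prop`, Bonferroni-corrected
#' across `cfg$n_tests` locations. The reliability call is `significant`;
#' the headline quantities reported downstream are the band-location median
#' and CI (not the p-value, which is computed on bootstrap counts).
#'
#' @param ps a `profile_set`.
#' @param cfg a [band_config()].
#' @return A `band_result` with `prop_p_value` and `significant` filled in.
#' @export
analyze_location <- function(ps, cfg = band_config()) {
  res <- bootstrap_band(ps, cfg)
  successes <- round(res$boot_proportion * cfg$n_boot)
  res$prop_p_value <- proportion_test(successes, cfg$n_boot,
                                      cfg$null_prop, cfg$correct)
  res$significant <- res$prop_p_value < cfg$alpha / cfg$n_tests
  res
}

#' @export
print.band_result <- function(x, ...) {
  cat(sprintf("<band_result> location %s, %d profiles\n", x$location_id,
              x$n_profiles))
  cat(sprintf("  band found in %.1f%% of %d bootstrap replicates%s\n",
              100 * x$boot_proportion, x$config$n_boot,
              if (isTRUE(x$significant)) " (reliable)" else ""))
  if (!is.na(x$min_depth_median)) {
    cat(sprintf("  band minimum depth: median %.3f, %d%% CI [%.3f, %.3f]\n",
                x$min_depth_median, round(100 * x$config$ci_level),
                x$min_depth_ci[1], x$min_depth_ci[2]))
  }
  if (!is.na(x$amplitude)) {
    cat(sprintf("  amplitude (start - minimum): %.3f\n", x$amplitude))
  }
  invisible(x)
}

#' Tidy the bootstrap replicates of a band result
#'
#' @param x a `band_result`.
#' @param ... unused.
#' @return Tibble with one row per bootstrap replicate (`replicate`,
#'   `found`, `min_depth`, `start_depth`).
#' @importFrom generics tidy
#' @export
tidy.band_result <- function(x, ...) {
  x$boot
}

#' One-row summary of a band result
#'
#' @param x a `band_result`.
#' @param ... unused.
#' @return One-row tibble with the location's detection summary.
#' @importFrom generics glance
#' @export
glance.band_result <- function(x, ...) {
  tibble::tibble(
    location_id = x$location_id,
    n_profiles = x$n_profiles,
    boot_proportion = x$boot_proportion,
    prop_p_value = x$prop_p_value,
    significant = x$significant,
    min_depth = x$features_mean$min_depth,
    min_depth_median = x$min_depth_median,
    min_depth_ci_low = x$min_depth_ci[1],
    min_depth_ci_high = x$min_depth_ci[2],
    start_depth = x$features_mean$start_depth,
    amplitude = x$amplitude
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance
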