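#' Plot a profile set
#'
#' One grey line per profile over relative cortical depth (0 = GM/WM
#' border, 1 = GM/CSF border) with the mean profile overlaid.
#'
#' @param object a `profile_set`.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.profile_set <- function(object, ...) {
  depths <- attr(object, "depths")
  long <- tibble::tibble(
    profile = rep(seq_len(nrow(object)),
                  each = length(depths)),
    depth = rep(depths, nrow(object)),
    intensity = unlist(object$intensities)
  )
  mean_df <- tibble::tibble(depth = depths,
                            intensity = average_profiles(object))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth, y = .data$intensity,
                                     group = .data$profile)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40") +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       linewidth = 1, colour = "black") +
    ggplot2::labs(x = "relative cortical depth (WM → CSF)",
                  y = "T1-w intensity (a.u.)",
                  title = object$location_id[1]) +
    ggplot2::theme_minimal()
}

#' Plot a band detection result
#'
#' Mean profile with across-profile standard-deviation error bars at a
#' subset of depths, the smoothed spline fit, and (when a band was found)
#' vertical lines at the bootstrap median band-minimum depth and its CI.
#'
#' @param object a `band_result`.
#' @param profile_set optionally the `profile_set` it was computed from,
#'   for the error bars; otherwise only the smoothed mean is drawn.
#' @param n_errorbars number of depths at which to draw error bars.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.band_result <- function(object, profile_set = NULL,
                                 n_errorbars = 13, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::labs(x = "relative cortical depth (WM → CSF)",
                  y = "T1-w intensity (a.u.)",
                  title = sprintf(
                    "%s: band in %.1f%% of bootstrap replicates%s",
                    object$location_id, 100 * object$boot_proportion,
                    if (isTRUE(object$significant)) " (reliable)" else "")) +
    ggplot2::theme_minimal()
  if (!is.null(profile_set)) {
    depths <- attr(profile_set, "depths")
    m <- do.call(rbind, profile_set$intensities)
    pick <- unique(round(seq(1, length(depths), length.out = n_errorbars)))
    eb <- tibble::tibble(depth = depths[pick],
                         mean = colMeans(m)[pick],
                         sd = apply(m, 2, stats::sd)[pick])
    p <- p +
      ggplot2::geom_errorbar(
        data = eb,
        ggplot2::aes(x = .data$depth, ymin = .data$mean - .data$sd,
                     ymax = .data$mean + .data$sd),
        width = 0.015, colour = "grey50") +
      ggplot2::geom_point(data = eb,
                          ggplot2::aes(x = .data$depth, y = .data$mean))
    sm <- smooth_profile(colMeans(m), object$config$spar)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(depth = sm$depths, intensity = sm$smoothed),
      ggplot2::aes(x = .data$depth, y = .data$intensity), linewidth = 0.8)
  }
  if (!is.na(object$min_depth_median)) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$min_depth_median,
                          colour = "red", linewidth = 0.8) +
      ggplot2::geom_vline(xintercept = object$min_depth_ci,
                          colour = "red", linetype = "dashed")
  }
  p
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
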