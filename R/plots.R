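#' Plot the permutation null of a signal test
#'
#' Histogram of the null contrast variances with the observed variance
#' marked; signal shows as an observed value in the lower tail.
#'
#' @param object A `signal_test`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot signal_test
#' @export
autoplot.signal_test <- function(object, ...) {
  df <- tibble(null_var = object$null_vars)
  ggplot(df, aes(x = .data$null_var)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$var_obs, colour = "red", linewidth = 1) +
    labs(x = "contrast variance (null reshuffles)", y = "count",
         title = sprintf("K = %.3f, p = %.3g", object$K, object$p_value)) +
    theme_minimal()
}

#' Scatter of independent contrasts with the through-origin fit
#'
#' @param cx,cy `pic_contrasts` for the two traits (same tree).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_pic_correlation <- function(cx, cy, xlab = "contrasts (x)",
                                 ylab = "contrasts (y)") {
  slope <- sum(cx$contrast * cy$contrast) / sum(cx$contrast^2)
  df <- tibble(x = cx$contrast, y = cy$contrast)
  ggplot(df, aes(.data$x, .data$y)) +
    geom_point(alpha = 0.7) +
    geom_abline(intercept = 0, slope = slope, colour = "red") +
    labs(x = xlab, y = ylab,
         title = sprintf("r (through origin) = %.3f", pic_correlation(cx, cy))) +
    theme_minimal()
}

#' Fitted mean log recombination rate per life-form
#'
#' Point-range plot (mean +/- 1 SE) of the fitted per-life-form means of a
#' comparative model, in the style of a fitted-group-means figure.
#'
#' @param fit A `phylo_gls` fit (or precomputed output of
#'   [fitted_group_means()]).
#' @param at_He Optional He value at which means are evaluated.
#' @return A ggplot object.
#' @export
plot_group_means <- function(fit, at_He = NULL) {
  gm <- if (is.data.frame(fit)) fit else fitted_group_means(fit, at_He = at_He)
  ggplot(gm, aes(x = .data$life_form, y = .data$mean)) +
    geom_pointrange(aes(ymin = .data$mean - .data$se,
                        ymax = .data$mean + .data$se)) +
    labs(x = NULL, y = "fitted log recombination rate (cM/Mb)") +
    theme_minimal()
}
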