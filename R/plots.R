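#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-correlation histogram
#'
#' Bars are the binned recurrence-interval counts over the +/-100 ms
#' analysis window; the horizontal line marks the baseline mean (the
#' chance-level count estimated far from zero lag). When a `peak` is
#' supplied its bins are highlighted.
#'
#' @param object A `correlogram`.
#' @param peak Optional `peak_region` to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlogram
#' @export
autoplot.correlogram <- function(object, peak = NULL, ...) {
  w <- window_bins(object)
  bw <- attr(object, "binwidth")
  w$in_peak <- if (is.null(peak)) FALSE else w$bin_left %in% peak$bin_lefts
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$bin_left + bw / 2,
                                       y = .data$count,
                                       fill = .data$in_peak)) +
    ggplot2::geom_col(width = bw, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35",
                                          `TRUE` = "steelblue")) +
    ggplot2::geom_hline(yintercept = attr(object, "baseline_mean"),
                        colour = "red") +
    ggplot2::labs(x = "recurrence interval (s)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(peak) && peak$n_bins > 0) {
    p <- p + ggplot2::geom_vline(xintercept = peak$boundaries,
                                 colour = "blue", linetype = 2)
  }
  p
}

#' Plot the normalized cumulative sum of a correlogram
#'
#' The plot used for investigator-judged peak boundaries: a
#' synchronization peak shows as a steep positive deflection near lag 0.
#'
#' @param hist A `correlogram`.
#' @return A ggplot.
#' @export
plot_cumsum <- function(hist) {
  cs <- normalized_cumsum(hist)
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$bin_left, y = .data$cusum)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60", linetype = 3) +
    ggplot2::labs(x = "recurrence interval (s)",
                  y = "normalized cumulative sum") +
    ggplot2::theme_minimal()
}

#' Plot a synchronization analysis
#'
#' Shows the correlogram with the peak of the requested method
#' highlighted.
#'
#' @param object A `synch_analysis`.
#' @param method Which computed method's peak to highlight (default: the
#'   first one computed).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synch_analysis
#' @export
autoplot.synch_analysis <- function(object, method = NULL, ...) {
  method <- method %||% names(object$peaks)[1]
  if (!method %in% names(object$peaks)) {
    stop(sprintf("method '%s' was not computed", method), call. = FALSE)
  }
  autoplot(object$correlogram, peak = object$peaks[[method]]) +
    ggplot2::ggtitle(sprintf("%s peak", method))
}

#' @importFrom rlang .data %||%
NULL
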