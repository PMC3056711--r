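#' Plot a closed-loop experiment log
#'
#' Stacked base-graphics panels in the style of the closed-loop figures:
#' per-trial target and success stems, the per-step action values, and the
#' per-step evaluative feedback.
#'
#' @param x an `experiment_log`.
#' @param which panels to draw, a subset of `c("trials", "values",
#'   "feedback")`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.experiment_log <- function(x, which = c("trials", "values", "feedback"),
                                ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  if ("trials" %in% which) {
    tr <- x$trials
    plot(tr$trial, tr$target, type = "h", col = "red", ylim = c(0, 4.5),
         xlab = "trial", ylab = "target / success")
    graphics::points(tr$trial, as.numeric(tr$success), type = "h",
                     col = "blue")
  }
  if ("values" %in% which && !is.null(x$values)) {
    graphics::matplot(x$values, type = "l", lty = 1, xlab = "step",
                      ylab = "action value")
  }
  if ("feedback" %in% which) {
    plot(x$steps$feedback, type = "l", col = "darkgreen", xlab = "step",
         ylab = "evaluative feedback")
  }
  invisible(x)
}

#' Plot a perievent time histogram
#'
#' @param x a `peth`.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.peth <- function(x, ...) {
  graphics::barplot(x$mean_rate, names.arg = sprintf("%.1f", x$bin_centers),
                    xlab = "time from event (s)", ylab = "rate (Hz)", ...)
  invisible(x)
}
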