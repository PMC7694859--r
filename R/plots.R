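# Scatter + prediction-interval plots (illustrative, base graphics).

#' Scatter plot with allometric mean and prediction band
#'
#' Plots measurements against body weight with the fitted mean curve and
#' the 95% prediction band superimposed; optionally restricted to one
#' breed.
#'
#' @param cohort Cohort to plot.
#' @param fit \code{allometric_fit} defining curve and band.
#' @param breed Optional breed to highlight (others drawn gray).
#' @param method PI method (default \code{"exact"}).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the grid data frame of curve values.
#' @export
plot_pi <- function(cohort, fit, breed = NULL,
                    method = c("exact", "approx"), ...) {
  method <- match.arg(method)
  v <- fit$variable
  ok <- !is.na(cohort[[v]]) & !is.na(cohort$bw_kg)
  d <- cohort[ok, , drop = FALSE]
  grid <- seq(min(d$bw_kg), max(d$bw_kg), length.out = 200)
  pi <- prediction_interval(fit, grid, method)
  col <- if (is.null(breed)) "grey40" else
    ifelse(d$breed == breed, "steelblue", "grey80")
  graphics::plot(d$bw_kg, d[[v]], pch = 16, cex = 0.4, col = col,
                 xlab = "Body weight (kg)",
                 ylab = paste0(mm_label(v), " (cm)"), ...)
  graphics::lines(grid, pi$mean, lwd = 2)
  graphics::lines(grid, pi$lower, lty = 2)
  graphics::lines(grid, pi$upper, lty = 2)
  invisible(pi)
}
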