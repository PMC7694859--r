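# Penalized B-spline (P-spline) smoother: cubic B-spline basis on equally
# spaced knots with a 2nd-order difference penalty, smoothing parameter by
# GCV over a log-spaced grid. Used to validate linearity of the allometric
# model and to compare groups.

default_lambda_grid <- function() 10^seq(-4, 6, length.out = 31)

#' Fit a penalized B-spline smoother
#'
#' Cubic B-splines on equally spaced knots spanning \code{[min(x), max(x)]}
#' with a second-order difference penalty on adjacent coefficients. Because
#' the penalty's null space contains straight lines, the fit reproduces any
#' exactly-linear signal regardless of lambda — the property the linearity
#' diagnostic relies on. If \code{lambda} is not supplied it is chosen by
#' minimizing GCV, \code{n * RSS / (n - edf)^2}, over a log-spaced grid
#' (10^-4 to 10^6, 31 points).
#'
#' @param x,y Numeric vectors of equal length; \code{x} finite with
#'   positive range; at least \code{n_knots + 4} points.
#' @param n_knots Number of interior knots (default 20).
#' @param lambda Optional fixed smoothing parameter (nonnegative).
#' @param lambda_grid Grid searched when \code{lambda} is missing.
#' @return A \code{pspline_fit}: knots, coefficients, \code{lambda},
#'   \code{edf} (trace of the smoother matrix), \code{gcv}, \code{rss},
#'   fitted values and the searched grid (with per-lambda GCV) when
#'   applicable.
#' @export
fit_pspline <- function(x, y, n_knots = 20, lambda = NULL,
                        lambda_grid = default_lambda_grid()) {
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite input", call. = FALSE)
  }
  n <- length(x)
  if (n < n_knots + 4L) {
    stop("need at least n_knots + 4 = ", n_knots + 4L, " points",
         call. = FALSE)
  }
  xl <- min(x); xr <- max(x)
  if (xr <= xl) stop("x has zero range", call. = FALSE)
  d <- (xr - xl) / (n_knots + 1)
  knots <- xl + d * seq(-3L, n_knots + 4L)
  # pin the inner boundary knots to the data range exactly, so the extreme
  # x values never fall outside the basis support by floating-point error
  knots[4L] <- xl
  knots[length(knots) - 3L] <- xr
  B <- splines::splineDesign(knots, x, ord = 4)
  K <- ncol(B)
  D <- diff(diag(K), differences = 2)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)

  solve_for <- function(lam) {
    M <- BtB + lam * P
    beta <- solve(M, Bty)
    fitted <- drop(B %*% beta)
    rss <- sum((y - fitted)^2)
    edf <- sum(diag(solve(M, BtB)))
    list(beta = drop(beta), fitted = fitted, rss = rss, edf = edf,
         gcv = n * rss / (n - edf)^2)
  }

  grid_gcv <- NULL
  if (is.null(lambda)) {
    fits <- lapply(lambda_grid, solve_for)
    grid_gcv <- vapply(fits, `[[`, numeric(1), "gcv")
    best <- which.min(grid_gcv)
    lambda <- lambda_grid[best]
    sol <- fits[[best]]
  } else {
    stopifnot(lambda >= 0)
    sol <- solve_for(lambda)
  }

  structure(list(
    knots = knots, basis_order = 4L, penalty_order = 2L,
    coefficients = sol$beta, lambda = lambda,
    edf = sol$edf, gcv = sol$gcv, rss = sol$rss,
    fitted = sol$fitted, x_range = c(xl, xr),
    lambda_grid = if (is.null(grid_gcv)) NULL else
      data.frame(lambda = lambda_grid, gcv = grid_gcv)
  ), class = "pspline_fit")
}

#' @export
print.pspline_fit <- function(x, ...) {
  cat(sprintf("<pspline_fit> %d basis functions, lambda = %.4g, edf = %.2f, GCV = %.4g\n",
              length(x$coefficients), x$lambda, x$edf, x$gcv))
  invisible(x)
}

#' @export
predict.pspline_fit <- function(object, newx, ...) {
  r <- object$x_range
  if (any(newx < r[1] - 1e-8) || any(newx > r[2] + 1e-8)) {
    stop("prediction outside the fitted x range", call. = FALSE)
  }
  newx <- pmin(pmax(newx, r[1]), r[2])
  B <- splines::splineDesign(object$knots, newx, ord = object$basis_order)
  drop(B %*% object$coefficients)
}

#' Check linearity of an allometric model with a P-spline smooth
#'
#' Fits the measurement (original scale) as a smooth function of
#' \code{BW^b} and compares the smooth to the straight line in
#' \code{BW^b} fitted by OLS. If the allometric model is adequate the two
#' coincide; curvature of the smooth relative to the line signals model
#' inadequacy. The comparison is the maximum absolute deviation between
#' smooth and line, relative to the range of the fitted line, over the
#' central 98% of the predictor span — an operationalization of the usual
#' visual inspection of the fitted prediction line.
#'
#' @param fit An \code{allometric_fit} (supplies b and the variable).
#' @param cohort Cohort the check is run on.
#' @param threshold Verdict threshold for the maximum relative deviation
#'   (default 0.02).
#' @param n_knots Passed to [fit_pspline()].
#' @return A \code{linearity_report}: \code{variable}, \code{max_rel_dev},
#'   \code{edf}, \code{verdict} (\code{TRUE} = adequate),
#'   \code{threshold}.
#' @export
linearity_check <- function(fit, cohort, threshold = 0.02, n_knots = 20) {
  v <- fit$variable
  ok <- !is.na(cohort[[v]]) & !is.na(cohort$bw_kg)
  x <- cohort$bw_kg[ok]^fit$b
  y <- cohort[[v]][ok]
  ps <- fit_pspline(x, y, n_knots = n_knots)
  line <- lm(y ~ x)
  grid <- seq(quantile(x, 0.01, type = 7), quantile(x, 0.99, type = 7),
              length.out = 200)
  smooth_hat <- predict(ps, grid)
  line_hat <- coef(line)[1] + coef(line)[2] * grid
  span <- diff(range(line_hat))
  if (span <= 0) span <- max(abs(line_hat), 1e-12)
  max_rel_dev <- max(abs(smooth_hat - line_hat)) / span
  structure(list(
    variable = v, max_rel_dev = max_rel_dev, edf = ps$edf,
    verdict = max_rel_dev < threshold, threshold = threshold
  ), class = "linearity_report")
}

#' @export
print.linearity_report <- function(x, ...) {
  cat(sprintf("<linearity_report> %s: max relative deviation %.4f (threshold %.3f) -> %s\n",
              mm_label(x$variable), x$max_rel_dev, x$threshold,
              if (x$verdict) "adequate" else "NOT adequate"))
  invisible(x)
}

#' Mean difference in upper PI limits between two groups
#'
#' Fits the allometric model in each cohort, evaluates the exact 95% upper
#' prediction-interval limit on a common body-weight grid, and reports the
#' average difference (group A minus group B) across the grid — the effect
#' estimate used to decide whether two cohort definitions yield materially
#' different reference limits. When the mgcv package is available a
#' companion joint additive model with a group indicator and a shared
#' P-spline smooth of BW is also fitted and its group coefficient (cm)
#' reported.
#'
#' @param cohort_a,cohort_b The two cohorts.
#' @param variable Measurement to compare.
#' @param bw_grid Body-weight grid; default 50 points over the overlap of
#'   the two BW ranges.
#' @return A \code{group_comparison}: \code{mean_diff} (cm),
#'   \code{grid} data frame (\code{bw_kg}, \code{upper_a}, \code{upper_b},
#'   \code{diff}), \code{group_effect} (joint-model coefficient or
#'   \code{NA}), and the two fits.
#' @export
group_upper_limit_difference <- function(cohort_a, cohort_b, variable,
                                         bw_grid = NULL) {
  if (nrow(cohort_a) == 0L || nrow(cohort_b) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  fit_a <- fit_allometric(cohort_a, variable)
  fit_b <- fit_allometric(cohort_b, variable)
  v <- fit_a$variable
  if (is.null(bw_grid)) {
    lo <- max(min(cohort_a$bw_kg), min(cohort_b$bw_kg))
    hi <- min(max(cohort_a$bw_kg), max(cohort_b$bw_kg))
    bw_grid <- seq(lo, hi, length.out = 50)
  }
  up_a <- prediction_interval(fit_a, bw_grid, "exact")$upper
  up_b <- prediction_interval(fit_b, bw_grid, "exact")$upper

  group_effect <- NA_real_
  if (requireNamespace("mgcv", quietly = TRUE)) {
    dat <- rbind(
      data.frame(y = cohort_a[[v]], bw = cohort_a$bw_kg, g = 0),
      data.frame(y = cohort_b[[v]], bw = cohort_b$bw_kg, g = 1)
    )
    dat <- dat[complete.cases(dat), ]
    gm <- mgcv::gam(y ~ g + s(bw, bs = "ps"), data = dat)
    group_effect <- -unname(coef(gm)["g"])  # A minus B, like mean_diff
  }

  structure(list(
    variable = v,
    mean_diff = mean(up_a - up_b),
    grid = data.frame(bw_kg = bw_grid, upper_a = up_a, upper_b = up_b,
                      diff = up_a - up_b),
    group_effect = group_effect,
    fit_a = fit_a, fit_b = fit_b
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: mean upper-limit difference %.4f cm over %d grid points\n",
              mm_label(x$variable), x$mean_diff, nrow(x$grid)))
  if (is.finite(x$group_effect)) {
    cat(sprintf("  joint-GAM group effect: %.4f cm\n", x$group_effect))
  }
  invisible(x)
}
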