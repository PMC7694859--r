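# The allometric model Y = a * BW^b and its prediction intervals.

#' Fit an allometric scaling model
#'
#' Ordinary least squares of \code{log(Y)} on \code{log(BW)} (natural
#' logs). The back-transformed intercept is the allometric constant
#' \code{a}, the slope is the scaling exponent \code{b}, and the residual
#' SD \code{sigma} (df = n - 2) measures multiplicative scatter. The
#' log-BW mean and centered sum of squares are stored so exact prediction
#' intervals (with the leverage term) can be computed later, along with the
#' two-sided Student-t quantile for the requested level.
#'
#' @param cohort An \code{echo_cohort} (or any data frame with
#'   \code{bw_kg}).
#' @param variable Measurement to model, e.g. \code{"lvdd_cm"} or
#'   \code{"LVDd"}.
#' @param level Prediction-interval level (default 0.95).
#' @return An \code{allometric_fit}: list with \code{variable}, \code{a},
#'   \code{b}, \code{sigma}, \code{n}, \code{r2}, \code{xbar_log},
#'   \code{sxx_log}, \code{t_crit}, \code{level}.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(seed = 1, n_total = 400))
#' fit_allometric(coh, "LVDd")
fit_allometric <- function(cohort, variable, level = 0.95) {
  variable <- match_mm_variable(variable)
  stopifnot(is.numeric(level), level > 0, level < 1)
  ok <- !is.na(cohort[[variable]]) & !is.na(cohort$bw_kg)
  y <- cohort[[variable]][ok]
  bw <- cohort$bw_kg[ok]
  n <- length(y)
  if (n < 3L) {
    stop("need at least 3 complete records to fit '", variable,
         "' (got ", n, "); the residual SD has df = n - 2", call. = FALSE)
  }
  if (any(y <= 0) || any(bw <= 0)) {
    stop("nonpositive measurement or body weight", call. = FALSE)
  }
  lx <- log(bw); ly <- log(y)
  if (var(lx) == 0) stop("zero body-weight variance", call. = FALSE)
  m <- lm(ly ~ lx)
  s <- summary(m)
  structure(list(
    variable = variable,
    a = exp(unname(coef(m)[1])),
    b = unname(coef(m)[2]),
    sigma = s$sigma,
    n = n,
    r2 = s$r.squared,
    xbar_log = mean(lx),
    sxx_log = sum((lx - mean(lx))^2),
    t_crit = qt(1 - (1 - level) / 2, df = n - 2),
    level = level
  ), class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> %s = %.4g * BW^%.4g  (n = %d, R2 = %.3f, sigma = %.4g)\n",
              mm_label(x$variable), x$a, x$b, x$n, x$r2, x$sigma))
  invisible(x)
}

#' Predicted mean of an allometric model
#'
#' @param fit An \code{allometric_fit} (or any list with \code{a},
#'   \code{b}).
#' @param bw_kg Body weight(s) in kg, positive.
#' @return Predicted value(s) \code{a * bw_kg^b} in cm.
#' @export
#' @examples
#' f <- list(a = 1.38, b = 0.322)
#' predict_mean(f, 30)  # 4.1 cm at 1 d.p.
predict_mean <- function(fit, bw_kg) {
  if (any(!is.finite(bw_kg)) || any(bw_kg <= 0)) {
    stop("body weight must be positive", call. = FALSE)
  }
  fit$a * bw_kg^fit$b
}

#' Prediction interval at a given body weight
#'
#' Exact method: on the log scale, \code{center +/- t * sigma *
#' sqrt(1 + 1/n + (log bw - xbar)^2 / Sxx)}, back-transformed — the
#' standard OLS prediction interval for a new observation. Approximate
#' method: \code{center +/- t * sigma}, i.e. the leverage term dropped;
#' equivalently the constants \code{a * exp(-t*sigma)} and
#' \code{a * exp(+t*sigma)} times \code{BW^b}, which is what makes
#' on-the-spot interval calculation from two indexing constants possible.
#' At screening-database sample sizes the two are indistinguishable in
#' practice.
#'
#' @param fit An \code{allometric_fit}.
#' @param bw_kg Body weight(s) in kg.
#' @param method \code{"exact"} or \code{"approx"}.
#' @return Data frame with one row per body weight: \code{bw_kg},
#'   \code{mean}, \code{lower}, \code{upper}, \code{level}, \code{method}.
#' @export
prediction_interval <- function(fit, bw_kg, method = c("exact", "approx")) {
  method <- match.arg(method)
  if (any(!is.finite(bw_kg)) || any(bw_kg <= 0)) {
    stop("body weight must be positive", call. = FALSE)
  }
  if (is.null(fit$sigma) || is.null(fit$t_crit)) {
    stop("fit lacks sigma/t_crit; use fit_allometric()", call. = FALSE)
  }
  lbw <- log(bw_kg)
  center <- log(fit$a) + fit$b * lbw
  if (method == "exact") {
    if (is.null(fit$xbar_log) || is.null(fit$sxx_log)) {
      stop("exact method needs stored xbar_log/sxx_log", call. = FALSE)
    }
    se <- fit$sigma * sqrt(1 + 1 / fit$n + (lbw - fit$xbar_log)^2 / fit$sxx_log)
  } else {
    se <- fit$sigma
  }
  half <- fit$t_crit * se
  data.frame(
    bw_kg = bw_kg,
    mean = exp(center),
    lower = exp(center - half),
    upper = exp(center + half),
    level = fit$level,
    method = method,
    stringsAsFactors = FALSE
  )
}

# ---- percentile indexing constants ----

#' Construct an index-constants object
#'
#' Constants c_p such that \code{c_p * BW^exponent} traces the p-th
#' percentile curve of a measurement. Validates that constants are
#' nondecreasing in percentile.
#'
#' @param variable Variable name (cohort column).
#' @param exponent Scaling exponent b.
#' @param percentiles Numeric vector of percentiles in (0, 100).
#' @param constants Positive numeric vector, same length, named by
#'   percentile.
#' @return An \code{index_constants} object.
#' @export
new_index_constants <- function(variable, exponent, percentiles, constants) {
  stopifnot(length(percentiles) == length(constants),
            all(percentiles > 0 & percentiles < 100),
            all(constants > 0))
  o <- order(percentiles)
  percentiles <- percentiles[o]
  constants <- constants[o]
  if (is.unsorted(constants)) {
    stop("indexing constants must be nondecreasing in percentile",
         call. = FALSE)
  }
  names(constants) <- as.character(percentiles)
  structure(list(variable = variable, exponent = exponent,
                 percentiles = percentiles, constants = constants),
            class = "index_constants")
}

#' @export
print.index_constants <- function(x, ...) {
  cat("<index_constants> ", mm_label(x$variable),
      " (exponent ", format(x$exponent), ")\n", sep = "")
  print(x$constants)
  invisible(x)
}

#' Empirical percentile indexing constants
#'
#' Computes the index \code{I_i = Y_i / BW_i^b} for every dog and returns
#' its empirical percentiles (type-7 quantiles, the same convention as the
#' outlier screen). The parametric alternative
#' \code{a * exp(z_p * sigma)} is available via \code{method =
#' "parametric"}; under lognormal residuals the two agree.
#'
#' @param fit An \code{allometric_fit} for the variable (supplies b).
#' @param cohort Cohort to take percentiles over.
#' @param percentiles Percentiles in (0, 100); default
#'   \code{c(2.5, 5, 25, 50, 75, 95, 97.5)}.
#' @param method \code{"empirical"} (default) or \code{"parametric"}.
#' @return An \code{index_constants} object.
#' @export
index_constants <- function(fit, cohort,
                            percentiles = c(2.5, 5, 25, 50, 75, 95, 97.5),
                            method = c("empirical", "parametric")) {
  method <- match.arg(method)
  stopifnot(all(percentiles > 0 & percentiles < 100))
  v <- fit$variable
  if (method == "parametric") {
    z <- qnorm(percentiles / 100)
    cons <- fit$a * exp(z * fit$sigma)
  } else {
    ok <- !is.na(cohort[[v]]) & !is.na(cohort$bw_kg)
    if (!any(ok)) stop("no complete records for ", v, call. = FALSE)
    idx <- cohort[[v]][ok] / cohort$bw_kg[ok]^fit$b
    cons <- quantile(idx, percentiles / 100, type = 7, names = FALSE)
  }
  new_index_constants(v, fit$b, percentiles,
                      setNames(cons, as.character(percentiles)))
}

# ---- prediction-interval tables ----

#' Reference-interval table over a body-weight grid
#'
#' One row per body weight with the mean and the 95% lower/upper bounds,
#' rounded to \code{digits} decimals (half-up, the convention of printed
#' reference tables). Accepts either an \code{allometric_fit} (approximate
#' PI from the fitted sigma) or an \code{index_constants} object (bounds
#' from the 2.5/97.5 constants, mean from the 50th).
#'
#' @param object \code{allometric_fit} or \code{index_constants}.
#' @param bw_grid Positive body weights (kg).
#' @param digits Decimals to round to (default 1; use \code{NULL} for
#'   unrounded values).
#' @return Data frame with \code{bw_kg}, \code{mean}, \code{lower},
#'   \code{upper} and a formatted \code{pretty} column
#'   \code{"mean (lower-upper)"}.
#' @export
#' @examples
#' cons <- reference_index_constants()$lvdd_cm
#' pi_table(cons, c(12, 25, 30))
pi_table <- function(object, bw_grid, digits = 1) {
  if (length(bw_grid) == 0L) stop("empty body-weight grid", call. = FALSE)
  if (any(!is.finite(bw_grid)) || any(bw_grid <= 0)) {
    stop("body weights must be positive", call. = FALSE)
  }
  if (inherits(object, "index_constants")) {
    cc <- object$constants
    need <- c("2.5", "50", "97.5")
    if (!all(need %in% names(cc))) {
      stop("index constants must include percentiles 2.5, 50 and 97.5",
           call. = FALSE)
    }
    scale <- bw_grid^object$exponent
    out <- data.frame(bw_kg = bw_grid,
                      mean = cc[["50"]] * scale,
                      lower = cc[["2.5"]] * scale,
                      upper = cc[["97.5"]] * scale)
  } else if (inherits(object, "allometric_fit") || !is.null(object$sigma)) {
    pi <- prediction_interval(object, bw_grid, method = "approx")
    out <- pi[, c("bw_kg", "mean", "lower", "upper")]
  } else {
    stop("object must be an allometric_fit or index_constants",
         call. = FALSE)
  }
  if (!is.null(digits)) {
    out$mean <- round_half_up(out$mean, digits)
    out$lower <- round_half_up(out$lower, digits)
    out$upper <- round_half_up(out$upper, digits)
  }
  fmt <- paste0("%.", if (is.null(digits)) 2 else digits, "f")
  out$pretty <- sprintf(paste0(fmt, " (", fmt, "-", fmt, ")"),
                        out$mean, out$lower, out$upper)
  rownames(out) <- NULL
  out
}

#' Weight-independent cutoff for weakly BW-associated variables
#'
#' Some variables (fractional shortening, typically) show almost no
#' association with body weight; a single percentile cutoff is then more
#' appropriate than a BW-dependent interval. Fits the allometric model and,
#' if its R-squared falls below \code{r2_gate}, returns the empirical
#' percentile of the raw values (type-7 quantiles); otherwise returns the
#' fit itself so the caller can build BW-dependent intervals.
#'
#' @param cohort Cohort.
#' @param variable Variable, e.g. \code{"fs_pct"}.
#' @param percentile Percentile for the cutoff (default 5).
#' @param r2_gate R-squared below which the variable is treated as
#'   weight-independent (default 0.1 — dimensional variables sit well above
#'   it, fractional shortening well below).
#' @return List of class \code{weight_cutoff} with \code{type}
#'   (\code{"cutoff"} or \code{"allometric"}), \code{value} (the cutoff, if
#'   applicable), \code{percentile}, \code{r2} and \code{fit}.
#' @export
weight_independent_cutoff <- function(cohort, variable, percentile = 5,
                                      r2_gate = 0.1) {
  variable <- if (variable %in% names(cohort)) variable else
    match_mm_variable(variable)
  stopifnot(percentile > 0, percentile < 100)
  vals <- cohort[[variable]]
  ok <- !is.na(vals) & !is.na(cohort$bw_kg)
  if (sum(ok) < 20L) {
    stop("need at least 20 complete records for '", variable, "'",
         call. = FALSE)
  }
  lx <- log(cohort$bw_kg[ok]); ly <- log(vals[ok])
  m <- summary(lm(ly ~ lx))
  # a (near-)constant response has no BW association, whatever numerical
  # R-squared the degenerate regression reports
  if (is.nan(m$r.squared) || var(ly) < 1e-20) m$r.squared <- 0
  fit <- structure(list(
    variable = variable, a = exp(unname(coef(m)[1, 1])),
    b = unname(coef(m)[2, 1]), sigma = m$sigma, n = sum(ok),
    r2 = m$r.squared, xbar_log = mean(lx),
    sxx_log = sum((lx - mean(lx))^2),
    t_crit = qt(0.975, df = sum(ok) - 2), level = 0.95
  ), class = "allometric_fit")
  if (m$r.squared < r2_gate) {
    structure(list(type = "cutoff",
                   value = quantile(vals[ok], percentile / 100, type = 7,
                                    names = FALSE),
                   percentile = percentile, r2 = m$r.squared, fit = fit),
              class = "weight_cutoff")
  } else {
    structure(list(type = "allometric", value = NA_real_,
                   percentile = percentile, r2 = m$r.squared, fit = fit),
              class = "weight_cutoff")
  }
}

#' @export
print.weight_cutoff <- function(x, ...) {
  if (x$type == "cutoff") {
    cat(sprintf("<weight_cutoff> weight-independent %.1f-percentile cutoff = %.2f (R2 = %.3f)\n",
                x$percentile, x$value, x$r2))
  } else {
    cat(sprintf("<weight_cutoff> BW-dependent (R2 = %.3f >= gate); see $fit\n",
                x$r2))
  }
  invisible(x)
}
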