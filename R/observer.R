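# Interobserver variability: share of residual variance attributable to a
# random examiner intercept, after removing the body-weight trend.

#' Interobserver variance decomposition
#'
#' Two-stage estimator of interobserver variability for one variable,
#' restricted to one breed (by default the largest, so breed differences
#' cannot masquerade as examiner effects): (1) the body-weight trend is
#' removed by a P-spline smooth of the log-transformed measurement on BW;
#' (2) on the detrended residuals a one-way random-intercept model
#' (examiner) is fitted by REML via \code{lme4::lmer}. The reported RVa is
#' the percentage of residual variance explained by the examiner effect,
#' \code{100 * s2_examiner / (s2_examiner + s2_residual)}. Working on the
#' log scale makes the decomposition invariant to rescaling the
#' measurement.
#'
#' @param cohort Cohort.
#' @param variable Measurement, e.g. \code{"LVWd"}.
#' @param breed Breed to restrict to; default the breed with most dogs.
#' @param n_knots Knots for the detrending smooth (default 10).
#' @return A \code{variance_decomposition}: \code{variable},
#'   \code{breed_used}, \code{sigma2_examiner}, \code{sigma2_residual}
#'   (log-scale), \code{rva_pct}, \code{n_examiners}, \code{n_dogs}.
#' @export
interobserver_rva <- function(cohort, variable, breed = NULL,
                              n_knots = 10) {
  variable <- if (variable %in% names(cohort)) variable else
    match_mm_variable(variable)
  if (is.null(breed)) {
    breed <- names(which.max(table(cohort$breed)))
  }
  d <- cohort[cohort$breed == breed, , drop = FALSE]
  d <- d[!is.na(d[[variable]]) & !is.na(d$bw_kg), , drop = FALSE]
  if (nrow(d) == 0L) stop("no data for breed '", breed, "'", call. = FALSE)
  ex_sizes <- table(d$examiner_id)
  if (sum(ex_sizes >= 2L) < 2L) {
    stop("need at least 2 examiners with at least 2 dogs each",
         call. = FALSE)
  }
  ly <- log(d[[variable]])
  # detrend; fall back to a straight line in log BW when the breed's BW
  # range is too narrow to support the spline basis
  res <- tryCatch({
    ps <- fit_pspline(d$bw_kg, ly, n_knots = n_knots)
    ly - ps$fitted
  }, error = function(e) resid(lm(ly ~ log(d$bw_kg))))

  vc_dat <- data.frame(r = res, examiner = factor(d$examiner_id))
  m <- lme4::lmer(r ~ 1 + (1 | examiner), data = vc_dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  s2_ex <- vc$vcov[vc$grp == "examiner"]
  s2_res <- vc$vcov[vc$grp == "Residual"]
  structure(list(
    variable = variable, breed_used = breed,
    sigma2_examiner = s2_ex, sigma2_residual = s2_res,
    rva_pct = 100 * s2_ex / (s2_ex + s2_res),
    n_examiners = length(unique(d$examiner_id)), n_dogs = nrow(d)
  ), class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition> %s in %s: RVa = %.1f%% (examiner %.3g, residual %.3g; %d examiners, %d dogs)\n",
              mm_label(x$variable), x$breed_used, x$rva_pct,
              x$sigma2_examiner, x$sigma2_residual,
              x$n_examiners, x$n_dogs))
  invisible(x)
}
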