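# Deviant-breed classification against the population prediction intervals.

#' Classify breeds by the fraction of measurements outside the population
#' prediction intervals
#'
#' For every breed and variable, evaluates the population PI at each dog's
#' body weight and counts strict exceedances above the upper and below the
#' lower bound (unrounded bounds). A breed is flagged deviant for a side if
#' the percentage exceeds \code{cutoff_pct} (strictly). The population fits
#' are applied to every breed — including sighthounds, which is precisely
#' how athletic-breed enlargement shows up. Dogs missing a measurement are
#' excluded from that variable's denominator.
#'
#' @param cohort Cohort to classify (typically all breeds incl.
#'   sighthounds).
#' @param fits Named list (by cohort column name) of \code{allometric_fit}
#'   or \code{index_constants} objects defining the population PIs.
#' @param cutoff_pct Deviance cutoff in percent (default 10).
#' @param pi_method Passed to [prediction_interval()] for fit objects
#'   (default \code{"exact"}).
#' @return A \code{breed_deviance} data frame: one row per breed x
#'   variable with \code{breed}, \code{sighthound}, \code{n} (nonmissing
#'   for that variable), \code{variable}, \code{pct_above},
#'   \code{pct_below} (1 d.p.), \code{deviant_above}, \code{deviant_below}.
#' @export
breed_deviance <- function(cohort, fits, cutoff_pct = 10,
                           pi_method = c("exact", "approx")) {
  pi_method <- match.arg(pi_method)
  stopifnot(is.list(fits), length(fits) > 0L)
  vars <- names(fits)
  missing_v <- setdiff(vars, names(cohort))
  if (length(missing_v) > 0L) {
    stop("cohort lacks variable(s): ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }

  bounds <- lapply(vars, function(v) {
    obj <- fits[[v]]
    if (inherits(obj, "index_constants")) {
      tab <- pi_table(obj, cohort$bw_kg, digits = NULL)
      cbind(lower = tab$lower, upper = tab$upper)
    } else {
      pi <- prediction_interval(obj, cohort$bw_kg, pi_method)
      cbind(lower = pi$lower, upper = pi$upper)
    }
  })
  names(bounds) <- vars

  rows <- list()
  for (br in unique(cohort$breed)) {
    in_br <- cohort$breed == br
    for (v in vars) {
      y <- cohort[[v]][in_br]
      lo <- bounds[[v]][in_br, "lower"]
      hi <- bounds[[v]][in_br, "upper"]
      keep <- !is.na(y)
      n <- sum(keep)
      pct_above <- if (n > 0) 100 * sum(y[keep] > hi[keep]) / n else NA_real_
      pct_below <- if (n > 0) 100 * sum(y[keep] < lo[keep]) / n else NA_real_
      pct_above <- round(pct_above, 1)
      pct_below <- round(pct_below, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        breed = br, sighthound = any(cohort$sighthound[in_br]),
        n = n, variable = v,
        pct_above = pct_above, pct_below = pct_below,
        deviant_above = isTRUE(pct_above > cutoff_pct),
        deviant_below = isTRUE(pct_below > cutoff_pct),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cutoff_pct") <- cutoff_pct
  class(out) <- c("breed_deviance", "data.frame")
  out
}

#' Wide-format breed deviance table
#'
#' Reshapes a [breed_deviance()] result to one row per breed with
#' above/below percentage columns per variable, sighthounds marked with an
#' asterisk — the layout of printed deviance tables.
#'
#' @param deviance A \code{breed_deviance} object.
#' @return Data frame, one row per breed.
#' @export
breed_deviance_wide <- function(deviance) {
  stopifnot(inherits(deviance, "breed_deviance"))
  d <- as.data.frame(deviance)
  breeds <- unique(d[, c("breed", "sighthound")])
  out <- data.frame(
    breed = ifelse(breeds$sighthound, paste0(breeds$breed, "*"),
                   breeds$breed),
    n = vapply(breeds$breed, function(b)
      max(d$n[d$breed == b]), numeric(1)),
    stringsAsFactors = FALSE)
  for (v in unique(d$variable)) {
    lab <- mm_label(v)
    sel <- d[d$variable == v, ]
    m <- match(breeds$breed, sel$breed)
    out[[paste0(lab, "_above_pct")]] <- sel$pct_above[m]
    out[[paste0(lab, "_below_pct")]] <- sel$pct_below[m]
  }
  rownames(out) <- NULL
  out
}
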