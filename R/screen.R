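# Quartile-fence outlier screening, stratified by breed.

#' Tukey-type quartile fences
#'
#' Fences at \code{Q1 - k*IQR} and \code{Q3 + k*IQR}. Quartiles use linear
#' interpolation between order statistics (the "type 7" convention, R's
#' default), which is documented and fixed so results are reproducible. The
#' default multiplier \code{k = 3} gives the wide "far out" fences used for
#' gross-error screening rather than the exploratory k = 1.5.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param k Fence multiplier (default 3).
#' @return Named numeric vector \code{c(low = , high = )}.
#' @export
#' @examples
#' quartile_fences(c(1, 2, 3, 4, 5, 100))  # (-5.25, 12.25)
quartile_fences <- function(values, k = 3) {
  if (any(!is.finite(values))) stop("non-finite input", call. = FALSE)
  if (length(values) < 4L) {
    stop("need at least 4 values to place quartile fences", call. = FALSE)
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(low = q[1] - k * iqr, high = q[2] + k * iqr)
}

#' Screen a cohort for gross outliers
#'
#' Applies [quartile_fences()] per breed stratum and variable. The six
#' dimensional variables are screened on the natural-log scale (they are
#' modeled there and right-skewed on the original scale); fractional
#' shortening is screened untransformed. Strata are breeds with at least
#' \code{min_stratum_n} dogs; all smaller breeds are pooled into one
#' stratum so every record is screened. Flagged values are set missing —
#' the dog is kept for its other measurements.
#'
#' @param cohort An \code{echo_cohort}.
#' @param min_stratum_n Minimum breed size for its own stratum (default 50).
#' @param k Fence multiplier, passed to [quartile_fences()].
#' @param screen_fs Screen fractional shortening too (default \code{TRUE})?
#' @return List with \code{cohort} (screened) and \code{report}, an
#'   \code{outlier_report} whose \code{fences} data frame gives per
#'   stratum/variable the fences on the analysis (log or raw) scale, the
#'   stratum size and the number flagged, whose \code{flagged} data frame
#'   lists every removed measurement (\code{dog_id}, \code{variable},
#'   \code{value}), and whose \code{total_removed} counts removed
#'   measurements (not dogs).
#' @export
screen_cohort <- function(cohort, min_stratum_n = 50, k = 3,
                          screen_fs = TRUE) {
  stopifnot(inherits(cohort, "echo_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)

  breed_n <- table(cohort$breed)
  big <- names(breed_n)[breed_n >= min_stratum_n]
  stratum <- ifelse(cohort$breed %in% big, cohort$breed, "(pooled)")

  vars <- names(.MM_VARS)
  if (screen_fs) vars <- c(vars, "fs_pct")

  fences <- list()
  flagged <- list()
  for (st in unique(stratum)) {
    in_st <- stratum == st
    for (v in vars) {
      vals <- cohort[[v]][in_st]
      present <- which(in_st)[!is.na(vals)]
      vals <- vals[!is.na(vals)]
      if (length(vals) < 4L) next
      on_log <- v != "fs_pct"
      x <- if (on_log) log(vals) else vals
      f <- quartile_fences(x, k = k)
      out <- x < f[["low"]] | x > f[["high"]]
      fences[[length(fences) + 1L]] <- data.frame(
        stratum = st, variable = v, scale = if (on_log) "log" else "raw",
        fence_low = f[["low"]], fence_high = f[["high"]],
        n = length(vals), n_flagged = sum(out), stringsAsFactors = FALSE)
      if (any(out)) {
        rows <- present[out]
        flagged[[length(flagged) + 1L]] <- data.frame(
          dog_id = cohort$dog_id[rows], stratum = st, variable = v,
          value = cohort[[v]][rows], stringsAsFactors = FALSE)
        cohort[[v]][rows] <- NA_real_
      }
    }
  }

  fences <- if (length(fences)) do.call(rbind, fences) else
    data.frame(stratum = character(), variable = character(),
               scale = character(), fence_low = numeric(),
               fence_high = numeric(), n = integer(), n_flagged = integer())
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(dog_id = character(), stratum = character(),
               variable = character(), value = numeric())
  rownames(fences) <- rownames(flagged) <- NULL

  report <- structure(
    list(fences = fences, flagged = flagged,
         total_removed = nrow(flagged), min_stratum_n = min_stratum_n,
         k = k),
    class = "outlier_report")
  list(cohort = cohort, report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", x$total_removed,
      " measurement(s) removed (k = ", x$k,
      ", breed strata with n >= ", x$min_stratum_n, ")\n", sep = "")
  if (x$total_removed > 0L) {
    tab <- table(x$flagged$variable)
    cat("  by variable:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
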