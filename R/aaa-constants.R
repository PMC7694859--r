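# Canonical M-mode variable set and published reference constants.

# column name -> display label
.MM_VARS <- c(
  lvdd_cm = "LVDd", lvds_cm = "LVDs",
  ivsd_cm = "IVSd", ivss_cm = "IVSs",
  lvwd_cm = "LVWd", lvws_cm = "LVWs"
)

#' Canonical M-mode dimension variables
#'
#' The six left-ventricular linear dimensions handled by the package, as the
#' cohort column names. Display labels (\code{"LVDd"}, ...) are attached as
#' names.
#'
#' @return Named character vector: values are cohort column names
#'   (\code{"lvdd_cm"}, ...), names are display labels.
#' @export
#' @examples
#' mm_variables()
mm_variables <- function() {
  setNames(names(.MM_VARS), unname(.MM_VARS))
}

# Accepts "lvdd_cm", "lvdd", "LVDd" (case-insensitive); returns column name.
match_mm_variable <- function(variable) {
  stopifnot(is.character(variable), length(variable) == 1L)
  v <- tolower(variable)
  if (v %in% names(.MM_VARS)) return(v)
  v2 <- paste0(v, "_cm")
  if (v2 %in% names(.MM_VARS)) return(v2)
  if (v %in% c("fs", "fs_pct")) return("fs_pct")
  stop("unknown M-mode variable: ", variable, call. = FALSE)
}

mm_label <- function(variable) {
  if (variable == "fs_pct") return("FS")
  unname(.MM_VARS[[variable]])
}

#' Published allometric coefficients for the nonsighthound dog population
#'
#' Coefficients of the allometric model Y = a * BW^b (Y in cm, BW in kg)
#' reported for a large multicenter screening population of nonsighthound
#' dogs, for both the full group (n = 6097) and its "immaculate" subgroup
#' (n = 1794). These are the defaults of the synthetic-cohort generator and
#' the reference against which parameter-recovery tests are run.
#'
#' @param group \code{"all"} (default) or \code{"immaculate"}.
#' @return Data frame with columns \code{variable}, \code{label}, \code{a},
#'   \code{b}, \code{r2}.
#' @seealso [reference_index_constants()], [default_truth()]
#' @export
#' @examples
#' reference_allometry()
reference_allometry <- function(group = c("all", "immaculate")) {
  group <- match.arg(group)
  if (group == "all") {
    out <- data.frame(
      variable = names(.MM_VARS),
      label = unname(.MM_VARS),
      a  = c(1.38, 0.87, 0.36, 0.51, 0.40, 0.60),
      b  = c(0.322, 0.346, 0.289, 0.276, 0.261, 0.247),
      r2 = c(0.766, 0.680, 0.494, 0.484, 0.465, 0.487),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      variable = names(.MM_VARS),
      label = unname(.MM_VARS),
      a  = c(1.32, 0.79, 0.35, 0.50, 0.37, 0.57),
      b  = c(0.335, 0.370, 0.299, 0.287, 0.278, 0.259),
      r2 = c(0.887, 0.827, 0.684, 0.661, 0.607, 0.634),
      stringsAsFactors = FALSE
    )
  }
  out
}

# percentiles used throughout for indexing constants
.INDEX_PERCENTILES <- c(2.5, 5, 25, 50, 75, 95, 97.5)

#' Published percentile indexing constants (all-nonsighthound group)
#'
#' Indexing constants c_p such that c_p * BW^b is the p-th percentile curve
#' of a measurement at body weight BW. Multiplying the 2.5th and 97.5th
#' constants by BW^b gives an approximate 95% prediction interval suitable
#' for bedside calculation.
#'
#' @return Named list of [index_constants] objects, one per dimension
#'   (names are the cohort column names).
#' @export
#' @examples
#' reference_index_constants()$lvdd_cm
reference_index_constants <- function() {
  tab <- list(
    #            2.5   5     25    50    75    95    97.5
    lvdd_cm = c(1.17, 1.20, 1.30, 1.38, 1.46, 1.59, 1.63),
    lvds_cm = c(0.70, 0.72, 0.81, 0.87, 0.94, 1.05, 1.09),
    ivsd_cm = c(0.27, 0.28, 0.33, 0.36, 0.40, 0.47, 0.49),
    ivss_cm = c(0.38, 0.40, 0.46, 0.51, 0.56, 0.65, 0.68),
    lvwd_cm = c(0.30, 0.31, 0.36, 0.40, 0.44, 0.51, 0.53),
    lvws_cm = c(0.46, 0.48, 0.55, 0.60, 0.65, 0.75, 0.78)
  )
  b <- setNames(reference_allometry()$b, reference_allometry()$variable)
  out <- lapply(names(tab), function(v) {
    new_index_constants(
      variable = v, exponent = b[[v]],
      percentiles = .INDEX_PERCENTILES,
      constants = setNames(tab[[v]], as.character(.INDEX_PERCENTILES))
    )
  })
  setNames(out, names(tab))
}

#' Indexing constants of Cornell et al. (2004) for LVDd
#'
#' The earlier allometric reference values commonly used in practice, shipped
#' for side-by-side comparison with the population constants in
#' [reference_index_constants()]. Exponent 0.294; the 95th-percentile
#' constant 1.70 corresponds to the normalized-LVDd cardiomegaly threshold
#' used in clinical trials.
#'
#' @return An [index_constants] object for LVDd.
#' @export
cornell_lvdd_constants <- function() {
  new_index_constants(
    variable = "lvdd_cm", exponent = 0.294,
    percentiles = c(2.5, 95, 97.5),
    constants = c("2.5" = 1.27, "95" = 1.70, "97.5" = 1.85)
  )
}

#' Round half away from zero
#'
#' The rounding convention of printed reference tables (base \code{round()}
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
#' @examples
#' round_half_up(c(3.45, 3.55))  # 3.5 3.6
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
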