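# Synthetic-cohort generator emulating a multicenter breeding-screen
# database: breed-specific body-weight distributions, lognormal
# multiplicative measurement noise around allometric means, examiner random
# effects, deviant-breed multipliers and rare gross outliers.

#' Default generative truth for synthetic cohorts
#'
#' Returns the parameter set that [generate_cohort()] samples from. The
#' allometric coefficients are the published all-nonsighthound values
#' ([reference_allometry()]); the per-variable log-scale noise SD is
#' calibrated from the published indexing constants so that
#' \code{exp(1.96 * sigma_log)} equals the 97.5th/50th percentile-constant
#' ratio; the examiner random-effect SD (0.05 on the log scale) puts the
#' implied interobserver variance share between roughly 9% and 26% across
#' variables. Breed sample sizes follow the published breed counts; breed
#' body-weight medians are synthetic breed-standard placeholder values (the
#' source database's per-breed summaries are not public). Sighthound
#' chamber multipliers exceed 1, the Newfoundland's are below 1, and the
#' Irish Wolfhound's wall multipliers are below 1, reproducing the
#' deviant-breed patterns the classifier is meant to detect.
#'
#' @return A \code{generative_truth} list with elements \code{dims} (data
#'   frame: \code{variable}, \code{a}, \code{b}, \code{sigma_log}),
#'   \code{fs} (\code{intercept}, \code{slope_b}, \code{sigma}; the weak
#'   inverse power law of fractional shortening on BW),
#'   \code{examiner_sd_log}, \code{n_examiners}, \code{breeds} (data frame
#'   with \code{breed}, \code{n}, \code{bw_median_kg}, \code{bw_log_sd},
#'   \code{sighthound} and one multiplier column per dimension),
#'   \code{outlier_rate}, \code{outlier_scale}, \code{curvature}.
#' @seealso [generate_cohort()], [sim_config()]
#' @export
#' @examples
#' tr <- default_truth()
#' tr$dims
default_truth <- function() {
  ref <- reference_allometry()
  cons <- reference_index_constants()
  sigma_log <- vapply(ref$variable, function(v) {
    cc <- cons[[v]]$constants
    log(cc[["97.5"]] / cc[["50"]]) / 1.96
  }, numeric(1))
  dims <- data.frame(
    variable = ref$variable, a = ref$a, b = ref$b,
    sigma_log = unname(sigma_log), stringsAsFactors = FALSE
  )

  m1 <- rep(1, 6)  # multiplier order: lvdd, lvds, ivsd, ivss, lvwd, lvws
  breeds <- rbind(
    breed_row("Boxer",            3111, 30, FALSE, m1),
    breed_row("Great Dane",        900, 62, FALSE, m1),
    breed_row("Irish Wolfhound",   837, 60, TRUE,
              c(0.96, 0.96, 0.94, 0.92, 0.94, 0.94)),
    breed_row("Doberman",          427, 36, FALSE, m1),
    breed_row("Afghan",            306, 25, TRUE,
              c(1.08, 1.08, 1, 1, 1, 1)),
    breed_row("Saluki",            302, 20, TRUE,
              c(1.15, 1.15, 1, 1, 1, 1)),
    breed_row("French Bulldog",    203, 12, FALSE, m1),
    breed_row("Hovawart",          184, 33, FALSE, m1),
    breed_row("Newfoundland",      161, 60, FALSE,
              c(0.90, 0.90, 0.97, 0.97, 0.93, 0.93)),
    breed_row("Labrador Retriever", 159, 31, FALSE, m1),
    breed_row("Polski Owczarek Nizinny", 121, 17, FALSE, m1),
    breed_row("Cavalier King Charles Spaniel", 94, 8, FALSE, m1),
    breed_row("Golden Retriever",   89, 32, FALSE, m1),
    breed_row("Whippet",            47, 12, TRUE,
              c(1.10, 1.10, 1, 1, 1, 1))
  )

  structure(list(
    dims = dims,
    fs = list(intercept = 41, slope_b = -0.065, sigma = 0.175),
    examiner_sd_log = 0.05,
    n_examiners = 48L,
    breeds = breeds,
    outlier_rate = 0.001,
    outlier_scale = 10,
    curvature = 0
  ), class = "generative_truth")
}

breed_row <- function(breed, n, bw_median, sighthound, mult) {
  out <- data.frame(breed = breed, n = as.integer(n),
                    bw_median_kg = bw_median, bw_log_sd = 0.12,
                    sighthound = sighthound, stringsAsFactors = FALSE)
  mcols <- paste0("mult_", sub("_cm$", "", names(.MM_VARS)))
  out[mcols] <- as.list(mult)
  out
}

#' Simulation configuration
#'
#' @param seed Integer seed; fixes the generated cohort bit-for-bit.
#' @param truth A \code{generative_truth}, default [default_truth()].
#' @param n_per_breed Optional named integer vector overriding breed sample
#'   sizes (names must match \code{truth$breeds$breed}; unnamed breeds keep
#'   their default n). Breeds set to 0 are omitted.
#' @param n_total Optional total cohort size; breed sizes are rescaled
#'   proportionally (applied after \code{n_per_breed}).
#' @param fraction_immaculate Probability that a dog's record carries the
#'   \code{"immaculate"} health class (no remarks at all) rather than
#'   \code{"all_ok"}; default 0.29, the share observed in the screening
#'   population the generator emulates.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed, truth = default_truth(), n_per_breed = NULL,
                       n_total = NULL, fraction_immaculate = 0.29) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  stopifnot(inherits(truth, "generative_truth"))
  if (nrow(truth$breeds) == 0L) stop("empty breed table", call. = FALSE)
  if (any(truth$breeds$bw_median_kg <= 0) || any(truth$breeds$bw_log_sd < 0)) {
    stop("nonpositive body-weight parameters in breed table", call. = FALSE)
  }
  breeds <- truth$breeds
  if (!is.null(n_per_breed)) {
    if (is.null(names(n_per_breed))) {
      stop("n_per_breed must be a named vector", call. = FALSE)
    }
    idx <- match(names(n_per_breed), breeds$breed)
    if (anyNA(idx)) {
      stop("unknown breed in n_per_breed: ",
           paste(names(n_per_breed)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    breeds$n[idx] <- as.integer(n_per_breed)
  }
  if (!is.null(n_total)) {
    breeds$n <- round_preserving_total(breeds$n, n_total)
  }
  breeds <- breeds[breeds$n > 0L, , drop = FALSE]
  truth$breeds <- breeds
  structure(list(seed = as.integer(seed), truth = truth,
                 fraction_immaculate = fraction_immaculate),
            class = "sim_config")
}

# Largest-remainder scaling of integer counts to a new total.
round_preserving_total <- function(n, total) {
  raw <- n / sum(n) * total
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    take <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[take] <- out[take] + 1L
  }
  as.integer(out)
}

#' Generate a synthetic screening cohort
#'
#' Samples one dog per row: body weight lognormal around the breed median
#' (truncated to 1–90 kg); each M-mode dimension
#' \code{Y = multiplier * a * BW^b * exp(u_examiner + eps)} with examiner
#' random intercepts \code{u} (shared by all dogs an examiner scans, drawn
#' independently per variable) and lognormal noise \code{eps}; with
#' probability \code{outlier_rate} a measurement is multiplied or divided by
#' \code{outlier_scale} (a gross transcription-type error). Fractional
#' shortening is computed from the generated LVDd/LVDs and set missing where
#' a gross outlier corrupted either diameter. Fully deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return An \code{echo_cohort}.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(seed = 1, n_total = 300))
#' coh
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- config$truth
  breeds <- truth$breeds
  set.seed(config$seed)

  n_tot <- sum(breeds$n)
  breed_idx <- rep(seq_len(nrow(breeds)), breeds$n)
  bw <- exp(rnorm(n_tot, log(breeds$bw_median_kg[breed_idx]),
                  breeds$bw_log_sd[breed_idx]))
  bw <- pmin(pmax(bw, 1), 90)

  ex_pool <- sprintf("E%02d", seq_len(truth$n_examiners))
  examiner <- sample(ex_pool, n_tot, replace = TRUE)
  # one random intercept per examiner per variable (log scale)
  u <- matrix(rnorm(truth$n_examiners * 6, 0, truth$examiner_sd_log),
              nrow = truth$n_examiners, ncol = 6,
              dimnames = list(ex_pool, names(.MM_VARS)))
  ex_i <- match(examiner, ex_pool)

  dims <- truth$dims
  y <- matrix(NA_real_, n_tot, 6, dimnames = list(NULL, names(.MM_VARS)))
  outlier_hit <- matrix(FALSE, n_tot, 6,
                        dimnames = list(NULL, names(.MM_VARS)))
  lbw <- log(bw)
  for (j in seq_len(6)) {
    v <- dims$variable[j]
    mult <- breeds[[paste0("mult_", sub("_cm$", "", v))]][breed_idx]
    eps <- rnorm(n_tot, 0, dims$sigma_log[j])
    ly <- log(mult) + log(dims$a[j]) + dims$b[j] * lbw +
      truth$curvature * lbw^2 + u[cbind(ex_i, j)] + eps
    hit <- runif(n_tot) < truth$outlier_rate
    dir <- sample(c(-1, 1), n_tot, replace = TRUE)
    ly[hit] <- ly[hit] + (dir * log(truth$outlier_scale))[hit]
    outlier_hit[, j] <- hit
    y[, j] <- exp(ly)
  }

  fs <- 100 * (y[, "lvdd_cm"] - y[, "lvds_cm"]) / y[, "lvdd_cm"]
  fs[outlier_hit[, "lvdd_cm"] | outlier_hit[, "lvds_cm"]] <- NA_real_
  fs[!is.na(fs) & (fs <= 0.1 | fs >= 99.9)] <- NA_real_

  age <- pmin(pmax(exp(rnorm(n_tot, log(2.5), 0.5)), 0.5), 14)
  sex <- ifelse(runif(n_tot) < 0.55, "male", "female")
  health <- ifelse(runif(n_tot) < config$fraction_immaculate,
                   "immaculate", "all_ok")
  view <- ifelse(runif(n_tot) < 0.5, "long_axis", "short_axis")

  df <- data.frame(
    dog_id = sprintf("D%06d", seq_len(n_tot)),
    breed = breeds$breed[breed_idx],
    sex = sex,
    age_years = round(age, 1),
    bw_kg = bw,
    examiner_id = examiner,
    sighthound = breeds$sighthound[breed_idx],
    health_class = health,
    view = view,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(y))
  df$fs_pct <- fs
  as_echo_cohort(
    df,
    provenance = sprintf("synthetic: seed=%d, n=%d, breeds=%d",
                         config$seed, n_tot, nrow(breeds)),
    validate = FALSE
  )
}
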