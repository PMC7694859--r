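# Shared fixtures, built in code.

# Minimal hand-built valid cohort data frame (not yet an echo_cohort).
make_cohort_df <- function(n = 10, bw = NULL, lvdd = NULL, seed = 1) {
  set.seed(seed)
  bw <- if (is.null(bw)) round(exp(rnorm(n, log(25), 0.4)), 1) else bw
  lvdd <- if (is.null(lvdd)) 1.38 * bw^0.322 else lvdd
  lvds <- 0.87 * bw^0.346
  data.frame(
    dog_id = sprintf("X%03d", seq_len(n)),
    breed = rep(c("Boxer", "Doberman"), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    age_years = rep(2.5, n),
    bw_kg = bw,
    examiner_id = rep(c("E1", "E2"), length.out = n),
    sighthound = FALSE,
    health_class = rep(c("all_ok", "immaculate"), length.out = n),
    view = "long_axis",
    lvdd_cm = lvdd,
    lvds_cm = lvds,
    ivsd_cm = 0.36 * bw^0.289,
    ivss_cm = 0.51 * bw^0.276,
    lvwd_cm = 0.40 * bw^0.261,
    lvws_cm = 0.60 * bw^0.247,
    fs_pct = 100 * (lvdd - lvds) / lvdd,
    stringsAsFactors = FALSE
  )
}

# Breeds of a generative truth whose multipliers are all exactly 1: the
# sub-population that follows the truth's a/b and so supports parameter
# recovery.
nondeviant_breeds <- function(truth = default_truth()) {
  mults <- truth$breeds[, grep("^mult_", names(truth$breeds)), drop = FALSE]
  truth$breeds$breed[rowSums(mults != 1) == 0]
}

# A noise-free truth: no measurement noise, no examiner effect, no gross
# outliers; deterministic dimensions given BW.
noise_free_truth <- function() {
  tr <- default_truth()
  tr$dims$sigma_log <- 0
  tr$examiner_sd_log <- 0
  tr$outlier_rate <- 0
  tr
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
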