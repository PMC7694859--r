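test_that("the same seed reproduces the cohort bit-for-bit", {
  a <- generate_cohort(sim_config(seed = 9, n_total = 400))
  b <- generate_cohort(sim_config(seed = 9, n_total = 400))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(sim_config(seed = 10, n_total = 400))
  expect_false(identical(a$lvdd_cm, c$lvdd_cm))
})

test_that("requested cohort sizes are honored", {
  coh <- generate_cohort(sim_config(seed = 2, n_total = 500))
  expect_equal(nrow(coh), 500L)
  cfg <- sim_config(seed = 2, n_per_breed = c(Boxer = 120, Saluki = 30))
  expect_equal(sum(cfg$truth$breeds$n[cfg$truth$breeds$breed == "Boxer"]),
               120L)
  expect_error(sim_config(seed = 2, n_per_breed = c(Pug = 10)),
               "unknown breed")
})

test_that("default truth carries the published coefficients and a
           constants-calibrated noise SD", {
  tr <- default_truth()
  lvdd <- tr$dims[tr$dims$variable == "lvdd_cm", ]
  expect_equal(lvdd$a, 1.38)
  expect_equal(lvdd$b, 0.322)
  # sigma calibrated so exp(1.96 * sigma) = 97.5th/50th constant ratio
  expect_equal(lvdd$sigma_log, log(1.63 / 1.38) / 1.96, tolerance = 1e-12)
  expect_equal(exp(1.96 * lvdd$sigma_log), 1.63 / 1.38, tolerance = 1e-12)
  expect_equal(tr$fs$slope_b, -0.065)
  # multipliers default to 1 for nondeviant breeds; deviants as documented
  mults <- tr$breeds[, grep("^mult_", names(tr$breeds))]
  expect_true(all(mults[tr$breeds$breed == "Boxer", ] == 1))
  expect_true(all(mults[tr$breeds$breed == "Saluki", c("mult_lvdd", "mult_lvds")] > 1))
  expect_true(all(mults[tr$breeds$breed == "Newfoundland", ] < 1))
  expect_true(all(mults[tr$breeds$breed == "Irish Wolfhound",
                        c("mult_ivsd", "mult_ivss", "mult_lvwd", "mult_lvws")] < 1))
})

test_that("with all noise off, dimensions equal multiplier * a * BW^b
           exactly", {
  cfg <- sim_config(seed = 4, truth = noise_free_truth(), n_total = 300)
  coh <- generate_cohort(cfg)
  tr <- cfg$truth
  for (v in tr$dims$variable) {
    row <- tr$dims[tr$dims$variable == v, ]
    mult <- tr$breeds[[paste0("mult_", sub("_cm$", "", v))]][
      match(coh$breed, tr$breeds$breed)]
    expect_equal(coh[[v]], mult * row$a * coh$bw_kg^row$b,
                 tolerance = 1e-12, info = v)
  }
})

test_that("generated cohorts satisfy all record invariants", {
  coh <- generate_cohort(sim_config(seed = 6, n_total = 800))
  expect_silent(as_echo_cohort(as.data.frame(coh), validate = TRUE))
  expect_false(any(duplicated(coh$dog_id)))
  expect_true(all(coh$bw_kg >= 1 & coh$bw_kg <= 90))
})

test_that("fit_allometric agrees with the closed-form OLS oracle", {
  coh <- generate_cohort(sim_config(seed = 8, n_total = 1000))
  ok <- !is.na(coh$lvdd_cm)
  x <- log(coh$bw_kg[ok]); y <- log(coh$lvdd_cm[ok])
  # oracle: textbook formulas from raw sums
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hat <- exp(mean(y) - b_hat * mean(x))
  res <- y - (log(a_hat) + b_hat * x)
  sig_hat <- sqrt(sum(res^2) / (length(y) - 2))
  fit <- fit_allometric(coh, "LVDd")
  expect_equal(fit$b, b_hat, tolerance = 1e-10)
  expect_equal(fit$a, a_hat, tolerance = 1e-10)
  expect_equal(fit$sigma, sig_hat, tolerance = 1e-10)
  expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-10)
})

test_that("empirical log-residual SD matches sqrt(sigma^2 + examiner^2)
           on the nondeviant sub-population", {
  coh <- generate_cohort(sim_config(seed = 14, n_total = 12000))
  coh <- screen_cohort(coh)$cohort  # drop the rare gross outliers first
  sub <- coh[coh$breed %in% nondeviant_breeds(), ]
  fit <- fit_allometric(sub, "LVDd")
  tr <- default_truth()
  target <- sqrt(tr$dims$sigma_log[1]^2 + tr$examiner_sd_log^2)
  expect_close(fit$sigma, target, tol = 0.05 * target)
})

test_that("large-sample OLS on the nondeviant sub-population recovers the
           generative slope", {
  coh <- generate_cohort(sim_config(seed = 15, n_total = 20000))
  coh <- screen_cohort(coh)$cohort
  sub <- coh[coh$breed %in% nondeviant_breeds(), ]
  fit <- fit_allometric(sub, "LVDd")
  expect_close(fit$b, 0.322, tol = 0.01)
  expect_close(fit$a, 1.38, tol = 0.02)
})
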