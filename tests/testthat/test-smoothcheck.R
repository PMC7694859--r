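test_that("the penalty null space reproduces straight lines exactly at any
           lambda", {
  set.seed(41)
  x <- sort(runif(120, 0, 10))
  y <- 2.5 - 0.7 * x
  for (lam in c(0, 1, 1e4, 1e8)) {
    fit <- fit_pspline(x, y, n_knots = 12, lambda = lam)
    expect_lt(max(abs(fit$fitted - y)), 1e-7)
  }
})

test_that("GCV-selected lambda equals a brute-force grid search with an
           independently coded criterion", {
  set.seed(42)
  x <- sort(runif(200, 0, 1))
  y <- sin(2 * pi * x) + rnorm(200, 0, 0.3)
  fit <- fit_pspline(x, y, n_knots = 15)

  # oracle: rebuild basis and penalty, evaluate GCV per lambda via the
  # explicit n x n hat matrix
  n_knots <- 15
  d <- (max(x) - min(x)) / (n_knots + 1)
  knots <- seq(min(x) - 3 * d, max(x) + 3 * d, by = d)
  B <- splines::splineDesign(knots, x, ord = 4)
  D <- diff(diag(ncol(B)), differences = 2)
  gcv_oracle <- vapply(default_lambda_grid(), function(lam) {
    H <- B %*% solve(crossprod(B) + lam * crossprod(D), t(B))
    r <- y - H %*% y
    length(y) * sum(r^2) / (length(y) - sum(diag(H)))^2
  }, numeric(1))
  expect_equal(fit$lambda,
               default_lambda_grid()[which.min(gcv_oracle)])
  expect_equal(fit$lambda_grid$gcv, gcv_oracle, tolerance = 1e-8)
})

test_that("lambda = 0 reduces to unpenalized B-spline least squares", {
  set.seed(43)
  x <- sort(runif(80, 0, 5))
  y <- exp(0.3 * x) + rnorm(80, 0, 0.1)
  fit <- fit_pspline(x, y, n_knots = 5, lambda = 0)
  n_knots <- 5
  d <- (max(x) - min(x)) / (n_knots + 1)
  knots <- seq(min(x) - 3 * d, max(x) + 3 * d, by = d)
  B <- splines::splineDesign(knots, x, ord = 4)
  beta_ls <- qr.coef(qr(B), y)  # direct least-squares oracle
  expect_equal(fit$coefficients, unname(beta_ls), tolerance = 1e-8)
  expect_equal(fit$edf, ncol(B), tolerance = 1e-6)
})

test_that("effective degrees of freedom decrease in lambda, from basis
           dimension to the 2-dimensional null space", {
  set.seed(44)
  x <- sort(runif(150, 0, 1))
  y <- x + rnorm(150, 0, 0.2)
  lams <- 10^seq(-6, 10, by = 2)
  edfs <- vapply(lams, function(l)
    fit_pspline(x, y, n_knots = 10, lambda = l)$edf, numeric(1))
  expect_true(all(diff(edfs) <= 1e-8))
  expect_equal(edfs[1], 14, tolerance = 0.01)     # 10 knots -> 14 basis fns
  expect_equal(edfs[length(edfs)], 2, tolerance = 0.01)
})

test_that("errors on degenerate input", {
  expect_error(fit_pspline(rep(1, 50), rnorm(50)), "zero range")
  expect_error(fit_pspline(1:10, rnorm(10), n_knots = 20), "at least")
})

test_that("linearity verdicts: power-law truth passes, curved truth
           fails", {
  # the power-law sub-population: breeds with multiplier 1 follow
  # Y = a BW^b exactly in the mean, which is what the diagnostic certifies
  coh <- generate_cohort(sim_config(seed = 45, n_total = 5000))
  nonsh <- coh[coh$breed %in% nondeviant_breeds(), ]
  fit <- fit_allometric(nonsh, "LVDd")
  rep_lin <- linearity_check(fit, nonsh)
  expect_true(rep_lin$verdict)
  expect_lt(rep_lin$max_rel_dev, 0.02)

  # noise-free: deviation indistinguishable from zero
  coh0 <- generate_cohort(sim_config(seed = 46, truth = noise_free_truth(),
                                     n_total = 600))
  sub0 <- coh0[coh0$breed %in% nondeviant_breeds(), ]
  fit0 <- fit_allometric(sub0, "LVDd")
  rep0 <- linearity_check(fit0, sub0)
  expect_lt(rep0$max_rel_dev, 1e-6)
  expect_true(rep0$verdict)

  # quadratic term in log BW (coefficient 0.1) violates the power law
  trc <- default_truth()
  trc$curvature <- 0.1
  trc$outlier_rate <- 0
  cohc <- generate_cohort(sim_config(seed = 47, truth = trc,
                                     n_total = 5000))
  nonshc <- cohc[cohc$breed %in% nondeviant_breeds(), ]
  fitc <- fit_allometric(nonshc, "LVDd")
  repc <- linearity_check(fitc, nonshc)
  expect_false(repc$verdict)
})

test_that("upper-limit group differences: zero for identical groups, a
           known shift for scaled groups", {
  coh <- generate_cohort(sim_config(seed = 48, n_total = 10000))
  nonsh <- coh[!coh$sighthound, ]
  same <- group_upper_limit_difference(nonsh, nonsh, "LVDd")
  expect_equal(same$mean_diff, 0)
  expect_true(all(same$grid$diff == 0))

  # group B = group A with all Y scaled by exp(0.05): the log-model
  # intercept shifts by exactly -0.05, so upper limits scale by exp(-0.05)
  shifted <- nonsh
  shifted$lvdd_cm <- shifted$lvdd_cm * exp(-0.05)
  cmp <- group_upper_limit_difference(nonsh, shifted, "LVDd")
  expected <- mean(cmp$grid$upper_a) * (1 - exp(-0.05))
  expect_close(cmp$mean_diff, expected, tol = 0.01 * expected)
})

test_that("same-truth 'immaculate' subsetting moves the upper limits by
           under 2%", {
  coh <- generate_cohort(sim_config(seed = 49, n_total = 10000))
  nonsh <- coh[!coh$sighthound, ]
  imm <- nonsh[nonsh$health_class == "immaculate", ]
  cmp <- group_upper_limit_difference(nonsh, imm, "LVDd")
  expect_lt(abs(cmp$mean_diff), 0.02 * mean(cmp$grid$upper_a))
  if (is.finite(cmp$group_effect)) {
    # joint additive-model group effect agrees it is small
    expect_lt(abs(cmp$group_effect), 0.05)
  }
})
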