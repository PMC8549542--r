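test_that("noise-free data identify the generative parameters", {
  sess <- make_session(seed = 11, sigma = 0, w_reward = 0.4,
                       w_performance = 0.18, gamma = 0.5)
  fit <- fit_happiness(sess$trials, sess$ratings)
  est <- coef(fit)
  expect_equal(unname(est["w_reward"]), 0.4, tolerance = 1e-4)
  expect_equal(unname(est["w_performance"]), 0.18, tolerance = 1e-4)
  expect_equal(unname(est["gamma"]), 0.5, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$converged)
})

test_that("pure-noise ratings give near-zero weights and r-squared", {
  sess <- make_session(seed = 12)
  set.seed(99)
  ra <- sess$ratings
  ra$rating <- rnorm(nrow(ra))
  fits <- lapply(1:8, function(i) {
    ra$rating <- rnorm(nrow(ra))
    fit_happiness(sess$trials, ra)
  })
  w <- sapply(fits, function(f) coef(f)["w_reward"])
  r2 <- sapply(fits, function(f) f$r_squared)
  expect_lt(abs(mean(w)), 0.1)
  expect_lt(mean(r2), 0.15)
})

test_that("profiled weights equal the closed-form OLS solution at the
           fitted gamma", {
  sess <- make_session(seed = 13)
  fit <- fit_happiness(sess$trials, sess$ratings)
  reg <- fit$regressors
  g <- fit$params$gamma
  X <- cbind(decayed_sum(reg$reward, g), decayed_sum(reg$performance, g))
  X <- X[reg$probe_trials, ]
  w_ols <- solve(crossprod(X), crossprod(X, fit$ratings$rating))
  expect_equal(unname(coef(fit)[c("w_reward", "w_performance")]),
               drop(w_ols), tolerance = 1e-8)
})

test_that("optimizer RSS matches the dense gamma-grid oracle", {
  set.seed(20)
  for (seed in 1:5) {
    sess <- make_session(seed = 100 + seed)
    fit <- fit_happiness(sess$trials, sess$ratings)
    oracle <- grid_fit_oracle(sess$trials, sess$ratings, fit$model)
    # the optimizer must never be beaten by any grid point; the grid is
    # 0.01-coarse in gamma so it may itself sit slightly above the optimum
    expect_lte(fit$rss, oracle$rss + 1e-6)
    expect_lt(oracle$rss - fit$rss, 1e-3)
  }
})

test_that("sigma is the MLE residual SD and r-squared uses total SS", {
  sess <- make_session(seed = 14)
  fit <- fit_happiness(sess$trials, sess$ratings)
  y <- fit$ratings$rating
  expect_equal(fit$params$sigma, sqrt(fit$rss / fit$n_ratings),
               tolerance = 1e-12)
  expect_equal(fit$r_squared, 1 - fit$rss / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(sum(residuals(fit)^2), fit$rss, tolerance = 1e-10)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
})

test_that("BIC follows the Gaussian profile-likelihood convention", {
  # 50 * log(36.125/50) + 3 * log(50) = -4.5159 (hand-computed)
  expect_equal(compute_bic(rss = 36.125, n = 50, k = 3), -4.5159,
               tolerance = 1e-4)
  # penalty monotone in k at equal RSS
  expect_gt(compute_bic(36.125, 50, 4), compute_bic(36.125, 50, 3))
  # doubling all residuals (quadrupling RSS) raises BIC by 2 n log 2
  expect_equal(compute_bic(4 * 36.125, 50, 3) - compute_bic(36.125, 50, 3),
               2 * 50 * log(2), tolerance = 1e-10)
  expect_error(compute_bic(0, 50, 3), "strictly positive")
})

test_that("fit refuses too few ratings", {
  sess <- make_session(seed = 15)
  ra <- sess$ratings[1:6, ]
  expect_error(fit_happiness(sess$trials, ra), "at least")
})

test_that("nested likelihood-ratio test behaves sensibly", {
  sess <- make_session(seed = 16, w_performance = 0.6, sigma = 0.4)
  full <- fit_happiness(sess$trials, sess$ratings)
  red <- fit_happiness(sess$trials, sess$ratings, happiness_model("reward"))
  lt <- lr_test(full, red)
  expect_identical(lt$df, 1L)
  expect_gt(lt$statistic, 0)
  expect_lt(lt$p_value, 0.05)  # strong true performance effect
  expect_error(lr_test(red, full), "more structural parameters")
})

test_that("model comparison table ranks by summed BIC with delta 0 at best", {
  sess1 <- make_session(seed = 17)
  sess2 <- make_session(seed = 18)
  cohort <- list(list(trials = sess1$trials, ratings = sess1$ratings),
                 list(trials = sess2$trials, ratings = sess2$ratings))
  cmp <- compare_happiness_models(cohort)
  expect_setequal(cmp$model,
                  c("reward", "performance", "reward_performance",
                    "reward_performance_sepgamma"))
  expect_equal(min(cmp$delta_bic), 0)
  expect_identical(cmp$k, c(2L, 2L, 3L, 4L))
  expect_true(all(cmp$mean_r2 <= 1))
  # missing subject x model cells are rejected
  fits <- attr(cmp, "fits")
  fits$reward <- fits$reward[1]
  expect_error(compare_happiness_models(cohort, fits = fits),
               "missing subject fits")
})

test_that("r-squared is invariant to rescaling centered ratings", {
  # without an intercept the invariance holds on centered data (a shift
  # would otherwise have nothing to absorb it)
  sess <- make_session(seed = 19)
  ra1 <- sess$ratings
  ctr <- mean(ra1$rating[!ra1$pre_task])
  ra1$rating <- ra1$rating - ctr
  fit <- fit_happiness(sess$trials, ra1)
  ra2 <- ra1
  ra2$rating <- 7 * ra2$rating
  attr(ra2, "mode") <- "raw"  # forces standardization inside the fit
  fit2 <- fit_happiness(sess$trials, ra2)
  expect_equal(fit$r_squared, fit2$r_squared, tolerance = 1e-6)
})

test_that("trimming and detrending follow the stated arithmetic", {
  ra <- data.frame(trial = seq(2, 100, by = 2), rating = rnorm(50),
                   pre_task = FALSE)
  out <- trim_and_detrend(ra, trim_fraction = 0.10)
  expect_identical(nrow(out), 45L)
  expect_identical(out$trial[1], ra$trial[6])

  # exactly linear series detrends to a zero residual series
  lin <- data.frame(trial = seq(2, 100, by = 2),
                    rating = 3 + 0.5 * seq_len(50), pre_task = FALSE)
  det <- trim_and_detrend(lin, trim_fraction = 0, detrend = TRUE)
  expect_lt(max(abs(det$rating)), 1e-10)

  # no-op configuration is the identity
  same <- trim_and_detrend(ra, trim_fraction = 0, detrend = FALSE)
  expect_equal(same$rating, ra$rating)
  expect_error(trim_and_detrend(ra[1:8, ], trim_fraction = 0.5),
               "fewer than")
})
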