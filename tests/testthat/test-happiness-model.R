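test_that("model specifications enforce their structural invariants", {
  m <- happiness_model("reward_performance")
  expect_identical(m$terms, c("reward", "performance"))
  expect_true(m$shared_gamma)
  expect_false(m$include_baseline)
  expect_identical(m$k, 3L)
  expect_identical(happiness_model("reward")$k, 2L)
  expect_identical(happiness_model("reward_performance_sepgamma")$k, 4L)
  expect_identical(happiness_model("reward", rating_mode = "raw")$k, 3L)
  expect_error(happiness_model("reward", shared_gamma = FALSE),
               "both reward and performance")
  expect_error(happiness_params(happiness_model("reward"), w_reward = 1,
                                gamma = 1.2), "gamma")
  expect_error(happiness_params(happiness_model("reward"), w_reward = 1,
                                gamma = 0.5, sigma = -1), "sigma")
  expect_error(happiness_params(happiness_model("reward"), gamma = 0.5),
               "w_reward")
})

test_that("decayed_sum matches hand-computed values and limiting cases", {
  # 0.5^2*1 + 0.5*2 + 3 = 4.25
  expect_equal(decayed_sum(c(1, 2, 3), gamma = 0.5, t = 3), 4.25)
  # gamma = 0: only the most recent event
  x <- c(2, -1, 7, 0.5)
  expect_equal(decayed_sum(x, 0, t = seq_along(x)), x)
  # gamma = 1: undiscounted running sum
  expect_equal(decayed_sum(rep(1, 4), 1, t = 4), 4)
  expect_error(decayed_sum(x, 0.5, t = 5), "out of range")
  expect_error(decayed_sum(x, -0.1), "gamma")
})

test_that("recursive decayed sums equal the explicit double-loop sum", {
  set.seed(14)
  for (rep in 1:20) {
    x <- rnorm(sample(50:200, 1))
    g <- runif(1)
    direct <- vapply(seq_along(x), function(t)
      sum(g^(t - seq_len(t)) * x[seq_len(t)]), 0)
    expect_equal(decayed_sum(x, g), direct, tolerance = 1e-12)
  }
})

test_that("regressors are z-scored over the full session with population SD", {
  tr <- make_trials(rewards = c(40, 60), collisions = c(0, 1),
                    probe_every = 1L)
  reg <- build_regressors(tr)
  # population SD of {40, 60} is 10, so the z-scores are exactly -1, +1
  expect_equal(reg$reward, c(-1, 1))
  expect_equal(reg$performance, c(1, -1))  # success = 1 - collision

  set.seed(2)
  tr2 <- make_trials(rnorm(100, 40, 12), rbinom(100, 1, 0.3))
  reg2 <- build_regressors(tr2)
  expect_lt(abs(mean(reg2$reward)), 1e-10)
  expect_equal(sqrt(mean(reg2$reward^2)), 1, tolerance = 1e-10)
  expect_lt(abs(mean(reg2$performance)), 1e-10)

  # all-success performance column has zero variance
  expect_error(build_regressors(make_trials(rnorm(10, 40, 5), rep(0, 10))),
               "degenerate regressor column 'performance'")
  expect_error(build_regressors(make_trials(rep(50, 10), rbinom(10, 1, .5))),
               "degenerate regressor column 'reward'")
})

test_that("predictions match the brute-force evaluation of the model sum", {
  set.seed(31)
  tr <- make_trials(rnorm(80, 40, 10), rbinom(80, 1, 0.3))
  ra <- data.frame(trial = which(tr$probe_after == 1L), rating = 0,
                   pre_task = FALSE)
  reg <- build_regressors(tr, ra)

  m <- happiness_model("reward_performance")
  p <- happiness_params(m, w_reward = 0.39, w_performance = 0.18,
                        gamma = 0.48, sigma = 0)
  expect_equal(predict_happiness(m, p, reg),
               predict_bruteforce(m, p, reg$reward, reg$performance,
                                  reg$probe_trials),
               tolerance = 1e-12)

  m2 <- happiness_model("reward_performance_sepgamma")
  p2 <- happiness_params(m2, w_reward = 0.3, w_performance = -0.2,
                         gamma_reward = 0.7, gamma_performance = 0.2,
                         sigma = 0)
  expect_equal(predict_happiness(m2, p2, reg),
               predict_bruteforce(m2, p2, reg$reward, reg$performance,
                                  reg$probe_trials),
               tolerance = 1e-12)

  mr <- happiness_model("reward", rating_mode = "raw")
  pr <- happiness_params(mr, w0 = 62, w_reward = 6, gamma = 0.4, sigma = 0)
  expect_equal(predict_happiness(mr, pr, reg),
               predict_bruteforce(mr, pr, reg$reward, reg$performance,
                                  reg$probe_trials),
               tolerance = 1e-12)
})

test_that("baseline-only raw model predicts a constant w0", {
  tr <- make_trials(rnorm(40, 40, 10), rbinom(40, 1, 0.3))
  ra <- data.frame(trial = which(tr$probe_after == 1L), rating = 0,
                   pre_task = FALSE)
  m <- happiness_model("reward", rating_mode = "raw")
  p <- happiness_params(m, w0 = 62, w_reward = 0, gamma = 0.3, sigma = 0)
  expect_equal(predict_happiness(m, p, tr, ra),
               rep(62, sum(tr$probe_after)))
})

test_that("predictions are linear in the weights at fixed gamma", {
  set.seed(12)
  tr <- make_trials(rnorm(60, 40, 10), rbinom(60, 1, 0.3))
  ra <- data.frame(trial = which(tr$probe_after == 1L), rating = 0,
                   pre_task = FALSE)
  reg <- build_regressors(tr, ra)
  m <- happiness_model("reward_performance")
  p1 <- happiness_params(m, w_reward = 0.4, w_performance = 0.1,
                         gamma = 0.6, sigma = 0)
  p3 <- happiness_params(m, w_reward = 1.2, w_performance = 0.3,
                         gamma = 0.6, sigma = 0)
  expect_equal(3 * predict_happiness(m, p1, reg),
               predict_happiness(m, p3, reg), tolerance = 1e-12)
})

test_that("separate-gamma model with equal gammas reproduces the shared model", {
  set.seed(13)
  tr <- make_trials(rnorm(60, 40, 10), rbinom(60, 1, 0.3))
  ra <- data.frame(trial = which(tr$probe_after == 1L), rating = 0,
                   pre_task = FALSE)
  reg <- build_regressors(tr, ra)
  shared <- happiness_model("reward_performance")
  sep <- happiness_model("reward_performance_sepgamma")
  ps <- happiness_params(shared, w_reward = 0.39, w_performance = 0.18,
                         gamma = 0.48, sigma = 0)
  pp <- happiness_params(sep, w_reward = 0.39, w_performance = 0.18,
                         gamma_reward = 0.48, gamma_performance = 0.48,
                         sigma = 0)
  expect_equal(predict_happiness(shared, ps, reg),
               predict_happiness(sep, pp, reg), tolerance = 1e-14)
})
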