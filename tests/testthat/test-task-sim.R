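test_that("task_config validates its invariants", {
  expect_error(task_config(n_trials = 10), "no reversal realizable")
  expect_error(task_config(reversal_min = 25, reversal_max = 20),
               "reversal_min")
  expect_error(task_config(probe_min = 4, probe_max = 3), "probe_min")
  expect_error(task_config(free_choice_fraction = 1.2),
               "free_choice_fraction")
})

test_that("schedule reversal gaps, choice mix and probe gaps follow the config", {
  cfg <- task_config(n_trials = 100)
  sch <- generate_schedule(cfg, seed = 7)
  rev_trials <- which(sch$reversal == 1L)
  gaps <- diff(c(1L, rev_trials))
  expect_true(all(gaps >= 19 & gaps <= 23))

  # free-choice fraction exact up to rounding, forced options balanced
  expect_equal(sum(sch$choice_type == "free"), 50)
  forced <- sch[sch$choice_type == "forced", ]
  n_forced_high <- sum(forced$forced_option == forced$high_option)
  expect_equal(n_forced_high, nrow(forced) - n_forced_high)

  # probe gaps within {probe_min..probe_max}
  probes <- which(sch$probe_after == 1L)
  expect_true(all(diff(c(0L, probes)) %in% 2:3))

  # boundary: all trials forced when free fraction is 0
  sch0 <- generate_schedule(task_config(free_choice_fraction = 0), seed = 1)
  expect_true(all(sch0$choice_type == "forced"))
})

test_that("fixed probe gap of 2 over 120 trials puts probes at 2,4,...,120", {
  cfg <- task_config(n_trials = 120, probe_min = 2, probe_max = 2)
  sch <- generate_schedule(cfg, seed = 1)
  expect_identical(which(sch$probe_after == 1L), seq(2L, 120L, by = 2L))
})

test_that("reversal gap distribution is uniform on 19..23", {
  cfg <- task_config(n_trials = 120)
  set.seed(42)
  gaps <- unlist(lapply(1:2000, function(i) {
    sch <- generate_schedule(cfg)
    diff(c(1L, which(sch$reversal == 1L)))
  }))
  tab <- table(factor(gaps, levels = 19:23))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("simulated rewards match the configured option marginals", {
  cfg <- task_config(n_trials = 120)
  ag <- agent_spec()
  set.seed(5)
  pts_high <- pts_low <- numeric(0)
  for (i in 1:40) {
    tr <- simulate_agent_choices(generate_schedule(cfg), ag, cfg)
    hi <- tr$chose_high == 1L
    pts_high <- c(pts_high, tr$reward_points[hi])
    pts_low <- c(pts_low, tr$reward_points[!hi])
  }
  expect_equal(mean(pts_high), 50, tolerance = 0.01)
  expect_equal(mean(pts_low), 25, tolerance = 0.03)
  expect_equal(sd(pts_high), 10, tolerance = 0.03)
  expect_equal(sd(pts_low), 10, tolerance = 0.03)
})

test_that("choice policy limits behave as specified", {
  cfg <- task_config(n_trials = 120)
  set.seed(9)
  # zero inverse temperature: random free choice
  ag0 <- agent_spec(inverse_temperature = 0)
  acc0 <- replicate(30, {
    tr <- simulate_agent_choices(generate_schedule(cfg), ag0, cfg)
    mean(tr$chose_high[tr$choice_type == "free"])
  })
  expect_equal(mean(acc0), 0.5, tolerance = 0.03)

  # zero learning rate: values frozen at the common prior -> also chance
  agf <- agent_spec(learning_rate = 0, inverse_temperature = 5)
  accf <- replicate(30, {
    tr <- simulate_agent_choices(generate_schedule(cfg), agf, cfg)
    mean(tr$chose_high[tr$choice_type == "free"])
  })
  expect_equal(mean(accf), 0.5, tolerance = 0.03)

  # the default learner tracks the current high option well above chance
  ag <- agent_spec()
  acc <- replicate(30, {
    tr <- simulate_agent_choices(generate_schedule(cfg), ag, cfg)
    mean(tr$chose_high[tr$choice_type == "free"])
  })
  expect_gt(mean(acc), 0.65)
})

test_that("noise-free generated ratings equal model predictions at every probe", {
  m <- happiness_model("reward_performance")
  p <- happiness_params(m, w_reward = 0.39, w_performance = 0.18,
                        gamma = 0.48, sigma = 0)
  sess <- make_session(seed = 3)
  ra <- generate_ratings(sess$trials, p, m, seed = 1)
  reg <- build_regressors(sess$trials, ra)
  expect_equal(ra$rating[!ra$pre_task],
               predict_happiness(m, p, reg), tolerance = 1e-12)

  # gamma = 0 keeps only the most recent trial's z-scored reward
  m_r <- happiness_model("reward")
  p_r <- happiness_params(m_r, w_reward = 1, gamma = 0, sigma = 0)
  ra_r <- generate_ratings(sess$trials, p_r, m_r)
  expect_equal(ra_r$rating[!ra_r$pre_task],
               reg$reward[ra_r$trial[!ra_r$pre_task]], tolerance = 1e-12)
})

test_that("raw-mode ratings are clipped to the scale, z-mode left unclipped", {
  sess <- make_session(seed = 4)
  m_raw <- happiness_model("reward", rating_mode = "raw")
  p_raw <- happiness_params(m_raw, w0 = 98, w_reward = 30, gamma = 0.5,
                            sigma = 10)
  ra <- generate_ratings(sess$trials, p_raw, m_raw, seed = 2)
  expect_true(all(ra$rating >= 0 & ra$rating <= 100))
  expect_true(any(ra$rating == 100))  # saturation actually exercised

  m_z <- happiness_model("reward")
  p_z <- happiness_params(m_z, w_reward = 200, gamma = 0.5, sigma = 10)
  ra_z <- generate_ratings(sess$trials, p_z, m_z, seed = 2)
  expect_true(any(ra_z$rating > 100 | ra_z$rating < 0))  # unclipped
})

test_that("identical seeds give byte-identical sessions", {
  a <- make_session(seed = 77)
  b <- make_session(seed = 77)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ratings, b$ratings)
  c <- make_session(seed = 78)
  expect_false(identical(a$trials$reward_points, c$trials$reward_points))
})

test_that("pre-task rating is emitted, flagged, and excluded from fitting", {
  sess <- make_session(seed = 6)
  expect_true(sess$ratings$pre_task[1])
  expect_identical(sess$ratings$trial[1], 0L)
  fit <- fit_happiness(sess$trials, sess$ratings)
  expect_equal(fit$n_ratings, sum(!sess$ratings$pre_task))
})
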