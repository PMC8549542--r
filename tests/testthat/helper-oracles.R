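# Independent oracles and tiny fixture builders shared across the suite.
# The oracles deliberately avoid the package's computational paths: the
# predictor is an explicit double loop over the model sum, the fitter is a
# dense gamma grid with closed-form least squares, and the signed-rank
# null distribution is enumerated over all sign assignments.

# explicit O(t^2) evaluation of the discounted-history model
predict_bruteforce <- function(model, params, reward, performance,
                               probe_trials) {
  vapply(probe_trials, function(t) {
    p <- if (model$include_baseline) params$w0 else 0
    g_r <- if (model$shared_gamma) params$gamma else params$gamma_reward
    g_p <- if (model$shared_gamma) params$gamma else params$gamma_performance
    if ("reward" %in% model$terms)
      for (j in seq_len(t))
        p <- p + params$w_reward * g_r^(t - j) * reward[j]
    if ("performance" %in% model$terms)
      for (j in seq_len(t))
        p <- p + params$w_performance * g_p^(t - j) * performance[j]
    p
  }, 0)
}

# dense-grid fitter for shared-gamma models: closed-form weights at each
# gamma in {0, 0.01, ..., 1}, minimum RSS returned
grid_fit_oracle <- function(trials, ratings, model,
                            grid = seq(0, 1, by = 0.01)) {
  stopifnot(model$shared_gamma)
  pre <- ratings$pre_task
  y <- ratings$rating[!pre]
  if (model$rating_mode == "zscored" &&
      !identical(attr(ratings, "mode"), "zscored")) {
    m <- mean(y); y <- (y - m) / sqrt(mean((y - m)^2))
  }
  probe <- ratings$trial[!pre]
  zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  r_z <- zs(trials$reward_points)
  p_z <- zs(1 - trials$collision)
  best <- Inf; best_gamma <- NA
  for (g in grid) {
    cols <- list()
    if (model$include_baseline) cols$w0 <- rep(1, length(probe))
    if ("reward" %in% model$terms)
      cols$w_reward <- vapply(probe, function(t)
        sum(g^(t - seq_len(t)) * r_z[seq_len(t)]), 0)
    if ("performance" %in% model$terms)
      cols$w_performance <- vapply(probe, function(t)
        sum(g^(t - seq_len(t)) * p_z[seq_len(t)]), 0)
    X <- do.call(cbind, cols)
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    if (rss < best) { best <- rss; best_gamma <- g }
  }
  list(rss = best, gamma = best_gamma)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
# (assumes no zeros and no tied absolute differences)
wilcoxon_exact_enum <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# deterministic miniature trial log (no simulation involved)
make_trials <- function(rewards, collisions, probe_every = 2L) {
  n <- length(rewards)
  data.frame(
    trial = seq_len(n), block = 1L, choice_type = "free",
    high_option = "A", chosen_option = "A",
    reward_points = rewards, collision = collisions,
    cursor_speed = 1, probe_after = as.integer(seq_len(n) %% probe_every == 0))
}

# a reproducible session with known generative parameters
make_session <- function(seed = 1, sigma = 0.85, w_reward = 0.39,
                         w_performance = 0.18, gamma = 0.48,
                         n_trials = 120L) {
  m <- happiness_model("reward_performance")
  ag <- agent_spec(
    happiness_params = happiness_params(m, w_reward = w_reward,
                                        w_performance = w_performance,
                                        gamma = gamma, sigma = sigma),
    model = m)
  simulate_subject(task_config(n_trials = n_trials), ag, seed = seed)
}
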