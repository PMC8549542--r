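#' Configure the reversal-learning task
#'
#' The task presents two reward options whose point payoffs are Gaussian
#' (one mean 50, the other mean 25, SD 10); which option is the high-mean
#' one reverses every 19-23 trials. Half of the trials are free choices,
#' the other half present a single forced option. After each choice the
#' subject steers a cursor past four barriers at a staircased speed; a
#' happiness probe follows every two to three trials.
#'
#' @param n_trials total number of trials (default 120).
#' @param n_blocks number of equal-length blocks (default 2).
#' @param reward_mean_high,reward_mean_low,reward_sd Gaussian point
#'   distributions of the two options.
#' @param reversal_min,reversal_max inclusive range of inter-reversal gaps
#'   (trials).
#' @param free_choice_fraction proportion of free-choice trials.
#' @param probe_min,probe_max inclusive range of gaps between happiness
#'   probes (trials).
#' @param n_barriers barriers per trial (informational; only the
#'   any-collision outcome is simulated).
#' @param rating_scale numeric range of the raw rating line.
#' @return Object of class `"task_config"`.
#' @export
task_config <- function(n_trials = 120L, n_blocks = 2L,
                        reward_mean_high = 50, reward_mean_low = 25,
                        reward_sd = 10,
                        reversal_min = 19L, reversal_max = 23L,
                        free_choice_fraction = 0.5,
                        probe_min = 2L, probe_max = 3L,
                        n_barriers = 4L,
                        rating_scale = c(0, 100)) {
  n_trials <- as.integer(n_trials); n_blocks <- as.integer(n_blocks)
  reversal_min <- as.integer(reversal_min)
  reversal_max <- as.integer(reversal_max)
  probe_min <- as.integer(probe_min); probe_max <- as.integer(probe_max)
  if (n_trials < 1L || n_blocks < 1L || n_barriers < 1L)
    stop("counts must be >= 1")
  if (reversal_min > reversal_max || reversal_min < 1L)
    stop("need 1 <= reversal_min <= reversal_max")
  if (n_trials < reversal_min)
    stop("configuration error: n_trials < reversal_min, no reversal realizable")
  if (probe_min > probe_max || probe_min < 1L)
    stop("need 1 <= probe_min <= probe_max")
  if (free_choice_fraction < 0 || free_choice_fraction > 1)
    stop("free_choice_fraction must lie in [0, 1]")
  if (reward_sd <= 0) stop("reward_sd must be positive")
  structure(
    list(n_trials = n_trials, n_blocks = n_blocks,
         reward_mean_high = reward_mean_high,
         reward_mean_low = reward_mean_low, reward_sd = reward_sd,
         reversal_min = reversal_min, reversal_max = reversal_max,
         free_choice_fraction = free_choice_fraction,
         probe_min = probe_min, probe_max = probe_max,
         n_barriers = n_barriers, rating_scale = rating_scale),
    class = "task_config")
}

#' Specify a simulated agent
#'
#' The happiness model makes no claim about how choices or barrier
#' navigation are produced, so the simulator uses standard plumbing: a
#' delta-rule (Rescorla-Wagner) value learner with softmax choice on free
#' trials, and a logistic speed-success psychometric function whose
#' difficulty the PEST staircase titrates. The defaults (learning rate
#' 0.3, inverse temperature 0.25 on the points scale) put cohort
#' free-choice accuracy in the mid-80% range typical of this task.
#'
#' @param learning_rate delta-rule learning rate in \[0, 1\].
#' @param inverse_temperature nonnegative softmax inverse temperature
#'   (per point of value difference).
#' @param psychometric_threshold cursor speed at which success probability
#'   is 0.5.
#' @param psychometric_slope positive logistic slope of success vs speed.
#' @param happiness_params a [happiness_params()] generating the agent's
#'   ratings.
#' @param model the [happiness_model()] the parameters belong to.
#' @return Object of class `"agent_spec"`.
#' @export
agent_spec <- function(learning_rate = 0.3, inverse_temperature = 0.25,
                       psychometric_threshold = 1.0,
                       psychometric_slope = 5.0,
                       happiness_params = NULL, model = NULL) {
  if (learning_rate < 0 || learning_rate > 1)
    stop("learning_rate must lie in [0, 1]")
  if (inverse_temperature < 0)
    stop("inverse_temperature must be nonnegative")
  if (psychometric_slope <= 0)
    stop("psychometric_slope must be positive")
  if (is.null(model))
    model <- happiness_model("reward_performance")
  if (is.null(happiness_params))
    happiness_params <- happiness_params(model, w_reward = 0.39,
                                         w_performance = 0.18,
                                         gamma = 0.48, sigma = 0.85)
  structure(
    list(learning_rate = learning_rate,
         inverse_temperature = inverse_temperature,
         psychometric_threshold = psychometric_threshold,
         psychometric_slope = psychometric_slope,
         happiness_params = happiness_params, model = model),
    class = "agent_spec")
}

#' Generate the trial schedule
#'
#' Draws the reversal trials (inter-reversal gaps uniform on
#' `[reversal_min, reversal_max]`), assigns free/forced choice types (the
#' configured fraction of free trials, positions shuffled; forced trials
#' present the currently-high and currently-low option in alternation,
#' pseudo-randomly phased), and places happiness probes with gaps uniform
#' on `{probe_min, ..., probe_max}`.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed; when given the schedule is a pure
#'   function of `(config, seed)`.
#' @return data.frame with one row per trial: `trial`, `block`,
#'   `choice_type` (`"free"`/`"forced"`), `high_option` (`"A"`/`"B"`),
#'   `forced_option` (`NA` on free trials), `reversal` flag, `probe_after`
#'   flag.
#' @export
generate_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  # sample() treats a scalar first argument as 1:x; guard degenerate ranges
  draw_gap <- function(lo, hi)
    if (lo == hi) lo else sample(lo:hi, 1L)

  # reversal trials: cumulative uniform gaps
  gaps <- integer(0)
  total <- 0L
  repeat {
    g <- draw_gap(config$reversal_min, config$reversal_max)
    if (total + g > n) break
    gaps <- c(gaps, g)
    total <- total + g
  }
  reversal_at <- cumsum(gaps)           # reversal occurs before this trial+1
  high <- character(n)
  cur <- sample(c("A", "B"), 1L)
  for (t in seq_len(n)) {
    if (t > 1L && (t - 1L) %in% reversal_at)
      cur <- if (cur == "A") "B" else "A"
    high[t] <- cur
  }

  # free/forced assignment: exact count, shuffled positions
  n_free <- round(config$free_choice_fraction * n)
  choice_type <- rep("forced", n)
  choice_type[sample.int(n, n_free)] <- "free"

  # forced options: alternate high/low with a random phase
  forced_idx <- which(choice_type == "forced")
  forced_option <- rep(NA_character_, n)
  if (length(forced_idx)) {
    lvl <- rep(c("high", "low"), length.out = length(forced_idx))
    if (stats::runif(1) < 0.5) lvl <- rev(lvl)
    lvl <- lvl[sample.int(length(lvl))]
    is_high <- lvl == "high"
    forced_option[forced_idx] <-
      ifelse(is_high, high[forced_idx],
             ifelse(high[forced_idx] == "A", "B", "A"))
  }

  # probe placement: cumulative uniform gaps over {probe_min..probe_max}
  probe_after <- rep(0L, n)
  pos <- 0L
  repeat {
    pos <- pos + draw_gap(config$probe_min, config$probe_max)
    if (pos > n) break
    probe_after[pos] <- 1L
  }

  block <- pmin(ceiling(seq_len(n) / ceiling(n / config$n_blocks)),
                config$n_blocks)
  data.frame(trial = seq_len(n), block = block, choice_type = choice_type,
             high_option = high, forced_option = forced_option,
             reversal = as.integer(seq_len(n) %in% (reversal_at + 1L)),
             probe_after = probe_after,
             stringsAsFactors = FALSE)
}

#' Simulate choices and point outcomes for a scheduled session
#'
#' Runs the delta-rule/softmax agent over the schedule: on free trials the
#' choice is sampled by softmax over the learned option values; on forced
#' trials the single presented option is taken. Learned values update by
#' the prediction-error rule from the observed points; points are drawn
#' from the chosen option's Gaussian.
#'
#' @param schedule a [generate_schedule()] data.frame.
#' @param agent an [agent_spec()].
#' @param config the [task_config()] used for the schedule.
#' @return `schedule` with added columns `chosen_option`, `chose_high`,
#'   `reward_points`.
#' @export
simulate_agent_choices <- function(schedule, agent, config) {
  stopifnot(is.data.frame(schedule), inherits(agent, "agent_spec"),
            inherits(config, "task_config"))
  n <- nrow(schedule)
  v <- c(A = (config$reward_mean_high + config$reward_mean_low) / 2,
         B = (config$reward_mean_high + config$reward_mean_low) / 2)
  chosen <- character(n)
  points <- numeric(n)
  for (t in seq_len(n)) {
    if (schedule$choice_type[t] == "forced") {
      ch <- schedule$forced_option[t]
    } else {
      p_a <- 1 / (1 + exp(-agent$inverse_temperature * (v["A"] - v["B"])))
      ch <- if (stats::runif(1) < p_a) "A" else "B"
    }
    mu <- if (ch == schedule$high_option[t]) config$reward_mean_high
          else config$reward_mean_low
    r <- stats::rnorm(1, mu, config$reward_sd)
    v[ch] <- v[ch] + agent$learning_rate * (r - v[ch])
    chosen[t] <- ch
    points[t] <- r
  }
  schedule$chosen_option <- chosen
  schedule$chose_high <- as.integer(chosen == schedule$high_option)
  schedule$reward_points <- points
  schedule
}

#' Simulate barrier outcomes under the continuing staircase
#'
#' For each trial the success probability is the agent's logistic
#' psychometric function evaluated at the current staircased speed
#' (higher speed, lower success); a collision is recorded when the trial
#' is unsuccessful, and the PEST state advances.
#'
#' @param schedule trial schedule (only its length is used).
#' @param agent an [agent_spec()] providing the psychometric function.
#' @param state a calibrated [init_staircase()] state.
#' @return List with `collision` (0/1 per trial), `cursor_speed` (speed at
#'   which each trial was run) and the final `state`.
#' @export
simulate_trial_outcomes <- function(schedule, agent, state) {
  stopifnot(inherits(agent, "agent_spec"),
            inherits(state, "pest_staircase"))
  performer <- logistic_performer(agent$psychometric_threshold,
                                  agent$psychometric_slope)
  n <- nrow(schedule)
  collision <- integer(n)
  speed <- numeric(n)
  for (t in seq_len(n)) {
    v <- state$current_speed
    if (!is.finite(v)) stop("staircase corruption: non-finite speed")
    s <- stats::rbinom(1L, 1L, performer(v))
    collision[t] <- 1L - s
    speed[t] <- v
    state <- pest_update(state, s)
  }
  list(collision = collision, cursor_speed = speed, state = state)
}

#' Generate happiness ratings from a trial log
#'
#' At each probe trial the rating is the model prediction plus Gaussian
#' noise `N(0, sigma)`. Raw-mode ratings are clipped to the physical
#' rating line (default \[0, 100\]); standardized-mode ratings are left
#' unclipped. A pre-task rating (trial 0, flagged `pre_task`) mirrors the
#' rating taken before the first trial; it is excluded from fitting by
#' default.
#'
#' @param trials trial-log data.frame with `probe_after` flags.
#' @param params a [happiness_params()] (its `sigma` is the noise SD).
#' @param model the matching [happiness_model()].
#' @param seed optional integer seed for the rating noise.
#' @param rating_scale clip range for raw-mode ratings.
#' @param pre_task emit the pre-task rating row? (default `TRUE`).
#' @return A rating series: data.frame with columns `trial`, `rating`,
#'   `pre_task`; attribute `mode` is the model's rating mode.
#' @export
generate_ratings <- function(trials, params, model, seed = NULL,
                             rating_scale = c(0, 100), pre_task = TRUE) {
  stopifnot(inherits(model, "happiness_model"))
  if (is.null(params$sigma) || params$sigma < 0)
    stop("params$sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  probe <- which(trials$probe_after == 1L)
  reg <- build_regressors(trials)
  reg$probe_trials <- probe
  mu <- predict_happiness(model, params, reg)
  noise <- stats::rnorm(length(mu), 0, params$sigma)
  rating <- mu + noise
  if (model$rating_mode == "raw")
    rating <- pmin(pmax(rating, rating_scale[1]), rating_scale[2])
  out <- data.frame(trial = probe, rating = rating, pre_task = FALSE)
  if (pre_task) {
    base <- if (model$include_baseline) params$w0 else 0
    r0 <- base + stats::rnorm(1, 0, params$sigma)
    if (model$rating_mode == "raw")
      r0 <- min(max(r0, rating_scale[1]), rating_scale[2])
    out <- rbind(data.frame(trial = 0L, rating = r0, pre_task = TRUE), out)
  }
  attr(out, "mode") <- model$rating_mode
  out
}

#' Simulate one subject's full session
#'
#' Runs the pre-task 60-trial PEST calibration, generates the schedule,
#' simulates choices, barrier outcomes (staircase continuing throughout
#' the task) and happiness ratings.
#'
#' @param config a [task_config()].
#' @param agent an [agent_spec()].
#' @param seed integer seed; the whole session is a pure function of
#'   `(config, agent, seed)`.
#' @param calibration_trials pre-task staircase trials (default 60).
#' @return List of class `"hedonometer_session"` with elements `trials`
#'   (trial log), `ratings`, `calibration` (staircase trace) and
#'   `starting_speed` (speed after calibration).
#' @export
simulate_subject <- function(config = task_config(), agent = agent_spec(),
                             seed = NULL, calibration_trials = 60L) {
  if (!is.null(seed)) set.seed(seed)
  performer <- logistic_performer(agent$psychometric_threshold,
                                  agent$psychometric_slope)
  cal <- run_calibration(performer, calibration_trials,
                         init_staircase(initial_speed =
                                          agent$psychometric_threshold))
  schedule <- generate_schedule(config)
  trials <- simulate_agent_choices(schedule, agent, config)
  out <- simulate_trial_outcomes(trials, agent, cal$state)
  trials$collision <- out$collision
  trials$cursor_speed <- out$cursor_speed
  ratings <- generate_ratings(trials, agent$happiness_params, agent$model,
                              rating_scale = config$rating_scale)
  structure(list(trials = trials, ratings = ratings,
                 calibration = cal$trace,
                 starting_speed = cal$state$current_speed),
            class = "hedonometer_session")
}

#' @export
print.hedonometer_session <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf(
    "Simulated session: %d trials, %d probes, %.0f%% barrier-free\n",
    n, sum(!x$ratings$pre_task), 100 * mean(1 - x$trials$collision)))
  invisible(x)
}
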