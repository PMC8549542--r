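#' Initialize a PEST adaptive staircase
#'
#' Parametric Estimation by Sequential Testing (PEST) holds the success
#' probability of the skilled cursor-navigation component at a target
#' level (default 70% barrier-free trials) by adjusting cursor speed.
#' Trials accumulate into a run; when the number of successes deviates
#' from the expected `target_p * trials` by more than the Wald limit
#' `wald_w`, the speed steps in the direction that restores the target
#' (too many successes: speed up, making the task harder; too few: slow
#' down) and the run restarts.
#'
#' Step-size heuristics follow classic PEST practice: halve the step on a
#' direction reversal; keep it on the second step in the same direction;
#' double from the third step onward, except on the step immediately
#' following a reversal that came after a doubled step. The paper
#' tradition gives no constants, so the defaults here are the usual ones:
#' `wald_w = 1` expected success, initial step 10% of the starting speed,
#' step clamped to \[1%, 50%\] of the starting speed.
#'
#' @param target_p target success probability, strictly in (0, 1).
#' @param initial_speed starting cursor speed (arbitrary positive units).
#' @param initial_step initial speed step.
#' @param bounds length-2 numeric, allowed speed range.
#' @param wald_w Wald deviation limit, in expected successes.
#' @param min_step,max_step step-size clamp.
#' @return Object of class `"pest_staircase"`; a list holding the current
#'   speed, step size, run counters and decision history fields.
#' @references Taylor, M. M., & Creelman, C. D. (1967). PEST: Efficient
#'   estimates on probability functions. JASA, 41, 782-787.
#' @export
init_staircase <- function(target_p = 0.70, initial_speed = 1.0,
                           initial_step = 0.1 * initial_speed,
                           bounds = c(0.05 * initial_speed,
                                      5 * initial_speed),
                           wald_w = 1.0,
                           min_step = 0.01 * initial_speed,
                           max_step = 0.5 * initial_speed) {
  if (!is.numeric(target_p) || length(target_p) != 1L ||
      target_p <= 0 || target_p >= 1)
    stop("target_p must lie strictly between 0 and 1")
  if (length(bounds) != 2L || !all(is.finite(bounds)) ||
      bounds[1] <= 0 || bounds[1] >= bounds[2])
    stop("bounds must be an ordered pair of positive speeds")
  if (initial_speed < bounds[1] || initial_speed > bounds[2])
    stop("initial_speed outside speed bounds")
  if (min_step <= 0 || max_step < min_step)
    stop("step clamp must satisfy 0 < min_step <= max_step")
  step <- min(max(initial_step, min_step), max_step)
  structure(
    list(current_speed = initial_speed,
         step_size = step,
         last_direction = "none",
         doubled_last = FALSE,
         post_double_reversal = FALSE,
         steps_same_direction = 0L,
         successes_in_run = 0L,
         trials_in_run = 0L,
         target_p = target_p,
         wald_w = wald_w,
         min_step = min_step, max_step = max_step,
         speed_bounds = bounds),
    class = "pest_staircase")
}

#' @export
print.pest_staircase <- function(x, ...) {
  cat(sprintf(
    "PEST staircase: speed %.4g (step %.4g, %s), run %d/%d, target %.0f%%\n",
    x$current_speed, x$step_size, x$last_direction,
    x$successes_in_run, x$trials_in_run, 100 * x$target_p))
  invisible(x)
}

#' Advance a PEST staircase by one trial outcome
#'
#' Pure function of `(state, success)`: replaying a success history
#' reproduces the speed trajectory exactly.
#'
#' @param state a [init_staircase()] state.
#' @param success binary outcome of the trial (1 = no barrier contacted).
#' @return The updated state. `state$decision` records what the update did
#'   (`"none"`, `"up"` or `"down"`).
#' @export
pest_update <- function(state, success) {
  stopifnot(inherits(state, "pest_staircase"))
  success <- as.integer(success)
  if (!success %in% c(0L, 1L)) stop("success must be 0 or 1")
  state$trials_in_run <- state$trials_in_run + 1L
  state$successes_in_run <- state$successes_in_run + success
  deviation <- state$successes_in_run - state$target_p * state$trials_in_run
  state$decision <- "none"
  if (abs(deviation) <= state$wald_w) return(state)

  # excess successes: task too easy at this speed -> speed up (harder)
  direction <- if (deviation > 0) "up" else "down"
  reversal <- state$last_direction != "none" &&
    direction != state$last_direction
  if (reversal) {
    state$step_size <- state$step_size / 2
    state$steps_same_direction <- 1L
    # remember whether the step we are reversing away from was a double
    state$post_double_reversal <- isTRUE(state$doubled_last)
    state$doubled_last <- FALSE
  } else {
    state$steps_same_direction <- state$steps_same_direction + 1L
    if (state$steps_same_direction >= 3L &&
        !isTRUE(state$post_double_reversal)) {
      state$step_size <- state$step_size * 2
      state$doubled_last <- TRUE
    } else {
      state$doubled_last <- FALSE
    }
    if (state$steps_same_direction >= 3L) state$post_double_reversal <- FALSE
  }
  state$step_size <- min(max(state$step_size, state$min_step), state$max_step)
  delta <- if (direction == "up") state$step_size else -state$step_size
  state$current_speed <- min(max(state$current_speed + delta,
                                 state$speed_bounds[1]),
                             state$speed_bounds[2])
  state$last_direction <- direction
  state$successes_in_run <- 0L
  state$trials_in_run <- 0L
  state$decision <- direction
  state
}

#' Simulated performer with a logistic speed-success psychometric function
#'
#' Success probability decreases monotonically with cursor speed:
#' \eqn{P(\mathrm{success} \mid v) = \mathrm{logistic}((\theta - v) s)},
#' so that speed at the threshold \eqn{\theta} yields exactly 50% success
#' and the slope \eqn{s > 0} controls how sharply skill degrades as the
#' cursor accelerates.
#'
#' @param threshold speed at which success probability is 0.5.
#' @param slope positive logistic slope (per speed unit).
#' @return A function mapping speed to success probability.
#' @export
logistic_performer <- function(threshold = 1.0, slope = 5.0) {
  if (!is.finite(slope) || slope <= 0)
    stop("slope must be positive (faster must mean harder)")
  function(speed) stats::plogis((threshold - speed) * slope)
}

#' Run a staircased trial sequence against a simulated performer
#'
#' Runs `n_trials` trials: on each, success is drawn from the performer's
#' psychometric function at the current speed and the PEST state is
#' updated. Used both for the pre-task calibration block (60 trials) and
#' for the continued within-task adjustment.
#'
#' @param performer function mapping speed to success probability
#'   (monotone decreasing), e.g. [logistic_performer()].
#' @param n_trials number of trials to run.
#' @param state initial [init_staircase()] state.
#' @return List with `state` (final state), and a `trace` data.frame
#'   (`trial`, `speed`, `step`, `success`, `decision`).
#' @export
run_calibration <- function(performer, n_trials = 60L,
                            state = init_staircase()) {
  stopifnot(is.function(performer), inherits(state, "pest_staircase"))
  n_trials <- as.integer(n_trials)
  speed <- step <- numeric(n_trials)
  success <- integer(n_trials)
  decision <- character(n_trials)
  for (i in seq_len(n_trials)) {
    v <- state$current_speed
    p <- performer(v)
    if (!is.finite(p) || p < 0 || p > 1)
      stop("performer returned an invalid success probability")
    s <- stats::rbinom(1L, 1L, p)
    state <- pest_update(state, s)
    speed[i] <- v; step[i] <- state$step_size
    success[i] <- s; decision[i] <- state$decision
  }
  list(state = state,
       trace = data.frame(trial = seq_len(n_trials), speed = speed,
                          step = step, success = success,
                          decision = decision))
}
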