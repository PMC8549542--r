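#' Specify a momentary-happiness model
#'
#' Momentary happiness at a probe after trial \eqn{t} is modelled as a
#' weighted sum of exponentially discounted task events,
#' \deqn{H(t) = [w_0] + w_r \sum_{j=1}^{t} \gamma^{t-j} R_j +
#'   w_p \sum_{j=1}^{t} \gamma^{t-j} P_j + \epsilon,
#'   \quad \epsilon \sim N(0, \sigma),}
#' where \eqn{R_j} is the z-scored reward (points) obtained on trial
#' \eqn{j}, \eqn{P_j} the z-scored success indicator of the skilled
#' navigation component (1 = no barrier contacted), and the forgetting
#' factor \eqn{\gamma \in [0,1]} controls how quickly past events stop
#' mattering: \eqn{\gamma = 0} keeps only the most recent trial, and
#' \eqn{\gamma = 1} accumulates the whole history undiscounted.
#'
#' Four canonical variants are used for model comparison:
#' `"reward"` and `"performance"` (single-term, shared history decay),
#' `"reward_performance"` (both terms, one shared \eqn{\gamma}), and
#' `"reward_performance_sepgamma"` (both terms, each with its own
#' forgetting factor).
#'
#' Raw-rating fits include a baseline mood intercept \eqn{w_0} on the
#' native rating scale; z-scored fits omit it because standardized ratings
#' (and standardized regressors) are centred on zero.
#'
#' @param terms character vector, a non-empty subset of
#'   `c("reward", "performance")`, or one of the canonical model names
#'   above.
#' @param shared_gamma logical; if `FALSE` (both terms required) reward
#'   and performance histories decay with separate forgetting factors.
#' @param rating_mode `"zscored"` or `"raw"`. Raw mode adds the baseline
#'   intercept `w0`; z-scored mode omits it.
#' @return An object of class `"happiness_model"`: a list with elements
#'   `terms`, `shared_gamma`, `include_baseline`, `rating_mode`, `name`,
#'   and `k` (number of structural parameters, noise SD excluded).
#' @seealso [fit_happiness()], [predict_happiness()], [generate_ratings()]
#' @examples
#' happiness_model("reward_performance")
#' happiness_model("reward", rating_mode = "raw")
#' @export
happiness_model <- function(terms = c("reward", "performance"),
                            shared_gamma = TRUE,
                            rating_mode = c("zscored", "raw")) {
  canonical <- c("reward", "performance", "reward_performance",
                 "reward_performance_sepgamma")
  if (length(terms) == 1L && terms %in% canonical[3:4]) {
    shared_gamma <- terms != "reward_performance_sepgamma"
    terms <- c("reward", "performance")
  }
  terms <- match.arg(terms, c("reward", "performance"), several.ok = TRUE)
  rating_mode <- match.arg(rating_mode)
  if (!shared_gamma && length(terms) < 2L)
    stop("separate forgetting factors require both reward and performance terms")
  include_baseline <- rating_mode == "raw"
  name <- paste(terms, collapse = "_")
  if (!shared_gamma) name <- paste0(name, "_sepgamma")
  k <- length(terms) +                      # weights
    (if (shared_gamma) 1L else 2L) +        # forgetting factor(s)
    as.integer(include_baseline)            # w0
  structure(
    list(terms = terms, shared_gamma = shared_gamma,
         include_baseline = include_baseline, rating_mode = rating_mode,
         name = name, k = k),
    class = "happiness_model")
}

#' @export
print.happiness_model <- function(x, ...) {
  cat("Happiness model:", x$name, "\n")
  cat("  terms          :", paste(x$terms, collapse = ", "), "\n")
  cat("  forgetting     :",
      if (x$shared_gamma) "shared gamma" else "separate gamma per term", "\n")
  cat("  rating mode    :", x$rating_mode,
      if (x$include_baseline) "(baseline w0 included)" else "(no baseline)",
      "\n")
  cat("  structural k   :", x$k, "(noise SD excluded)\n")
  invisible(x)
}

#' Canonical four-model family
#'
#' The model set compared by summed BIC: reward only, performance only,
#' reward and performance with a shared forgetting factor, and reward and
#' performance with separate forgetting factors.
#'
#' @param rating_mode rating mode passed to [happiness_model()].
#' @return Named list of four `happiness_model` objects.
#' @export
happiness_model_family <- function(rating_mode = "zscored") {
  names <- c("reward", "performance", "reward_performance",
             "reward_performance_sepgamma")
  fam <- lapply(names, function(nm) {
    if (nm %in% c("reward", "performance"))
      happiness_model(nm, rating_mode = rating_mode)
    else
      happiness_model(nm, shared_gamma = nm == "reward_performance",
                      rating_mode = rating_mode)
  })
  names(fam) <- names
  fam
}

#' Construct happiness-model parameter sets
#'
#' Bundles the weights, forgetting factor(s) and noise SD demanded by a
#' [happiness_model()] specification, with domain checks.
#'
#' @param model a `happiness_model`.
#' @param w0 baseline mood (rating units); required iff the model includes
#'   a baseline.
#' @param w_reward,w_performance term weights (rating units per z-scored
#'   regressor unit); required iff the corresponding term is active.
#' @param gamma shared forgetting factor in \[0, 1\] (shared-gamma models).
#' @param gamma_reward,gamma_performance per-term forgetting factors
#'   (separate-gamma models).
#' @param sigma Gaussian rating-noise SD, `>= 0`.
#' @return Object of class `"happiness_params"` (named list).
#' @examples
#' m <- happiness_model("reward_performance")
#' happiness_params(m, w_reward = 0.39, w_performance = 0.18,
#'                  gamma = 0.48, sigma = 0.85)
#' @export
happiness_params <- function(model, w0 = NULL, w_reward = NULL,
                             w_performance = NULL, gamma = NULL,
                             gamma_reward = NULL, gamma_performance = NULL,
                             sigma = 0) {
  stopifnot(inherits(model, "happiness_model"))
  chk01 <- function(g, what) {
    if (is.null(g) || !is.finite(g) || g < 0 || g > 1)
      stop(what, " must be a single value in [0, 1]")
    g
  }
  p <- list()
  if (model$include_baseline) {
    if (is.null(w0)) stop("model includes a baseline: w0 is required")
    p$w0 <- as.numeric(w0)
  } else if (!is.null(w0)) {
    stop("w0 supplied but the model has no baseline term")
  }
  if ("reward" %in% model$terms) {
    if (is.null(w_reward)) stop("active reward term: w_reward is required")
    p$w_reward <- as.numeric(w_reward)
  }
  if ("performance" %in% model$terms) {
    if (is.null(w_performance))
      stop("active performance term: w_performance is required")
    p$w_performance <- as.numeric(w_performance)
  }
  if (model$shared_gamma) {
    p$gamma <- chk01(gamma, "gamma")
  } else {
    p$gamma_reward <- chk01(gamma_reward, "gamma_reward")
    p$gamma_performance <- chk01(gamma_performance, "gamma_performance")
  }
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  p$sigma <- as.numeric(sigma)
  structure(p, class = "happiness_params", model = model$name)
}

#' Exponentially discounted history sum
#'
#' Computes \eqn{S_t = \sum_{j=1}^{t} \gamma^{t-j} x_j} for a per-trial
#' event vector, evaluated through the numerically stable recursion
#' \eqn{S_t = \gamma S_{t-1} + x_t} (via [stats::filter()]).
#'
#' @param x numeric vector of per-trial events (trial 1 first).
#' @param gamma forgetting factor in \[0, 1\].
#' @param t trial index (or vector of indices) at which to evaluate; by
#'   default all trials.
#' @return `S_t` for each requested `t`.
#' @examples
#' decayed_sum(c(1, 2, 3), gamma = 0.5, t = 3)  # 0.25 + 1 + 3 = 4.25
#' @export
decayed_sum <- function(x, gamma, t = seq_along(x)) {
  if (!is.numeric(x) || length(x) == 0L) stop("x must be a numeric vector")
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must be in [0, 1]")
  if (any(t < 1L) || any(t > length(x))) stop("t out of range 1..length(x)")
  s <- as.numeric(stats::filter(x, gamma, method = "recursive"))
  s[t]
}

#' Build the z-scored reward and performance regressors
#'
#' Reward is the z-scored points outcome of the selected option on each
#' trial; performance is the z-scored success indicator (1 when no barrier
#' was contacted, 0 otherwise). Standardization uses the subject's full
#' trial sequence, free and forced trials alike, with the population-SD
#' convention (divide by n).
#'
#' @param trials a trial-log `data.frame` (see [simulate_subject()]), with
#'   columns `trial`, `reward_points`, `collision` at minimum.
#' @param ratings optional rating series; when given, its probe trials
#'   (pre-task probes excluded) are checked against the trial index range
#'   and stored as `probe_trials`.
#' @return Object of class `"happiness_regressors"`: list with numeric
#'   vectors `reward` and `performance` (one entry per trial, mean 0, SD 1)
#'   and `probe_trials`.
#' @export
build_regressors <- function(trials, ratings = NULL) {
  stopifnot(is.data.frame(trials))
  need <- c("trial", "reward_points", "collision")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(trials)
  if (!identical(as.integer(trials$trial), seq_len(n)))
    stop("trial indices must be contiguous from 1")
  zscore_pop <- function(v, what) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s < .Machine$double.eps^0.5)
      stop("degenerate regressor column '", what, "': zero variance")
    (v - m) / s
  }
  probe_trials <- integer(0)
  if (!is.null(ratings)) {
    probe_trials <- probe_trials_of(ratings)
    if (length(probe_trials) && (min(probe_trials) < 1L ||
                                 max(probe_trials) > n))
      stop("rating probe trials fall outside the trial index range")
  }
  structure(
    list(reward = zscore_pop(trials$reward_points, "reward"),
         performance = zscore_pop(1 - trials$collision, "performance"),
         probe_trials = probe_trials),
    class = "happiness_regressors")
}

# trial indices carrying model-relevant ratings (pre-task probes dropped)
probe_trials_of <- function(ratings) {
  stopifnot(is.data.frame(ratings))
  pre <- if ("pre_task" %in% names(ratings)) ratings$pre_task else
    ratings$trial < 1L
  as.integer(ratings$trial[!pre])
}

# decayed-sum design matrix at probe trials for the model's active terms,
# given gamma(s); columns ordered (w0), reward, performance
design_at_gamma <- function(model, regressors, gamma) {
  pt <- regressors$probe_trials
  cols <- list()
  if (model$include_baseline) cols$w0 <- rep(1, length(pt))
  g_r <- if (model$shared_gamma) gamma[1] else gamma[1]
  g_p <- if (model$shared_gamma) gamma[1] else gamma[2]
  if ("reward" %in% model$terms)
    cols$w_reward <- decayed_sum(regressors$reward, g_r, pt)
  if ("performance" %in% model$terms)
    cols$w_performance <- decayed_sum(regressors$performance, g_p, pt)
  do.call(cbind, cols)
}

#' Predict momentary happiness at probe trials
#'
#' Evaluates the deterministic part of the happiness model (no noise) at
#' each probe trial: the discounted reward/performance history sums,
#' weighted and, in raw mode, shifted by the baseline mood `w0`.
#'
#' @param model a [happiness_model()].
#' @param params a [happiness_params()] consistent with `model`.
#' @param regressors a [build_regressors()] result with non-empty
#'   `probe_trials`, or a trial-log `data.frame` combined with `ratings`.
#' @param ratings optional rating series supplying probe trials when
#'   `regressors` is a trial log.
#' @return Numeric vector of predictions, one per probe trial.
#' @export
predict_happiness <- function(model, params, regressors, ratings = NULL) {
  stopifnot(inherits(model, "happiness_model"))
  if (is.data.frame(regressors))
    regressors <- build_regressors(regressors, ratings)
  if (!length(regressors$probe_trials))
    stop("no probe trials: supply a rating series or probe_trials")
  gamma <- gamma_of(model, params)
  X <- design_at_gamma(model, regressors, gamma)
  w <- weights_of(model, params)
  drop(X %*% w)
}

gamma_of <- function(model, params) {
  if (model$shared_gamma) {
    if (is.null(params$gamma)) stop("missing parameter: gamma")
    params$gamma
  } else {
    if (is.null(params$gamma_reward) || is.null(params$gamma_performance))
      stop("missing parameter: gamma_reward / gamma_performance")
    c(params$gamma_reward, params$gamma_performance)
  }
}

weights_of <- function(model, params) {
  w <- numeric(0)
  if (model$include_baseline) {
    if (is.null(params$w0)) stop("missing parameter: w0")
    w <- c(w, w0 = params$w0)
  }
  if ("reward" %in% model$terms) {
    if (is.null(params$w_reward)) stop("missing parameter: w_reward")
    w <- c(w, w_reward = params$w_reward)
  }
  if ("performance" %in% model$terms) {
    if (is.null(params$w_performance))
      stop("missing parameter: w_performance")
    w <- c(w, w_performance = params$w_performance)
  }
  w
}
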