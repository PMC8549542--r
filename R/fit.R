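#' Fit a happiness model to one subject's ratings
#'
#' Estimates the model parameters by minimizing the residual sum of
#' squares between observed and predicted happiness ratings. The RSS is a
#' quadratic form in the weights at fixed forgetting factor(s), so the
#' weights are profiled out by ordinary least squares and the bounded
#' search runs only over gamma (1-D for shared-gamma models, 2-D for the
#' separate-gamma variant), multi-started from a grid of gamma values.
#' Ties between restarts are broken deterministically: lowest RSS, then
#' lowest gamma.
#'
#' The noise SD is the maximum-likelihood residual SD `sqrt(RSS/n)`
#' (consistent with the Gaussian profile likelihood behind [BIC]).
#' `r_squared` is `1 - RSS/TSS` with TSS the sum of squared deviations of
#' the ratings from their mean.
#'
#' @param trials trial-log data.frame (see [simulate_subject()]).
#' @param ratings rating series data.frame (`trial`, `rating`,
#'   `pre_task`); pre-task rows are excluded. For `rating_mode =
#'   "zscored"` models the ratings are used as given if their `mode`
#'   attribute is already `"zscored"`, and standardized (population SD)
#'   otherwise.
#' @param model a [happiness_model()] (default: shared-gamma reward +
#'   performance, z-scored).
#' @param restarts number of gamma starting values (default 10, evenly
#'   spread over \[0.05, 0.95\]).
#' @param weight_bounds box constraint on the weights (informational;
#'   the profiled least-squares solution is checked against it).
#' @param tol convergence tolerance on the RSS.
#' @return Object of class `"happiness_fit"`: estimates (`params`,
#'   including `sigma`), `rss`, `r_squared`, `n_ratings`, `bic`,
#'   `converged`, `n_restarts_used`, plus the data and regressors needed
#'   by the methods ([coef()], [predict()], [fitted()], [residuals()],
#'   [simulate()], [plot()], [BIC()]).
#' @examples
#' sess <- simulate_subject(seed = 1)
#' fit <- fit_happiness(sess$trials, sess$ratings)
#' coef(fit)
#' @export
fit_happiness <- function(trials, ratings,
                          model = happiness_model("reward_performance"),
                          restarts = 10L,
                          weight_bounds = c(-10, 10),
                          tol = 1e-8) {
  stopifnot(inherits(model, "happiness_model"))
  pre <- if ("pre_task" %in% names(ratings)) ratings$pre_task
         else ratings$trial < 1L
  ratings_used <- ratings[!pre, , drop = FALSE]
  y <- ratings_used$rating
  n <- length(y)
  if (n < model$k + 5L)
    stop("need at least ", model$k + 5L, " ratings to fit ", model$name)
  if (model$rating_mode == "zscored" &&
      !identical(attr(ratings, "mode"), "zscored")) {
    y <- zscore(y)
    ratings_used$rating <- y
  }
  reg <- build_regressors(trials, ratings_used)

  inner <- function(gamma) {
    X <- design_at_gamma(model, reg, gamma)
    ls <- stats::lm.fit(X, y)
    rss <- sum(ls$residuals^2)
    list(rss = rss, w = ls$coefficients)
  }
  obj <- function(gamma) inner(gamma)$rss

  d <- if (model$shared_gamma) 1L else 2L
  starts <- gamma_starts(restarts, d)
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    o <- stats::nlminb(as.numeric(starts[i, ]), obj,
                       lower = rep(0, d), upper = rep(1, d),
                       control = list(abs.tol = tol, rel.tol = tol))
    cand <- list(gamma = o$par, rss = o$objective, ok = o$convergence == 0)
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 &&
         sum(cand$gamma) < sum(best$gamma)))
      best <- cand
    conv <- conv || cand$ok
  }
  sol <- inner(best$gamma)
  if (any(!is.finite(sol$w)))
    stop("least-squares solution undefined (collinear regressors)")
  if (any(sol$w < weight_bounds[1] | sol$w > weight_bounds[2]))
    warning("profiled weights fall outside weight_bounds; returned unclamped")

  params <- as.list(sol$w)
  if (model$shared_gamma) {
    params$gamma <- best$gamma[1]
  } else {
    params$gamma_reward <- best$gamma[1]
    params$gamma_performance <- best$gamma[2]
  }
  params$sigma <- sqrt(sol$rss / n)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sol$rss / tss else NA_real_

  fit <- structure(
    list(model = model,
         params = structure(params, class = "happiness_params",
                            model = model$name),
         rss = sol$rss,
         r_squared = r2,
         n_ratings = n,
         n_restarts_used = nrow(starts),
         converged = conv,
         regressors = reg,
         ratings = ratings_used,
         call = match.call()),
    class = "happiness_fit")
  # a perfect (noise-free) fit has RSS = 0; BIC degenerates to -Inf there
  fit$bic <- if (sol$rss > 0) BIC(fit) else -Inf
  fit
}

# gamma start grid: restarts points in (0,1) for d = 1, a crossed grid for
# d = 2 (the separate-gamma surface is cheap enough to start coarsely)
gamma_starts <- function(restarts, d) {
  g <- seq(0.05, 0.95, length.out = max(2L, as.integer(restarts)))
  if (d == 1L) matrix(g, ncol = 1L)
  else {
    g2 <- seq(0.05, 0.95, length.out =
                max(2L, ceiling(sqrt(as.integer(restarts)))))
    as.matrix(expand.grid(g2, g2))
  }
}

# population z-score (divide by n)
zscore <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s < .Machine$double.eps^0.5)
    stop("cannot z-score a constant vector")
  (v - m) / s
}

#' Standardize a rating series within subject
#'
#' @param ratings rating series data.frame; pre-task rows are left out of
#'   the mean/SD computation and standardized with the same constants.
#' @return The series with standardized ratings and `mode` attribute
#'   `"zscored"`.
#' @export
zscore_ratings <- function(ratings) {
  pre <- if ("pre_task" %in% names(ratings)) ratings$pre_task
         else ratings$trial < 1L
  v <- ratings$rating[!pre]
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s < .Machine$double.eps^0.5)
    stop("cannot z-score a constant rating series")
  ratings$rating <- (ratings$rating - m) / s
  attr(ratings, "mode") <- "zscored"
  ratings
}

#' @export
print.happiness_fit <- function(x, digits = 3, ...) {
  cat("Happiness model fit:", x$model$name,
      sprintf("(%s ratings)\n", x$model$rating_mode))
  print(round(coef(x), digits))
  cat(sprintf("n = %d ratings, RSS = %.*f, r^2 = %.*f, BIC = %.*f\n",
              x$n_ratings, digits, x$rss, digits, x$r_squared,
              digits, x$bic))
  invisible(x)
}

#' @export
coef.happiness_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
fitted.happiness_fit <- function(object, ...) {
  predict_happiness(object$model, object$params, object$regressors)
}

#' @export
residuals.happiness_fit <- function(object, ...) {
  object$ratings$rating - fitted(object)
}

#' Predict from a fitted happiness model
#'
#' With no new data, returns the in-sample predictions at the fitted
#' probe trials. With `newtrials`/`newratings`, rebuilds the regressors
#' for the new session and predicts at its probe trials with the fitted
#' parameters.
#'
#' @param object a `happiness_fit`.
#' @param newtrials,newratings optional new session data.
#' @param ... unused.
#' @export
predict.happiness_fit <- function(object, newtrials = NULL,
                                  newratings = NULL, ...) {
  if (is.null(newtrials)) return(fitted(object))
  predict_happiness(object$model, object$params, newtrials, newratings)
}

#' Simulate rating series from a fitted happiness model
#'
#' Parametric simulation at the fitted parameters: model predictions at
#' the fitted probe trials plus Gaussian noise with the estimated
#' residual SD (the mechanism used by the recovery analyses).
#'
#' @param object a `happiness_fit`.
#' @param nsim number of simulated series.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame of `nsim` columns (`sim_1`, ...) plus `trial`.
#' @export
simulate.happiness_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                           object$params$sigma))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(trial = object$regressors$probe_trials), out)
}

#' @export
summary.happiness_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.happiness_fit")
}

#' @export
print.summary.happiness_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  res <- residuals(f)
  cat("Residuals:\n")
  print(round(stats::quantile(res, c(0, .25, .5, .75, 1)), digits))
  cat(sprintf("Converged: %s (%d restarts)\n",
              f$converged, f$n_restarts_used))
  invisible(x)
}

#' Plot observed and fitted happiness trajectories
#'
#' @param x a `happiness_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.happiness_fit <- function(x, ...) {
  pt <- x$regressors$probe_trials
  y <- x$ratings$rating
  graphics::plot(pt, y, type = "p", pch = 16, col = "grey40",
                 xlab = "trial", ylab = "happiness rating", ...)
  graphics::lines(pt, fitted(x), col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("rating", "model"),
                   pch = c(16, NA), lty = c(NA, 1),
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Bayesian information criterion of a happiness fit
#'
#' Uses the Gaussian profile-likelihood convention
#' `BIC = n * log(RSS/n) + k * log(n)` with `k` the number of structural
#' parameters (weights, forgetting factor(s) and, in raw mode, the
#' baseline; the noise SD is excluded from `k`). This drops the constant
#' `n * (1 + log(2*pi))` shared by all models, so only BIC differences
#' are interpretable — which is all model comparison uses.
#'
#' @param object a `happiness_fit`.
#' @param ... unused.
#' @export
BIC.happiness_fit <- function(object, ...) {
  compute_bic(object$rss, object$n_ratings, object$model$k)
}

#' @rdname BIC.happiness_fit
#' @param rss residual sum of squares (> 0).
#' @param n number of ratings.
#' @param k number of structural parameters.
#' @export
compute_bic <- function(rss, n, k) {
  if (!is.finite(rss) || rss <= 0)
    stop("BIC undefined: RSS must be strictly positive")
  if (n <= 0) stop("BIC undefined: n must be positive")
  n * log(rss / n) + k * log(n)
}

#' Likelihood-ratio test between nested happiness fits
#'
#' Tests whether the extra term(s) of the full model improve the fit,
#' using the Gaussian profile-likelihood statistic
#' `n * log(RSS_reduced / RSS_full)` referred to a chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference. Used for per-subject significance of individual weights
#' (full two-term model against a single-term reduction).
#'
#' @param full,reduced nested `happiness_fit` objects on the same
#'   ratings.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "happiness_fit"),
            inherits(reduced, "happiness_fit"))
  if (full$n_ratings != reduced$n_ratings)
    stop("fits must be on the same rating series")
  df <- full$model$k - reduced$model$k
  if (df <= 0) stop("'full' must have more structural parameters")
  stat <- full$n_ratings * log(reduced$rss / full$rss)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Compare happiness models across a cohort by summed BIC
#'
#' Fits every model to every subject (on z-scored ratings, so subjects
#' with larger rating variance do not dominate), sums BIC across
#' subjects per model and reports the difference from the best (lowest)
#' model alongside the across-subject mean r-squared.
#'
#' @param cohort list of sessions, each a list with `trials` and
#'   `ratings` (e.g. from [simulate_cohort()] or [simulate_subject()]).
#' @param models named list of [happiness_model()]s (default: the
#'   canonical four-model family).
#' @param fits optional precomputed fits: a list (one element per model
#'   name) of lists of `happiness_fit`s; when given, no fitting is done.
#' @param ... passed to [fit_happiness()].
#' @return Object of class `"happiness_comparison"`: a data.frame with
#'   one row per model (`model`, `k`, `mean_r2`, `bic`, `delta_bic`),
#'   best model first by `delta_bic = 0`; attribute `fits` holds the
#'   per-subject fits.
#' @export
compare_happiness_models <- function(cohort,
                                     models = happiness_model_family(),
                                     fits = NULL, ...) {
  stopifnot(length(cohort) >= 1L)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "name")
  if (is.null(fits)) {
    fits <- lapply(models, function(m)
      lapply(cohort, function(s) fit_happiness(s$trials, s$ratings, m, ...)))
  }
  if (!setequal(names(fits), names(models)))
    stop("fits must contain one entry per model")
  for (nm in names(models)) {
    if (length(fits[[nm]]) != length(cohort))
      stop("missing subject fits for model ", nm)
  }
  tab <- data.frame(
    model = names(models),
    k = vapply(models, `[[`, 0L, "k"),
    mean_r2 = vapply(names(models), function(nm)
      mean(vapply(fits[[nm]], `[[`, 0, "r_squared")), 0),
    bic = vapply(names(models), function(nm)
      sum(vapply(fits[[nm]], `[[`, 0, "bic")), 0),
    row.names = NULL)
  tab$delta_bic <- tab$bic - min(tab$bic)
  structure(tab, class = c("happiness_comparison", "data.frame"),
            fits = fits)
}

#' @export
print.happiness_comparison <- function(x, digits = 2, ...) {
  cat("Model comparison (BIC summed across",
      length(attr(x, "fits")[[1]]), "subjects)\n")
  y <- as.data.frame(x)
  y$mean_r2 <- round(y$mean_r2, digits)
  y$bic <- round(y$bic)
  y$delta_bic <- round(y$delta_bic)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Trim early ratings and optionally detrend
#'
#' Robustness preprocessing: drops the first `ceiling(trim_fraction * n)`
#' ratings (the settling-in period where ratings deviate from model
#' predictions on average) and, if `detrend`, removes the least-squares
#' linear trend in probe order from the remaining ratings.
#'
#' @param ratings rating series data.frame.
#' @param trim_fraction fraction of initial ratings to drop.
#' @param detrend remove a linear trend from the remaining ratings?
#' @param min_remaining smallest acceptable number of remaining ratings.
#' @return The processed rating series (pre-task rows are dropped).
#' @export
trim_and_detrend <- function(ratings, trim_fraction = 0.10,
                             detrend = FALSE, min_remaining = 8L) {
  pre <- if ("pre_task" %in% names(ratings)) ratings$pre_task
         else ratings$trial < 1L
  r <- ratings[!pre, , drop = FALSE]
  n <- nrow(r)
  drop_n <- ceiling(trim_fraction * n)
  if (n - drop_n < min_remaining)
    stop("trimming would leave fewer than ", min_remaining, " ratings")
  if (drop_n > 0L) r <- r[-seq_len(drop_n), , drop = FALSE]
  if (detrend) {
    idx <- seq_len(nrow(r))
    r$rating <- stats::lm.fit(cbind(1, idx), r$rating)$residuals
  }
  attr(r, "mode") <- attr(ratings, "mode")
  rownames(r) <- NULL
  r
}
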