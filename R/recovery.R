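#' Specify a synthetic cohort for recovery analyses
#'
#' Recovery analyses need a population of agents with heterogeneous true
#' parameters. Individual human parameter estimates are not available, so
#' agents sample their parameters from normal distributions matched to
#' the published group statistics of the z-scored reward + performance
#' model: mean +/- SEM with between-agent SD = SEM * sqrt(n), giving
#' `w_reward ~ N(0.39, 0.23^2)`, `w_performance ~ N(0.18, 0.17^2)`,
#' `gamma ~ N(0.48, 0.29^2)` truncated to \[0, 1\] and
#' `sigma ~ N(0.85, 0.115^2)` truncated positive. This preserves the
#' population's location and spread, which is what recovery correlations
#' depend on.
#'
#' @param n_agents cohort size (default 33).
#' @param means,sds named numeric vectors of per-parameter population
#'   mean and SD. Recognized names: `w0`, `w_reward`, `w_performance`,
#'   `gamma`, `gamma_reward`, `gamma_performance`, `sigma`. Setting an SD
#'   to 0 fixes that parameter across agents.
#' @param task a [task_config()] shared by all agents.
#' @param seed cohort seed; per-agent seeds are derived from it so agents
#'   are independent and the cohort reproducible.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_agents = 33L,
                        means = c(w_reward = 0.39, w_performance = 0.18,
                                  gamma = 0.48, sigma = 0.85),
                        sds = c(w_reward = 0.04, w_performance = 0.03,
                                gamma = 0.05, sigma = 0.02) *
                          sqrt(n_agents),
                        task = task_config(), seed = 1L) {
  n_agents <- as.integer(n_agents)
  if (n_agents < 2L) stop("n_agents must be >= 2")
  if (any(sds < 0)) stop("parameter SDs must be >= 0")
  if (!all(names(sds) %in% names(means)))
    stop("sds must be named after entries of means")
  if (all(sds == 0))
    warning("all parameter SDs are zero: recovery correlations undefined")
  structure(list(n_agents = n_agents, means = means, sds = sds,
                 task = task, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw per-agent true parameters for a cohort
#'
#' Samples each agent's parameters from the cohort's normal
#' distributions, truncating forgetting factors to \[0, 1\] and the noise
#' SD to positive values (by resampling).
#'
#' @param spec a [cohort_spec()].
#' @param model the generative [happiness_model()].
#' @return data.frame with `agent`, `seed` and one column per parameter.
#' @export
draw_cohort_params <- function(spec,
                               model = happiness_model("reward_performance")) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(model, "happiness_model"))
  set.seed(spec$seed)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_agents)
  need <- param_names(model)
  miss <- setdiff(need, names(spec$means))
  if (length(miss))
    stop("cohort spec lacks distribution(s) for: ",
         paste(miss, collapse = ", "))
  rtrunc <- function(n, mean, sd, lo, hi) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- which(x < lo | x > hi)
    }
    x
  }
  lims <- function(p) {
    if (grepl("^gamma", p)) c(0, 1)
    else if (p == "sigma") c(.Machine$double.eps, Inf)
    else c(-Inf, Inf)
  }
  out <- data.frame(agent = seq_len(spec$n_agents), seed = agent_seeds)
  for (p in need) {
    sd_p <- if (p %in% names(spec$sds)) spec$sds[[p]] else 0
    l <- lims(p)
    out[[p]] <- rtrunc(spec$n_agents, spec$means[[p]], sd_p, l[1], l[2])
  }
  out
}

param_names <- function(model) {
  c(if (model$include_baseline) "w0",
    if ("reward" %in% model$terms) "w_reward",
    if ("performance" %in% model$terms) "w_performance",
    if (model$shared_gamma) "gamma" else c("gamma_reward",
                                           "gamma_performance"),
    "sigma")
}

params_from_row <- function(model, row) {
  args <- as.list(row[intersect(param_names(model), names(row))])
  do.call(happiness_params, c(list(model = model), args))
}

#' Simulate a synthetic cohort under a generative happiness model
#'
#' Each agent gets an independent task realization (schedule, choices,
#' staircased barrier outcomes) and a rating series generated from its
#' own true parameters with its own noise SD.
#'
#' @param spec a [cohort_spec()].
#' @param model generative [happiness_model()].
#' @param agent_template an [agent_spec()] supplying the choice/
#'   psychometric plumbing shared by all agents.
#' @return Object of class `"hedonometer_cohort"`: list with `params`
#'   (the [draw_cohort_params()] manifest), `sessions` (per-agent lists
#'   with `trials`, `ratings`), `model` and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            model = happiness_model("reward_performance"),
                            agent_template = agent_spec()) {
  manifest <- draw_cohort_params(spec, model)
  sessions <- lapply(seq_len(spec$n_agents), function(i) {
    p <- params_from_row(model, manifest[i, ])
    ag <- agent_template
    ag$happiness_params <- p
    ag$model <- model
    simulate_subject(spec$task, ag, seed = manifest$seed[i])
  })
  structure(list(params = manifest, sessions = sessions,
                 model = model, spec = spec),
            class = "hedonometer_cohort")
}

#' @export
print.hedonometer_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d agents, generative model %s\n",
              x$spec$n_agents, x$model$name))
  invisible(x)
}

#' Parameter recovery on a simulated cohort
#'
#' Fits the generative model to each simulated agent and compares true
#' with estimated parameters: per-parameter Spearman rank correlations
#' (the noise SD enters as true sigma vs estimated residual SD) and mean
#' estimation bias.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param model model to fit (defaults to the cohort's generative model).
#' @param ... passed to [fit_happiness()].
#' @return Object of class `"recovery_result"`: list with `table`
#'   (per-parameter `spearman_rho`, `mean_true`, `mean_estimated`,
#'   `bias`), `true` and `estimated` data.frames, `fits`, and
#'   `n_failed` (fits that errored, excluded with a warning).
#' @export
parameter_recovery <- function(cohort, model = cohort$model, ...) {
  stopifnot(inherits(cohort, "hedonometer_cohort"))
  pn <- param_names(model)
  fits <- vector("list", length(cohort$sessions))
  ok <- logical(length(fits))
  for (i in seq_along(fits)) {
    fits[[i]] <- tryCatch(
      fit_happiness(cohort$sessions[[i]]$trials,
                    cohort$sessions[[i]]$ratings, model, ...),
      error = function(e) e)
    ok[i] <- inherits(fits[[i]], "happiness_fit")
  }
  n_failed <- sum(!ok)
  if (n_failed)
    warning(n_failed, " agent fit(s) failed and were excluded")
  est <- do.call(rbind, lapply(fits[ok], function(f)
    as.data.frame(as.list(coef(f)))))
  true <- cohort$params[ok, pn, drop = FALSE]
  tab <- data.frame(
    parameter = pn,
    spearman_rho = vapply(pn, function(p) {
      if (stats::sd(true[[p]]) == 0 || stats::sd(est[[p]]) == 0)
        return(NA_real_)
      stats::cor(true[[p]], est[[p]], method = "spearman")
    }, 0),
    mean_true = vapply(pn, function(p) mean(true[[p]]), 0),
    mean_estimated = vapply(pn, function(p) mean(est[[p]]), 0),
    row.names = NULL)
  tab$bias <- tab$mean_estimated - tab$mean_true
  structure(list(table = tab, true = true, estimated = est,
                 fits = fits[ok], n_failed = n_failed,
                 model = model),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, digits = 2, ...) {
  cat("Parameter recovery,", x$model$name, "model,",
      nrow(x$true), "agents\n")
  y <- x$table
  y[-1] <- lapply(y[-1], round, digits)
  print(y, row.names = FALSE)
  if (x$n_failed) cat(x$n_failed, "failed fits excluded\n")
  invisible(x)
}

#' Plot true against estimated parameters
#'
#' One panel per parameter, identity line overlaid (the recovery
#' scatter).
#'
#' @param x a `recovery_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.recovery_result <- function(x, ...) {
  pn <- names(x$true)
  old <- graphics::par(mfrow = c(1, length(pn)))
  on.exit(graphics::par(old))
  for (p in pn) {
    graphics::plot(x$true[[p]], x$estimated[[p]], pch = 16,
                   xlab = paste("true", p),
                   ylab = paste("estimated", p), ...)
    graphics::abline(0, 1, col = "firebrick")
  }
  invisible(x)
}

#' Model recovery: confusion matrix of generative vs best-BIC model
#'
#' For each generative model, simulates a cohort, fits all candidate
#' models to every agent, and records which model wins by BIC per agent
#' and (by summed BIC) per cohort.
#'
#' @param spec a [cohort_spec()] template reused for every generative
#'   model (its seed is offset per model so cohorts differ).
#' @param models named list of candidate [happiness_model()]s (default:
#'   the canonical four).
#' @param ... passed to [fit_happiness()].
#' @return Object of class `"model_recovery"`: list with `confusion`
#'   (matrix of per-agent best-BIC counts, generative models in rows) and
#'   `cohort_winner` (named character, summed-BIC winner per generative
#'   model).
#' @export
model_recovery <- function(spec = cohort_spec(),
                           models = happiness_model_family(), ...) {
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "name")
  nm <- names(models)
  confusion <- matrix(0L, length(nm), length(nm), dimnames = list(
    generative = nm, best_bic = nm))
  winner <- character(length(nm)); names(winner) <- nm
  for (gi in seq_along(nm)) {
    gspec <- spec
    gspec$seed <- spec$seed + gi - 1L
    gen <- models[[gi]]
    gspec$means <- default_means_for(gen, spec$means)
    gspec$sds <- default_sds_for(gen, spec$sds)
    cohort <- simulate_cohort(gspec, gen)
    cmp <- compare_happiness_models(cohort$sessions, models, ...)
    fits <- attr(cmp, "fits")
    for (a in seq_len(gspec$n_agents)) {
      bics <- vapply(nm, function(m) fits[[m]][[a]]$bic, 0)
      confusion[gi, which.min(bics)] <- confusion[gi, which.min(bics)] + 1L
    }
    winner[gi] <- cmp$model[which.min(cmp$bic)]
  }
  structure(list(confusion = confusion, cohort_winner = winner,
                 models = nm),
            class = "model_recovery")
}

# extend the reward+performance population parameters to single-term and
# separate-gamma generative models (same marginals; shared gamma splits
# into two identical per-term distributions)
default_means_for <- function(model, means) {
  out <- means
  if (!model$shared_gamma && !"gamma_reward" %in% names(out)) {
    out <- c(out, gamma_reward = unname(out[["gamma"]]),
             gamma_performance = unname(out[["gamma"]]))
  }
  out
}

default_sds_for <- function(model, sds) {
  out <- sds
  if (!model$shared_gamma && !"gamma_reward" %in% names(out)) {
    out <- c(out, gamma_reward = unname(out[["gamma"]]),
             gamma_performance = unname(out[["gamma"]]))
  }
  out
}

#' @export
print.model_recovery <- function(x, ...) {
  cat("Model recovery (per-agent best-BIC counts)\n")
  print(x$confusion)
  cat("Cohort-level summed-BIC winners:\n")
  for (m in x$models)
    cat(sprintf("  generated from %-28s -> %s\n", m, x$cohort_winner[m]))
  invisible(x)
}
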