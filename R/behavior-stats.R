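#' Condition split of happiness ratings with a Wilcoxon signed-rank test
#'
#' Assigns each rating to the condition of the immediately preceding
#' trial — either which reward option was selected (`"reward_level"`:
#' currently-high vs currently-low mean option) or the barrier outcome
#' (`"collision"`: clean run vs at least one collision) — computes
#' per-subject condition means, and tests the paired across-subject
#' difference with a two-sided Wilcoxon signed-rank test. Subjects
#' lacking ratings in one condition are excluded with a warning. A
#' window-averaging variant assigns each rating the mean condition of
#' all trials since the previous probe.
#'
#' @param cohort list of sessions (`trials` + `ratings` each).
#' @param condition `"reward_level"` or `"collision"`.
#' @param standardize z-score each subject's ratings first? (default
#'   `TRUE`; reported in the output).
#' @param window `"last_trial"` (default) or `"since_previous_probe"`.
#' @return Object of class `"condition_split"`: list with `condition`,
#'   `labels`, `per_subject` (means per condition), `group_mean`,
#'   `group_sem`, `statistic` (V), `z` (normal approximation), `p_value`,
#'   `n_subjects`, `zscored`.
#' @export
condition_split_test <- function(cohort,
                                 condition = c("reward_level", "collision"),
                                 standardize = TRUE,
                                 window = c("last_trial",
                                            "since_previous_probe")) {
  condition <- match.arg(condition)
  window <- match.arg(window)
  labels <- switch(condition,
                   reward_level = c("high_reward", "low_reward"),
                   collision = c("no_collision", "collision"))
  per_subject <- t(vapply(cohort, function(s) {
    r <- s$ratings[!s$ratings$pre_task, , drop = FALSE]
    y <- if (standardize) zscore(r$rating) else r$rating
    tr <- s$trials
    cond_trial <- switch(condition,
      reward_level = ifelse(tr$chosen_option == tr$high_option,
                            labels[1], labels[2]),
      collision = ifelse(tr$collision == 0L, labels[1], labels[2]))
    if (window == "last_trial") {
      cond <- cond_trial[r$trial]
    } else {
      prev <- c(0L, utils::head(r$trial, -1L))
      cond <- vapply(seq_along(r$trial), function(i) {
        win <- (prev[i] + 1L):r$trial[i]
        if (mean(cond_trial[win] == labels[1]) >= 0.5) labels[1]
        else labels[2]
      }, "")
    }
    c(mean(y[cond == labels[1]]), mean(y[cond == labels[2]]))
  }, numeric(2)))
  colnames(per_subject) <- labels
  keep <- stats::complete.cases(per_subject)
  if (any(!keep))
    warning(sum(!keep), " subject(s) lacked one condition and were excluded")
  per_subject <- per_subject[keep, , drop = FALSE]
  n <- nrow(per_subject)
  if (n < 2L) stop("need at least 2 subjects with both conditions")
  d <- per_subject[, 1] - per_subject[, 2]
  wt <- stats::wilcox.test(per_subject[, 1], per_subject[, 2],
                           paired = TRUE, exact = FALSE, correct = FALSE)
  # z from the normal approximation of the signed-rank statistic
  v <- unname(wt$statistic)
  mu_v <- n * (n + 1) / 4
  sd_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  structure(
    list(condition = condition, labels = labels,
         per_subject = per_subject,
         group_mean = colMeans(per_subject),
         group_sem = apply(per_subject, 2, stats::sd) / sqrt(n),
         mean_difference = mean(d),
         statistic = v, z = (v - mu_v) / sd_v,
         p_value = wt$p.value, n_subjects = n, zscored = standardize,
         window = window),
    class = "condition_split")
}

#' @export
print.condition_split <- function(x, digits = 3, ...) {
  cat(sprintf("Condition split (%s, %s ratings, n = %d subjects)\n",
              x$condition, if (x$zscored) "z-scored" else "raw",
              x$n_subjects))
  for (i in 1:2)
    cat(sprintf("  %-14s %6.*f +/- %.*f (SEM)\n", x$labels[i],
                digits, x$group_mean[i], digits, x$group_sem[i]))
  cat(sprintf("  Wilcoxon signed-rank V = %g, z = %.2f, p = %.3g\n",
              x$statistic, x$z, x$p_value))
  invisible(x)
}

#' Rank correlation between per-subject values and a covariate
#'
#' Spearman rank correlation with its p-value, the workhorse for
#' questionnaire/parameter association checks (e.g. baseline mood against
#' symptom scores, performance weight against starting cursor speed).
#'
#' @param values,covariate numeric vectors of equal length (pairs with
#'   missing values dropped).
#' @param method correlation method (default `"spearman"`).
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
correlate_covariate <- function(values, covariate, method = "spearman") {
  if (length(values) != length(covariate))
    stop("values and covariate must have equal length")
  keep <- stats::complete.cases(values, covariate)
  values <- values[keep]; covariate <- covariate[keep]
  if (length(values) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(values) == 0 || stats::sd(covariate) == 0)
    stop("undefined correlation: constant vector")
  ct <- suppressWarnings(
    stats::cor.test(values, covariate, method = method))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(values), method = method)
}

#' Split-half reliability of happiness-model parameters
#'
#' Fits the model separately to each subject's two task blocks (ratings
#' re-standardized within block for z-scored models) and correlates the
#' block-1 with block-2 estimates across subjects, per parameter
#' (Spearman).
#'
#' @param cohort list of sessions whose trial logs carry a `block`
#'   column with at least two blocks.
#' @param model the [happiness_model()] to fit in both blocks.
#' @param blocks length-2 vector naming the two blocks to compare.
#' @param ... passed to [fit_happiness()].
#' @return data.frame with `parameter`, `rho`, `p_value`, `n_subjects`.
#' @export
split_half_reliability <- function(cohort,
                                   model = happiness_model("reward_performance"),
                                   blocks = c(1L, 2L), ...) {
  fit_block <- function(s, b) {
    tr <- s$trials[s$trials$block == b, , drop = FALSE]
    first <- min(tr$trial)
    tr$trial <- tr$trial - first + 1L
    ra <- s$ratings[!s$ratings$pre_task &
                      s$ratings$trial >= first &
                      s$ratings$trial <= max(tr$trial) + first - 1L, ,
                    drop = FALSE]
    ra$trial <- ra$trial - first + 1L
    attr(ra, "mode") <- "raw"   # force within-block re-standardization
    fit_happiness(tr, ra, model, ...)
  }
  est <- lapply(cohort, function(s)
    lapply(blocks, function(b) coef(fit_block(s, b))))
  pn <- names(est[[1]][[1]])
  out <- data.frame(parameter = pn, rho = NA_real_, p_value = NA_real_,
                    n_subjects = length(cohort))
  for (j in seq_along(pn)) {
    a <- vapply(est, function(e) e[[1]][[pn[j]]], 0)
    b <- vapply(est, function(e) e[[2]][[pn[j]]], 0)
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    out$rho[j] <- unname(ct$estimate)
    out$p_value[j] <- ct$p.value
  }
  out
}
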