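#' Write a session's trial log and ratings as delimited text
#'
#' Two comma-separated UTF-8 files with header rows are written under a
#' common prefix: `<prefix>_trials.csv` (one row per trial: `trial`,
#' `block`, `choice_type`, `high_option`, `chosen_option`,
#' `reward_points`, `collision`, `cursor_speed`, `probe_after`) and
#' `<prefix>_ratings.csv` (`trial`, `rating`, `pre_task`, `mode`).
#' Floats are written with full decimal precision so that write-then-read
#' reproduces the records exactly.
#'
#' @param trials trial-log data.frame.
#' @param ratings rating-series data.frame.
#' @param prefix file path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_trial_log <- function(trials, ratings, prefix) {
  tcols <- c("trial", "block", "choice_type", "high_option",
             "chosen_option", "reward_points", "collision", "cursor_speed",
             "probe_after")
  miss <- setdiff(tcols, names(trials))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "))
  t_out <- trials[tcols]
  t_out$reward_points <- sprintf("%.17g", t_out$reward_points)
  t_out$cursor_speed <- sprintf("%.17g", t_out$cursor_speed)
  r_out <- data.frame(trial = ratings$trial,
                      rating = sprintf("%.17g", ratings$rating),
                      pre_task = as.integer(ratings$pre_task),
                      mode = attr_mode(ratings))
  paths <- paste0(prefix, c("_trials.csv", "_ratings.csv"))
  utils::write.csv(t_out, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(r_out, paths[2], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

attr_mode <- function(ratings) {
  m <- attr(ratings, "mode")
  if (is.null(m)) "raw" else m
}

#' Read a session's trial log and ratings back from delimited text
#'
#' Validates the documented schema: required columns, 1-based contiguous
#' trial indices, and that every probe-flagged trial carries a rating
#' (when a ratings file is present). Violations raise errors naming the
#' offending row and column.
#'
#' @param prefix the prefix passed to [write_trial_log()].
#' @param require_ratings error if the ratings file is absent? A
#'   trials-only log is valid input for simulation diagnostics but is
#'   refused by the fitting functions downstream.
#' @return List with `trials` and `ratings` (or `NULL`).
#' @export
read_trial_log <- function(prefix, require_ratings = FALSE) {
  tpath <- paste0(prefix, "_trials.csv")
  rpath <- paste0(prefix, "_ratings.csv")
  if (!file.exists(tpath)) stop("no trial log at ", tpath)
  trials <- utils::read.csv(tpath, stringsAsFactors = FALSE)
  tcols <- c("trial", "block", "choice_type", "high_option",
             "chosen_option", "reward_points", "collision", "cursor_speed",
             "probe_after")
  miss <- setdiff(tcols, names(trials))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "))
  jump <- which(diff(trials$trial) != 1L)
  if (length(jump) || (nrow(trials) && trials$trial[1] != 1L)) {
    row <- if (length(jump)) jump[1] + 1L else 1L
    stop("non-contiguous trial index at row ", row, ", column 'trial'")
  }
  ratings <- NULL
  if (file.exists(rpath)) {
    ratings <- utils::read.csv(rpath, stringsAsFactors = FALSE)
    rcols <- c("trial", "rating", "pre_task", "mode")
    miss <- setdiff(rcols, names(ratings))
    if (length(miss))
      stop("rating series is missing column(s): ",
           paste(miss, collapse = ", "))
    mode <- unique(ratings$mode)
    if (length(mode) != 1L)
      stop("rating series mixes rating modes")
    ratings$pre_task <- as.logical(ratings$pre_task)
    probe_trials <- which(trials$probe_after == 1L)
    missing_probe <- setdiff(probe_trials, ratings$trial[!ratings$pre_task])
    if (length(missing_probe))
      stop("probe without rating at trial ", missing_probe[1],
           " (column 'probe_after')")
    ratings$mode <- NULL
    attr(ratings, "mode") <- mode
  } else if (require_ratings) {
    stop("no rating series at ", rpath)
  }
  list(trials = trials, ratings = ratings)
}

#' Write a cohort manifest (true parameters and seeds)
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "hedonometer_cohort"))
  m <- cohort$params
  num <- vapply(m, is.double, TRUE)
  m[num] <- lapply(m[num], function(v) sprintf("%.17g", v))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble and validate a run configuration
#'
#' Bundles everything [run_experiment()] needs; unknown arguments are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param task a [task_config()].
#' @param cohort a [cohort_spec()] (its `task`/`seed` are overridden by
#'   `task` and `seed` here).
#' @param models named list of candidate models.
#' @param stages subset of `c("simulate", "behavior", "fit", "compare",
#'   "recover")` to run.
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @param restarts fitting restarts.
#' @param verbose logical.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(task = task_config(), cohort = cohort_spec(),
                       models = happiness_model_family(),
                       stages = c("simulate", "behavior", "fit",
                                  "compare", "recover"),
                       seed = 1L, out_dir = tempfile("hedonometer_run_"),
                       restarts = 10L, verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(inherits(task, "task_config"), inherits(cohort, "cohort_spec"))
  cohort$task <- task
  cohort$seed <- as.integer(seed)
  structure(list(task = task, cohort = cohort, models = models,
                 stages = stages, seed = as.integer(seed),
                 out_dir = out_dir, restarts = as.integer(restarts),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full synthetic pipeline: simulate, analyse, compare, recover
#'
#' Orchestrates the standard analysis order on a synthetic cohort:
#' cohort simulation, behavioural condition splits, per-subject fits of
#' the generative model, four-model BIC comparison, and parameter
#' recovery. All outputs are written to `config$out_dir` as delimited
#' text, along with a JSON manifest recording the seed and configuration
#' summary; the run is fully deterministic given the global seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `behavior`, `comparison`, `recovery`) and `out_dir`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(...)
  gen <- config$models[["reward_performance"]]
  if (is.null(gen)) gen <- config$models[[1]]
  res <- list(out_dir = config$out_dir)

  say("simulating cohort of ", config$cohort$n_agents, " agents")
  cohort <- simulate_cohort(config$cohort, gen)
  res$cohort <- cohort
  if ("simulate" %in% config$stages) {
    write_cohort_manifest(cohort, file.path(config$out_dir, "manifest.csv"))
    for (i in seq_along(cohort$sessions))
      write_trial_log(cohort$sessions[[i]]$trials,
                      cohort$sessions[[i]]$ratings,
                      file.path(config$out_dir, sprintf("agent_%02d", i)))
  }

  if ("behavior" %in% config$stages) {
    say("behavioural statistics")
    res$behavior <- list(
      reward = condition_split_test(cohort$sessions, "reward_level"),
      collision = condition_split_test(cohort$sessions, "collision"))
    beh <- do.call(rbind, lapply(res$behavior, function(b)
      data.frame(condition = b$condition,
                 level = b$labels,
                 mean = b$group_mean, sem = b$group_sem,
                 z = b$z, p_value = b$p_value)))
    utils::write.csv(beh, file.path(config$out_dir, "behavior.csv"),
                     row.names = FALSE)
  }

  if (any(c("fit", "compare") %in% config$stages)) {
    say("fitting ", length(config$models), " models per agent")
    cmp <- compare_happiness_models(cohort$sessions, config$models,
                                    restarts = config$restarts)
    res$comparison <- cmp
    utils::write.csv(as.data.frame(cmp),
                     file.path(config$out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    fits <- attr(cmp, "fits")[[gen$name]]
    est <- do.call(rbind, lapply(seq_along(fits), function(i)
      cbind(data.frame(agent = i), as.data.frame(as.list(coef(fits[[i]]))),
            data.frame(rss = fits[[i]]$rss, r_squared = fits[[i]]$r_squared,
                       bic = fits[[i]]$bic, n = fits[[i]]$n_ratings))))
    utils::write.csv(est, file.path(config$out_dir, "fits.csv"),
                     row.names = FALSE)
  }

  if ("recover" %in% config$stages) {
    say("parameter recovery")
    rec <- parameter_recovery(cohort, restarts = config$restarts)
    res$recovery <- rec
    utils::write.csv(rec$table,
                     file.path(config$out_dir, "recovery.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "hedonometer",
    version = as.character(utils::packageVersion("hedonometer")),
    seed = config$seed,
    n_agents = config$cohort$n_agents,
    n_trials = config$task$n_trials,
    stages = config$stages,
    models = names(config$models))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
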