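#' Build a run configuration
#'
#' A validated, JSON-round-trippable description of an end-to-end run. Every
#' stochastic stage receives an explicit seed derived from `seed`.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"adaptation"`.
#' @param n_participants Number of simulated participants (threshold runs).
#' @param trials_per_staircase Trials per staircase (default 65).
#' @param profile An [effect_profile()] or a plain list of its fields.
#' @param geometry A [display_geometry()] or a plain list of its fields.
#' @param n_trials Adaptation trials per condition (adaptation runs).
#' @param duration Trial duration in seconds (adaptation runs, default 1).
#' @param sampler List of MCMC settings: `chains`, `iter`, `warmup`.
#' @param seed Master seed.
#' @param out Output directory for the report bundle.
#' @return An object of class `cfs_run_config`.
#' @export
run_config <- function(experiment = c("exp1", "exp2", "adaptation"),
                       n_participants = 20, trials_per_staircase = 65,
                       profile = effect_profile(),
                       geometry = display_geometry(),
                       n_trials = 99, duration = 1,
                       sampler = list(chains = 2, iter = 1500, warmup = 750),
                       seed = 1L, out = tempfile("cfsim_run_")) {
  experiment <- match.arg(experiment)
  if (inherits(profile, "cfs_effect_profile")) profile <- unclass(profile)
  if (inherits(geometry, "cfs_geometry")) {
    geometry <- unclass(geometry)
    geometry$side_px <- NULL # derived
  }
  structure(
    list(experiment = experiment, n_participants = as.integer(n_participants),
         trials_per_staircase = as.integer(trials_per_staircase),
         profile = profile, geometry = geometry,
         n_trials = as.integer(n_trials), duration = duration,
         sampler = sampler, seed = as.integer(seed), out = out),
    class = "cfs_run_config")
}

#' Write / read a run configuration
#'
#' Configurations round-trip losslessly through their JSON representation
#' (all defaults are printed into the emitted copy for auditability).
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the configuration.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "cfs_run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

log_stage <- function(log, stage, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf(...), collapse = ""))
  c(log, line)
}

#' Run a full simulated threshold experiment
#'
#' Orchestrates the end-to-end pipeline for a simulated study: builds the
#' observer bank from the effect profile, plans interleaved (and, for the
#' two-factor design, blocked and counterbalanced) staircase sessions,
#' simulates every trial, estimates and normalizes contrast thresholds, fits
#' the matching hierarchical robust-t model, computes the matched-vs-rest
#' contrast, a posterior predictive check and the default-prior Bayes
#' factors, and writes a CSV/JSON report bundle including all seeds.
#'
#' @param config A [run_config()] with `experiment` `"exp1"` or `"exp2"`.
#' @return Invisibly, a list with the trial table, threshold table, fitted
#'   posterior, contrast, PPC summary, Bayes factors and output paths.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "cfs_run_config"))
  if (!config$experiment %in% c("exp1", "exp2")) {
    stop_invalid("run_experiment needs experiment 'exp1' or 'exp2'")
  }
  profile <- do.call(effect_profile, config$profile)
  exp2 <- config$experiment == "exp2"
  target_speeds <- if (exp2) c(2, 5) else NA
  n <- config$n_participants
  seeds <- derive_seeds(config$seed, 4L + 3L * n)
  log <- log_stage(character(0), "start", "%s seed %d", config$experiment,
                   config$seed)

  bank <- generate_observer_bank(profile, standard_mask_speeds(), n,
                                 seed = seeds[1],
                                 target_speeds = target_speeds)
  log <- log_stage(log, "observers", "%d simulated observers", n)

  conds <- names(standard_mask_speeds())
  all_trials <- list()
  thr_rows <- list()
  for (p in seq_len(n)) {
    # counterbalance target-speed block order across participants
    ts_p <- if (exp2 && p %% 2 == 0) rev(target_speeds) else target_speeds
    plan <- plan_session(conds, config$trials_per_staircase,
                         seed = seeds[4 + 3 * (p - 1) + 1],
                         target_speeds = ts_p)
    sess <- simulate_session(plan, bank[[p]],
                             seed = seeds[4 + 3 * (p - 1) + 2])
    tt <- sess$trials
    tt$participant <- sprintf("P%02d", p)
    all_trials[[p]] <- tt
    th <- session_thresholds(sess, plan)
    th$participant <- sprintf("P%02d", p)
    th$normalized <- normalize_thresholds(th$threshold)
    thr_rows[[p]] <- th
  }
  trials <- do.call(rbind, all_trials)
  thresholds <- do.call(rbind, thr_rows)
  log <- log_stage(log, "staircases", "%d trials simulated", nrow(trials))

  if (!exp2) thresholds$target_speed <- NULL
  data <- rm_dataset(thresholds)
  fit <- if (exp2) {
    fit_two_way(data, chains = config$sampler$chains,
                iter = config$sampler$iter, warmup = config$sampler$warmup,
                seed = seeds[2], on_nonconvergence = "warn")
  } else {
    fit_one_way(data, chains = config$sampler$chains,
                iter = config$sampler$iter, warmup = config$sampler$warmup,
                seed = seeds[2], on_nonconvergence = "warn")
  }
  log <- log_stage(log, "fit", "max R-hat %.3f", max(fit$rhat, na.rm = TRUE))

  matched <- if (exp2) "MMM 2" else sprintf("MMM %g", profile$tuning_center)
  w <- setNames(rep(-1 / (length(conds) - 1), length(conds)), conds)
  w[matched] <- 1
  contrast <- contrast_hdi(fit, w, target_level = if (exp2) "2")
  ppc <- posterior_predictive(fit, data, seed = seeds[3])

  bf_models <- if (exp2) {
    c("null", "mask_speed", "target_speed", "additive")
  } else c("null")
  ref <- if (exp2) "full" else "mask_speed"
  bfs <- data.frame(
    model = bf_models, reference = ref,
    bf = vapply(bf_models, function(m) jzs_anova_bf(data, m, ref)$bf, 0))
  log <- log_stage(log, "inference", "BF table with %d rows", nrow(bfs))

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    trials = file.path(config$out, "trials.csv"),
    thresholds = file.path(config$out, "thresholds.csv"),
    bf = file.path(config$out, "bayes_factors.csv"),
    report = file.path(config$out, "report.json"),
    config = file.path(config$out, "config.json"),
    log = file.path(config$out, "run.log"))
  write.csv(trials, paths["trials"], row.names = FALSE)
  write.csv(thresholds, paths["thresholds"], row.names = FALSE)
  write.csv(bfs, paths["bf"], row.names = FALSE)
  report <- list(
    experiment = config$experiment, seed = config$seed,
    stage_seeds = seeds[1:4],
    max_rhat = max(fit$rhat, na.rm = TRUE),
    condition_means = as.list(tapply(data$value, data$condition, mean)),
    matched_contrast = list(mean = contrast$mean, hdi = contrast$hdi,
                            excludes_zero = contrast$excludes_zero),
    ppc_coverage = ppc$coverage,
    bayes_factors = setNames(as.list(bfs$bf), bfs$model))
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE, digits = NA)
  write_run_config(run_config(experiment = config$experiment,
                              n_participants = config$n_participants,
                              trials_per_staircase = config$trials_per_staircase,
                              profile = profile, sampler = config$sampler,
                              n_trials = config$n_trials,
                              duration = config$duration,
                              seed = config$seed, out = config$out),
                   paths["config"])
  writeLines(log, paths["log"])
  invisible(list(trials = trials, thresholds = thresholds, data = data,
                 fit = fit, contrast = contrast, ppc = ppc, bfs = bfs,
                 report = report, paths = paths))
}

#' Run the adaptation simulation over all mask conditions
#'
#' Simulates every standard mask condition at the configured resolution and
#' trial count, writes per-trial summaries, the condition ranking and the
#' monotonicity verdict (does simulated adaptation decrease from the slowest
#' mask speed up through regular CFS?).
#'
#' @param config A [run_config()] with `experiment = "adaptation"`.
#' @return Invisibly, a list with the summary table, ranking, verdict and
#'   output paths.
#' @export
run_adaptation <- function(config) {
  stopifnot(inherits(config, "cfs_run_config"))
  geometry <- do.call(display_geometry, config$geometry)
  conds <- standard_mask_conditions()
  seeds <- derive_seeds(config$seed, length(conds))
  bank <- build_gabor_bank(geometry$side_px)
  log <- log_stage(character(0), "start", "adaptation seed %d side %d px",
                   config$seed, geometry$side_px)
  summaries <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    summaries[[i]] <- simulate_condition(conds[[i]], geometry,
                                         n_trials = config$n_trials,
                                         duration = config$duration,
                                         seed = seeds[i], bank = bank)
    log <- log_stage(log, "condition", "%s mean %.4f (seed %d)",
                     conds[[i]]$label, summaries[[i]]$mean, seeds[i])
  }
  ranking <- rank_conditions(summaries)
  expected <- c("MMM 1", "MMM 2", "MMM 3", "MMM 5", "MMM 8", "CFS")
  means <- setNames(vapply(summaries, `[[`, 0, "mean"),
                    vapply(summaries, `[[`, "", "condition"))[expected]
  monotone <- all(diff(means) > 0)

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  per_trial <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, trial = seq_len(s$n_trials),
               summary = s$per_trial)
  }))
  paths <- c(trials = file.path(config$out, "adaptation_trials.csv"),
             report = file.path(config$out, "adaptation_report.json"),
             config = file.path(config$out, "config.json"),
             log = file.path(config$out, "run.log"))
  write.csv(per_trial, paths["trials"], row.names = FALSE)
  report <- list(seed = config$seed, side_px = geometry$side_px,
                 n_trials = config$n_trials, duration = config$duration,
                 means = as.list(means), ranking = ranking$condition,
                 monotone_speed_then_cfs = monotone)
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE, digits = NA)
  write_run_config(config, paths["config"])
  writeLines(log, paths["log"])
  invisible(list(summaries = summaries, ranking = ranking, means = means,
                 monotone = monotone, report = report, paths = paths))
}
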