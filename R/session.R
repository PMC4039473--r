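#' Plan a staircase session
#'
#' Builds the trial schedule for one participant: two staircases per
#' condition with distinct starting contrasts, randomly interleaved within
#' each block, with target motion paths balanced within every staircase.
#' When `target_speeds` has more than one entry, target speed is blocked
#' (one block per speed, in the order given) and the condition set is crossed
#' with it, as in a two-factor design.
#'
#' @param conditions Character vector of mask condition labels.
#' @param n_per_staircase Trials per staircase (default 65; must be >= 21 so
#'   the last-20-trials threshold is computable).
#' @param seed Integer seed for the interleave and path assignment.
#' @param start_levels Two distinct starting contrasts (linear), default
#'   `c(1, 0.1)` (near-maximum and mid-range).
#' @param target_speeds Target speeds defining the blocks; `NA` (default)
#'   plans a single unblocked session.
#' @return An object of class `cfs_session_plan` with elements `trials`
#'   (data frame: `trial`, `block`, `staircase_id`, `condition`,
#'   `target_speed`, `path`) and `staircases` (data frame: `staircase_id`,
#'   `condition`, `target_speed`, `start_level`).
#' @export
#' @examples
#' plan <- plan_session(names(standard_mask_conditions()), seed = 1)
#' nrow(plan$trials) # 780
plan_session <- function(conditions, n_per_staircase = 65L, seed = 1L,
                         start_levels = c(1, 0.1), target_speeds = NA) {
  if (length(conditions) < 1L) stop_invalid("need at least one condition")
  if (n_per_staircase < 21L) {
    stop_invalid("n_per_staircase must be at least 21 (last-20 estimator)")
  }
  if (length(start_levels) != 2L || start_levels[1] == start_levels[2]) {
    stop_invalid("start_levels must be two distinct values")
  }
  with_seed(seed, {
    sc_list <- list()
    trial_list <- list()
    sc_id <- 0L
    for (b in seq_along(target_speeds)) {
      ts <- target_speeds[b]
      block_ids <- integer(0)
      for (cond in conditions) {
        for (s in 1:2) {
          sc_id <- sc_id + 1L
          sc_list[[sc_id]] <- data.frame(
            staircase_id = sc_id, condition = cond, target_speed = ts,
            start_level = start_levels[s])
          block_ids <- c(block_ids, sc_id)
        }
      }
      order_ids <- sample(rep(block_ids, each = n_per_staircase))
      paths <- lapply(block_ids, function(id) sample(
        rep(1:6, length.out = n_per_staircase)))
      names(paths) <- as.character(block_ids)
      taken <- setNames(integer(length(block_ids)), as.character(block_ids))
      path_seq <- integer(length(order_ids))
      for (i in seq_along(order_ids)) {
        key <- as.character(order_ids[i])
        taken[key] <- taken[key] + 1L
        path_seq[i] <- paths[[key]][taken[key]]
      }
      cond_of <- setNames(rep(conditions, each = 2L), as.character(block_ids))
      trial_list[[b]] <- data.frame(
        block = b, staircase_id = order_ids,
        condition = cond_of[as.character(order_ids)],
        target_speed = ts, path = path_seq)
    }
    trials <- do.call(rbind, trial_list)
    trials$trial <- seq_len(nrow(trials))
    rownames(trials) <- NULL
    structure(
      list(trials = trials[, c("trial", "block", "staircase_id", "condition",
                               "target_speed", "path")],
           staircases = do.call(rbind, sc_list),
           n_per_staircase = as.integer(n_per_staircase), seed = seed),
      class = "cfs_session_plan")
  })
}

#' @export
print.cfs_session_plan <- function(x, ...) {
  cat(sprintf("<cfs_session_plan> %d trials, %d staircases, %d block(s)\n",
              nrow(x$trials), nrow(x$staircases), max(x$trials$block)))
  invisible(x)
}

#' Condition key used to look up observer thresholds
#'
#' @param condition Mask condition label.
#' @param target_speed Target speed or `NA`.
#' @return Character key, e.g. `"MMM 3"` or `"MMM 3@2"`.
#' @export
condition_key <- function(condition, target_speed = NA) {
  ts <- rep_len(target_speed, length(condition))
  ifelse(is.na(ts), as.character(condition), paste0(condition, "@", ts))
}

#' Simulate a session against an observer
#'
#' Runs every planned trial: the response is a Bernoulli draw with success
#' probability given by the observer's psychometric function at the
#' staircase's current contrast, and the staircase is updated accordingly.
#'
#' @param plan A [plan_session()] plan.
#' @param observer A [observer_model()] whose `alpha` covers every condition
#'   key appearing in the plan.
#' @param seed Integer seed.
#' @return A list with `trials` (the plan's trial table plus `level` in
#'   linear contrast and `correct`) and `staircases` (list of final
#'   [staircase()] states, indexed by staircase id).
#' @export
simulate_session <- function(plan, observer, seed = 1L) {
  stopifnot(inherits(plan, "cfs_session_plan"), inherits(observer, "cfs_observer"))
  keys <- condition_key(plan$staircases$condition, plan$staircases$target_speed)
  missing <- setdiff(unique(keys), names(observer$alpha))
  if (length(missing)) {
    stop_invalid("observer lacks thresholds for condition(s): ",
                 paste(missing, collapse = ", "))
  }
  states <- lapply(seq_len(nrow(plan$staircases)), function(i) {
    staircase(plan$staircases$start_level[i],
              condition = keys[i])
  })
  n <- nrow(plan$trials)
  level <- numeric(n)
  correct <- logical(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      id <- plan$trials$staircase_id[i]
      st <- states[[id]]
      c_lin <- 10^st$level
      p <- p_correct(observer, st$condition, c_lin)
      ok <- runif(1) < p
      states[[id]] <- staircase_update(st, ok)
      level[i] <- c_lin
      correct[i] <- ok
    }
  })
  trials <- plan$trials
  trials$level <- level
  trials$correct <- correct
  list(trials = trials, staircases = states)
}

#' Per-condition thresholds from a simulated session
#'
#' Estimates each staircase's threshold as the mean of its last 20 trials
#' and averages the two staircases of every condition.
#'
#' @param session Result of [simulate_session()].
#' @param plan The plan the session was run from.
#' @param space Averaging space passed to [estimate_threshold()].
#' @return Data frame with `condition`, `target_speed`, `threshold`.
#' @export
session_thresholds <- function(session, plan, space = "linear") {
  sc <- plan$staircases
  sc$threshold <- vapply(session$staircases, estimate_threshold, 0,
                         space = space)
  key <- paste(sc$condition, sc$target_speed, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(condition = sc$condition[first],
                    target_speed = sc$target_speed[first],
                    threshold = as.numeric(
                      tapply(sc$threshold, key, mean)[key[first]]))
  rownames(out) <- NULL
  out
}

#' Normalize thresholds within a participant
#'
#' Divides each threshold by the participant's mean threshold, so that the
#' mean of the normalized values is exactly 1. This removes large
#' between-participant differences in absolute contrast sensitivity before
#' group analysis.
#'
#' @param per_condition Positive numeric vector of one participant's
#'   per-condition thresholds.
#' @return Normalized vector with mean 1.
#' @export
normalize_thresholds <- function(per_condition) {
  if (any(!is.finite(per_condition)) || any(per_condition <= 0)) {
    stop_invalid("thresholds must be positive and finite")
  }
  per_condition / mean(per_condition)
}

#' Within-subject confidence intervals for repeated measures
#'
#' Cousineau-centered data (subtract each participant's mean, add the grand
#' mean) with Morey's bias correction `sqrt(C / (C - 1))`, then an ordinary
#' t-based interval per condition at the stated probability.
#'
#' @param data Participants x conditions numeric matrix, no missing cells.
#' @param prob Interval probability (default 0.95).
#' @return Data frame with `condition`, `mean`, `lo`, `hi`.
#' @export
within_subject_ci <- function(data, prob = 0.95) {
  data <- as.matrix(data)
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stop_invalid("need at least 2 participants and 2 conditions")
  }
  if (any(!is.finite(data))) stop_invalid("missing cells are not allowed")
  n <- nrow(data)
  C <- ncol(data)
  centered <- data - rowMeans(data) + mean(data)
  morey <- sqrt(C / (C - 1))
  se <- apply(centered, 2, sd) * morey / sqrt(n)
  m <- colMeans(data)
  tcrit <- qt((1 + prob) / 2, df = n - 1)
  data.frame(condition = colnames(data) %||% as.character(seq_len(C)),
             mean = m, lo = m - tcrit * se, hi = m + tcrit * se,
             row.names = NULL)
}
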