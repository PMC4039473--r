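#' Create an adaptation field
#'
#' Per-pixel, per-category activation state for the retinotopic adaptation
#' dynamics. Each pixel carries four activation values in `[0, 1]`, one per
#' response category (two orientations times two contrast polarities), all
#' starting at 1 (fully responsive). While a category is stimulated by a
#' *persisting* feature its activation decays exponentially with time
#' constant `tau_decay`; otherwise it recovers toward 1 with time constant
#' `tau_recover`.
#'
#' Adaptation requires the same orientation and contrast polarity across
#' successive stimulus updates: a label that just appeared (or just changed)
#' at a pixel does not yet drive decay. A fresh field therefore treats its
#' first update as stimulus onset. To model a stimulus that is already
#' established on screen (e.g. for the closed-form decay checks), pass the
#' current response map as `initial_labels`.
#'
#' @param side Frame side in pixels (field is `side` x `side` x 4).
#' @param tau_decay Decay time constant (s), default 4.
#' @param tau_recover Recovery time constant (s), default 6.
#' @param dt Interval between stimulus updates (s), default 1/60.
#' @param initial_labels Optional integer label matrix describing the
#'   stimulus assumed present before the first update.
#' @return An object of class `cfs_adaptation_field`.
#' @export
adaptation_field <- function(side, tau_decay = 4, tau_recover = 6, dt = 1 / 60,
                             initial_labels = NULL) {
  if (tau_decay <= 0 || tau_recover <= 0 || dt <= 0) {
    stop_invalid("time constants and dt must be positive")
  }
  structure(
    list(activation = array(1, dim = c(side, side, 4)),
         tau_decay = tau_decay, tau_recover = tau_recover, dt = dt,
         prev_labels = initial_labels),
    class = "cfs_adaptation_field")
}

# Effective (persistence-gated) labels: a label drives decay only where it
# equals the previous update's label; everywhere else the map counts as
# "no input" for this step.
effective_labels <- function(responses, prev) {
  if (is.null(prev)) {
    return(matrix(0L, nrow(responses), ncol(responses)))
  }
  eff <- responses
  eff[eff != prev] <- 0L
  eff
}

#' Advance the adaptation field by one stimulus update
#'
#' For every pixel and response category: if the pixel's current label equals
#' the category and equals the label of the previous update (the feature
#' persisted), activation is multiplied by `exp(-dt / tau_decay)`; otherwise
#' it relaxes toward 1 as `1 - (1 - activation) * exp(-dt / tau_recover)`.
#' These discrete multiplicative updates telescope to the continuous
#' exponential solutions, so constant stimulation for time T leaves
#' activation `exp(-T / tau_decay)` exactly, and unstimulated recovery from
#' level a0 reaches `1 - (1 - a0) * exp(-T / tau_recover)` exactly.
#'
#' @param field A [adaptation_field()].
#' @param responses Integer label matrix from [classify_responses()].
#' @return The updated field (its persistence state advances to `responses`);
#'   the summed activation of the new state is available as `attr(, "total")`.
#' @export
update_adaptation <- function(field, responses) {
  stopifnot(inherits(field, "cfs_adaptation_field"))
  d <- dim(field$activation)
  if (nrow(responses) != d[1] || ncol(responses) != d[2]) {
    stop_invalid("response map dimensions do not match the field")
  }
  fd <- exp(-field$dt / field$tau_decay)
  fr <- exp(-field$dt / field$tau_recover)
  eff <- effective_labels(responses, field$prev_labels)
  res <- cpp_adapt_update(field$activation, eff, fd, fr)
  field$activation <- res$activation
  field$prev_labels <- responses
  attr(field, "total") <- res$total
  field
}

#' Summarize adaptation over a trial
#'
#' Aggregates per-frame total activation into one scalar per trial,
#' normalized by `n_pixels * 4` so that a trial with no stimulation anywhere
#' scores exactly 1 and every trial scores in `(0, 1]`. Higher values mean
#' less adaptation.
#'
#' Three aggregation variants are provided (the trial-level scalar in the
#' underlying procedure is stated only as a sum over locations):
#' `"time_mean"` (default) averages the per-frame normalized sums over the
#' trial, `"final"` takes the last frame only, and `"per_frame"` returns the
#' whole trajectory.
#'
#' @param totals Numeric vector of per-frame activation sums (as accumulated
#'   by [simulate_condition()] or from `attr(update_adaptation(...), "total")`).
#' @param n_pixels Number of pixels per frame.
#' @param variant One of `"time_mean"`, `"final"`, `"per_frame"`.
#' @return A scalar (or vector for `"per_frame"`).
#' @export
summarize_trial <- function(totals, n_pixels,
                            variant = c("time_mean", "final", "per_frame")) {
  variant <- match.arg(variant)
  if (length(totals) == 0L) stop_invalid("empty trial: no frames to summarize")
  norm <- totals / (n_pixels * 4)
  switch(variant,
         time_mean = mean(norm),
         final = norm[length(norm)],
         per_frame = norm)
}

#' Define a mask condition
#'
#' @param type `"mmm"` (moving Mondrian mask) or `"cfs"` (classic flashing CFS).
#' @param speed Element speed in deg/s (MMM only).
#' @param refresh_rate Refresh rate in Hz (CFS only, default 10).
#' @param label Condition label; defaults to `"MMM <speed>"` or `"CFS"`.
#' @return A list describing the condition.
#' @export
mask_condition <- function(type = c("mmm", "cfs"), speed = NULL,
                           refresh_rate = 10, label = NULL) {
  type <- match.arg(type)
  if (type == "mmm") {
    if (is.null(speed) || speed <= 0) {
      stop_invalid("an MMM condition needs a positive speed")
    }
    if (is.null(label)) label <- sprintf("MMM %g", speed)
  } else {
    if (is.null(label)) label <- "CFS"
  }
  list(type = type, speed = speed, refresh_rate = refresh_rate, label = label)
}

#' The six mask conditions of the speed-tuning design
#'
#' Moving Mondrian masks at 1, 2, 3, 5 and 8 deg/s plus the classic 10 Hz CFS
#' mask.
#'
#' @return A named list of [mask_condition()] objects.
#' @export
standard_mask_conditions <- function() {
  speeds <- c(1, 2, 3, 5, 8)
  conds <- c(lapply(speeds, function(s) mask_condition("mmm", speed = s)),
             list(mask_condition("cfs")))
  names(conds) <- vapply(conds, `[[`, "", "label")
  conds
}

#' Simulate retinotopic adaptation for one mask condition
#'
#' Generates `n_trials` independently seeded stimulus sequences for the
#' condition, converts each stimulus update to grayscale, classifies
#' per-pixel filter responses, runs the decay/recovery dynamics, and records
#' one summary scalar per trial. Activation is reset to 1 at the start of
#' every trial (trials are independent) and each trial starts at stimulus
#' onset (no persistence carried in).
#'
#' The simulation steps once per *distinct stimulus update*: a moving
#' Mondrian mask updates every display frame (dt = 1/frame_rate), while the
#' flashing CFS mask updates at its refresh rate (dt = 1/refresh_rate) — a
#' 100 ms hold of an unchanged layout is a single presentation, not repeated
#' evidence of a persisting feature.
#'
#' @param condition A [mask_condition()].
#' @param geometry A [display_geometry()].
#' @param n_trials Number of simulated trials (default 999).
#' @param duration Trial length in seconds (default 3.6).
#' @param seed Master seed; per-trial seeds are derived from it.
#' @param bank Optional [build_gabor_bank()]; built for the geometry if NULL.
#' @param variant Summary aggregation, see [summarize_trial()].
#' @param tau_decay,tau_recover Adaptation time constants (s).
#' @return An object of class `cfs_adaptation_summary` with fields
#'   `condition`, `per_trial`, `mean`, `n_trials`.
#' @export
simulate_condition <- function(condition, geometry, n_trials = 999,
                               duration = 3.6, seed = 1L, bank = NULL,
                               variant = c("time_mean", "final"),
                               tau_decay = 4, tau_recover = 6) {
  variant <- match.arg(variant)
  stopifnot(inherits(geometry, "cfs_geometry"))
  if (n_trials < 1) stop_invalid("n_trials must be at least 1")
  if (!is.list(condition) || is.null(condition$type) ||
      !condition$type %in% c("mmm", "cfs")) {
    stop_invalid("unknown condition; use mask_condition()")
  }
  if (is.null(bank)) bank <- build_gabor_bank(geometry$side_px)
  side <- geometry$side_px
  rate <- if (condition$type == "mmm") {
    geometry$frame_rate
  } else {
    condition$refresh_rate %||% 10
  }
  n_updates <- as.integer(round(duration * rate))
  dt <- 1 / rate
  fd <- exp(-dt / tau_decay)
  fr <- exp(-dt / tau_recover)
  trial_seeds <- derive_seeds(seed, n_trials)

  per_trial <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    totals <- numeric(n_updates)
    act <- array(1, dim = c(side, side, 4))
    prev <- NULL
    if (condition$type == "mmm") {
      el <- init_mmm_elements(geometry, condition$speed, trial_seeds[tr])
    } else {
      layout_seeds <- derive_seeds(trial_seeds[tr], n_updates)
    }
    for (f in seq_len(n_updates)) {
      if (condition$type == "mmm") {
        gray <- render_mask_gray(el, geometry)
        if (f < n_updates) el <- step_mmm(el, dt, geometry)
      } else {
        gray <- render_mask_gray(mmm_layout(geometry, layout_seeds[f]),
                                 geometry)
      }
      lab <- cpp_gabor_classify(gray, bank$k0, bank$k90, bank$epsilon)
      res <- cpp_adapt_update(act, effective_labels(lab, prev), fd, fr)
      act <- res$activation
      prev <- lab
      totals[f] <- res$total
    }
    per_trial[tr] <- summarize_trial(totals, side * side, variant)
  }
  structure(
    list(condition = condition$label, per_trial = per_trial,
         mean = mean(per_trial), n_trials = as.integer(n_trials),
         meta = list(duration = duration, seed = seed, side = side,
                     variant = variant)),
    class = "cfs_adaptation_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cfs_adaptation_summary <- function(x, ...) {
  cat(sprintf("<cfs_adaptation_summary> %s: mean %.4f (sd %.4f, %d trials)\n",
              x$condition, x$mean, sd(x$per_trial), x$n_trials))
  invisible(x)
}

#' Rank mask conditions by simulated adaptation
#'
#' Conditions are sorted ascending by mean summary value (most adapted
#' first); since high summary values indicate less adaptation, the last rank
#' is the condition least prone to retinotopic adaptation. Ties are broken
#' by label order, so the ranking is invariant to the input order.
#'
#' @param summaries List of `cfs_adaptation_summary` objects (>= 2).
#' @return A data frame with columns `condition`, `mean`, `sd`, `rank`.
#' @export
rank_conditions <- function(summaries) {
  if (length(summaries) < 2L) stop_invalid("need at least two summaries")
  df <- data.frame(
    condition = vapply(summaries, `[[`, "", "condition"),
    mean = vapply(summaries, `[[`, 0, "mean"),
    sd = vapply(summaries, function(s) sd(s$per_trial), 0))
  df <- df[order(df$mean, df$condition), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
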