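#' Create an adaptive staircase
#'
#' An accelerated transformed up-down staircase for contrast thresholds.
#' Levels are tracked in log10 contrast with a fixed step. The staircase
#' starts in an accelerated one-up-one-down phase (every correct response
#' lowers the level) and switches permanently to the main one-up-two-down
#' phase at the first incorrect response; the main phase converges on the
#' 70.71% correct point. Levels are clamped to `[level_min, level_max]`.
#'
#' @param start_level Starting contrast (linear units, in `(0, 1]`).
#' @param step Step size in log10 contrast units (default 0.05).
#' @param level_min,level_max Contrast bounds (linear), default `[1e-4, 1]`.
#' @param condition Optional condition label carried along.
#' @return An object of class `cfs_staircase`.
#' @export
staircase <- function(start_level, step = 0.05, level_min = 1e-4,
                      level_max = 1, condition = NA_character_) {
  if (start_level <= 0 || start_level > level_max || start_level < level_min) {
    stop_invalid("start_level must lie within [level_min, level_max]")
  }
  structure(
    list(level = log10(start_level), step = step,
         lo = log10(level_min), hi = log10(level_max),
         phase = "accelerated", n_correct = 0L,
         history_level = numeric(0), history_correct = logical(0),
         reversals = numeric(0), last_move = 0,
         condition = condition),
    class = "cfs_staircase")
}

#' Update a staircase with one response
#'
#' Records the trial at the current level, then moves the level. In the
#' accelerated phase a correct response lowers the level by one step and the
#' first incorrect response raises it and switches to the main phase. In the
#' main phase an incorrect response raises the level (and resets the correct
#' counter) while the second of two consecutive correct responses lowers it.
#' A reversal level (the level at which the trial was run) is recorded
#' whenever the direction of movement flips; reversal levels carry a
#' `"phase"` attribute so main-phase reversals can be selected.
#'
#' @param state A [staircase()].
#' @param correct Logical, whether the response was correct.
#' @return The updated staircase.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "cfs_staircase"))
  lvl <- state$level
  state$history_level <- c(state$history_level, lvl)
  state$history_correct <- c(state$history_correct, correct)

  move <- 0
  if (state$phase == "accelerated") {
    if (correct) {
      move <- -state$step
    } else {
      move <- +state$step
      state$phase <- "main"
      state$n_correct <- 0L
    }
  } else {
    if (correct) {
      state$n_correct <- state$n_correct + 1L
      if (state$n_correct >= 2L) {
        move <- -state$step
        state$n_correct <- 0L
      }
    } else {
      move <- +state$step
      state$n_correct <- 0L
    }
  }
  if (move != 0) {
    if (state$last_move != 0 && sign(move) != sign(state$last_move)) {
      phases <- attr(state$reversals, "phase")
      state$reversals <- c(state$reversals, lvl)
      attr(state$reversals, "phase") <- c(phases, state$phase)
    }
    state$last_move <- move
    state$level <- min(max(lvl + move, state$lo), state$hi)
  }
  state
}

#' Main-phase reversal levels of a staircase
#'
#' @param state A staircase after some trials.
#' @return Numeric vector of log10-contrast reversal levels recorded in the
#'   main (one-up-two-down) phase.
#' @export
main_reversals <- function(state) {
  ph <- attr(state$reversals, "phase")
  as.numeric(state$reversals[ph == "main"])
}

#' Estimate a threshold from a staircase
#'
#' The threshold is the arithmetic mean of the levels of the final 20 trials.
#' By default levels are exponentiated to linear contrast before averaging;
#' set `space = "log"` to average in log10 units (and return 10^mean).
#'
#' @param state A staircase with at least 20 recorded trials.
#' @param n_last Number of final trials to average (default 20).
#' @param space `"linear"` (default) or `"log"` averaging.
#' @return Threshold in linear contrast units.
#' @export
estimate_threshold <- function(state, n_last = 20L, space = c("linear", "log")) {
  space <- match.arg(space)
  h <- state$history_level
  if (length(h) < n_last) {
    stop_invalid("insufficient data: need at least ", n_last, " trials, have ",
                 length(h))
  }
  last <- h[(length(h) - n_last + 1L):length(h)]
  if (space == "linear") mean(10^last) else 10^mean(last)
}
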