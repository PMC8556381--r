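#' Compose a stimulus frame sequence from signal and noise
#'
#' Builds the displayed frames for one trial. Each frame is the linear
#' blend `w_k * signal + (1 - w_k) * noise`, where `w_k` is the sampling
#' function's SNR value for frame `k` (peaking at 0.5, so the noise
#' component is never outweighed), `signal` is the target image overlaid
#' with a white-noise mask whose contrast is set by the staircase's noise
#' level (level 1 is a zero-contrast, i.e. null, mask; level `n_levels` is
#' full black/white contrast), and `noise` is an independent maximal-contrast
#' white-noise field. Two fresh noise fields are drawn per trial. After
#' blending, every frame is equalized to the first frame's mean luminance
#' and RMS contrast, then clipped to \[0, 1\].
#'
#' @param target Numeric matrix, grayscale intensities in \[0, 1\].
#' @param noise_level Integer white-noise contrast level in `1:n_levels`.
#' @param sf A `sampling_function` (its `values` supply the per-frame
#'   weights `w_k`).
#' @param n_levels Number of available noise contrast levels (default 128).
#' @return Object of class `frame_sequence`: list with `frames` (list of
#'   matrices in \[0, 1\]), `sf`, `noise_level`, and the equalization
#'   targets `mean_ref` and `rms_ref`.
#' @export
compose_frames <- function(target, noise_level, sf, n_levels = 128) {
  stopifnot(is.matrix(target), is.numeric(target))
  if (any(target < 0 | target > 1)) stop("target intensities must lie in [0, 1]")
  noise_level <- as.integer(noise_level)
  if (noise_level < 1L || noise_level > n_levels)
    stop("noise_level must be in 1..", n_levels)
  w <- if (inherits(sf, "sampling_function")) sf$values else as.numeric(sf)

  # signal component: target overlaid by a mask of contrast c in [0, 1];
  # level 1 -> c = 0 (null mask), level n_levels -> c = 1 (full contrast)
  cmask <- (noise_level - 1) / (n_levels - 1)
  mask <- matrix(stats::runif(length(target)), nrow(target))
  signal <- (1 - cmask) * target + cmask * mask
  # noise component: independent maximal-contrast white-noise field
  noise <- matrix(stats::runif(length(target)), nrow(target))

  blends <- lapply(w, function(wk) wk * signal + (1 - wk) * noise)
  mean_ref <- mean(blends[[1L]])
  rms_ref <- stats::sd(as.vector(blends[[1L]]))
  # center and rescale every frame to the first frame's RMS contrast ...
  devs <- lapply(blends, function(fr) {
    fr <- fr - mean(fr)
    s <- stats::sd(as.vector(fr))
    if (s > 0 && rms_ref > 0) fr * (rms_ref / s) else fr
  })
  # ... then back off contrast uniformly (same factor for all frames, so
  # the cross-frame matching is exact) if any pixel would leave [0, 1]
  hi <- max(vapply(devs, max, 0))
  lo <- min(vapply(devs, min, 0))
  alpha <- min(1,
               if (hi > 0) (1 - mean_ref) / hi else 1,
               if (lo < 0) mean_ref / (-lo) else 1)
  frames <- lapply(devs, function(d) mean_ref + alpha * d)
  rms_ref <- alpha * rms_ref
  structure(list(frames = frames, sf = sf, noise_level = noise_level,
                 mean_ref = mean_ref, rms_ref = rms_ref),
            class = "frame_sequence")
}

#' Initial adaptive staircase state
#'
#' The staircase adjusts the white-noise contrast of the signal component
#' to hold response accuracy near 50%. It starts at the middle of the
#' available range (level 64 of 128) with a step of 16 levels and runs
#' unchanged for the first 10 trials; from trial 11 the mean accuracy of
#' the 10 preceding trials drives the level down (accuracy below 0.5,
#' making the task easier), up (above 0.5), or leaves it unchanged (exactly
#' 0.5). The step halves on every reversal of adjustment direction, down to
#' a floor of 1, and the state persists across blocks.
#'
#' @param n_levels Number of noise contrast levels (default 128).
#' @param start Starting level (default the range midpoint, `n_levels / 2`).
#' @param step Initial step size in levels (default 16).
#' @return Object of class `staircase_state` with fields `level`, `step`,
#'   `last_direction` (`"up"`, `"down"` or `"none"`) and `n_levels`.
#' @export
staircase_state <- function(n_levels = 128, start = n_levels %/% 2, step = 16) {
  stopifnot(n_levels >= 2, start >= 1, start <= n_levels, step >= 1)
  structure(list(level = as.integer(start), step = as.integer(step),
                 last_direction = "none", n_levels = as.integer(n_levels)),
            class = "staircase_state")
}

#' Advance the staircase by one trial
#'
#' @param state A [staircase_state()].
#' @param trial_index 1-based index of the upcoming trial.
#' @param window Accuracies (0/1) of the 10 trials preceding `trial_index`;
#'   ignored for trials 1-10.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, trial_index, window) {
  stopifnot(inherits(state, "staircase_state"), trial_index >= 1)
  if (trial_index <= 10L) return(state)
  if (missing(window) || length(window) == 0L)
    stop("an accuracy window is required from trial 11 onwards")
  if (!all(window %in% c(0, 1))) stop("window accuracies must be 0 or 1")
  acc <- mean(window)
  if (acc == 0.5) return(state)
  dir <- if (acc < 0.5) "down" else "up"
  if (state$last_direction != "none" && dir != state$last_direction)
    state$step <- max(1L, state$step %/% 2L)
  delta <- if (dir == "down") -state$step else state$step
  state$level <- max(1L, min(state$n_levels, state$level + delta))
  state$last_direction <- dir
  state
}

#' Simulate a staircase-driven session
#'
#' Runs `n_trials` of the adaptive staircase against a psychometric
#' function giving the probability of a correct response at each noise
#' level. The default psychometric is logistic in the level, spanning the
#' 128 levels with 50% accuracy at the range midpoint, so accuracy
#' decreases as noise contrast rises.
#'
#' @param n_trials Number of trials.
#' @param psychometric Function mapping a level (1..n_levels) to
#'   P(correct).
#' @param state Initial [staircase_state()].
#' @return Data frame with one row per trial: `trial`, `level`, `step`,
#'   `direction` and `accuracy`.
#' @examples
#' set.seed(7)
#' log <- simulate_staircase(1200)
#' mean(log$accuracy[801:1200])  # near 0.5
#' @export
simulate_staircase <- function(n_trials,
                               psychometric = function(level)
                                 stats::plogis((64 - level) / 12),
                               state = staircase_state()) {
  stopifnot(n_trials >= 1)
  acc <- integer(n_trials)
  lev <- integer(n_trials)
  stp <- integer(n_trials)
  dirs <- character(n_trials)
  for (i in seq_len(n_trials)) {
    if (i > 10L)
      state <- staircase_update(state, i, acc[(i - 10L):(i - 1L)])
    lev[i] <- state$level
    stp[i] <- state$step
    dirs[i] <- state$last_direction
    acc[i] <- stats::rbinom(1L, 1L, psychometric(state$level))
  }
  data.frame(trial = seq_len(n_trials), level = lev, step = stp,
             direction = dirs, accuracy = acc)
}
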