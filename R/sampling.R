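#' Temporal sampling basis specification
#'
#' Defines the sinusoidal basis from which random temporal sampling
#' functions are built: a set of temporal frequencies, a stimulus duration
#' and a display refresh rate. The defaults describe a 200 ms stimulus on a
#' 120 Hz display sampled by sinusoids of 5 to 55 Hz in 5 Hz steps, giving
#' 24 display frames and 11 basis frequencies.
#'
#' @param frequencies Numeric vector of basis frequencies in Hz, strictly
#'   increasing and positive. All must lie below the Nyquist frequency
#'   (`refresh_rate / 2`).
#' @param duration Stimulus duration in seconds.
#' @param refresh_rate Display refresh rate in Hz.
#'
#' @return An object of class `basis_spec`: a list with elements
#'   `frequencies`, `duration`, `refresh_rate`, `n_frames` (number of display
#'   frames) and `times` (frame midpoint times in seconds). Each frame is
#'   represented by its midpoint `(k + 0.5) / refresh_rate`, the unbiased
#'   time point for an image displayed over a whole refresh interval.
#' @examples
#' spec <- basis_spec()
#' spec$n_frames  # 24
#' @export
basis_spec <- function(frequencies = seq(5, 55, by = 5),
                       duration = 0.200,
                       refresh_rate = 120) {
  stopifnot(is.numeric(frequencies), length(frequencies) >= 1L,
            all(is.finite(frequencies)), all(frequencies > 0),
            is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(refresh_rate), length(refresh_rate) == 1L,
            refresh_rate > 0)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("`frequencies` must be strictly increasing")
  if (any(frequencies >= refresh_rate / 2))
    stop("all basis frequencies must be below the Nyquist frequency (",
         refresh_rate / 2, " Hz)")
  n_frames <- as.integer(round(duration * refresh_rate))
  if (n_frames < 2L)
    stop("duration x refresh_rate must give at least 2 frames")
  structure(list(frequencies = as.numeric(frequencies),
                 duration = duration,
                 refresh_rate = refresh_rate,
                 n_frames = n_frames,
                 times = (seq_len(n_frames) - 0.5) / refresh_rate),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("Temporal sampling basis: ", length(x$frequencies), " frequencies (",
      min(x$frequencies), "-", max(x$frequencies), " Hz), ",
      x$n_frames, " frames over ", x$duration * 1000, " ms at ",
      x$refresh_rate, " Hz\n", sep = "")
  invisible(x)
}

# Basis design matrices so that a draw with amplitudes A and phases P has
# waveform rows (A*cos(P)) %*% Bs + (A*sin(P)) %*% Bc, i.e.
# sum_j a_j sin(2 pi f_j t + phi_j) evaluated at the frame midpoints.
basis_matrices <- function(spec) {
  ang <- outer(spec$frequencies, spec$times, function(f, t) 2 * pi * f * t)
  list(sin = sin(ang), cos = cos(ang))  # each n_freq x n_frames
}

# Evaluate the raw (pre-normalization) waveforms for amplitude and phase
# matrices (n_draws x n_freq). Returns n_draws x n_frames.
basis_waveform <- function(amplitudes, phases, spec, bm = basis_matrices(spec)) {
  (amplitudes * cos(phases)) %*% bm$sin + (amplitudes * sin(phases)) %*% bm$cos
}

#' Normalize a waveform's range to \[0, 0.5\]
#'
#' Affinely rescales a series so that its minimum is exactly 0 and its
#' maximum exactly 0.5, the signal-to-noise ratio range used for stimulus
#' composition. Idempotent: applying it twice equals applying it once.
#'
#' @param x Numeric vector (or matrix of row-wise series).
#' @return The rescaled vector or matrix.
#' @export
normalize_snr_range <- function(x) {
  if (is.matrix(x)) {
    lo <- apply(x, 1L, min)
    hi <- apply(x, 1L, max)
    rng <- hi - lo
    if (any(rng <= 0)) stop("degenerate (flat) series cannot be range-normalized")
    (x - lo) / rng * 0.5
  } else {
    rng <- max(x) - min(x)
    if (rng <= 0) stop("degenerate (flat) series cannot be range-normalized")
    (x - min(x)) / rng * 0.5
  }
}

# Generator behind make_sampling_function() and the observer simulator:
# draws candidate waveforms, range-normalizes, and keeps those whose frame
# sum falls within `sum_tol` of `sum_target` (rejection sampling; the
# unconstrained mean frame sum is n_frames x 0.25, hence the default
# target of 6 for 24 frames; about 4% of candidates are accepted under the
# defaults). The rejection loop is compiled (see src/) and consumes R's
# RNG, so draws are reproducible under set.seed().
sample_functions <- function(n, spec = basis_spec(),
                             sum_target = 0.25 * spec$n_frames,
                             sum_tol = 0.05,
                             max_draws = 10000 * n) {
  bm <- basis_matrices(spec)
  cpp_sample_functions(n, bm$sin, bm$cos, sum_target, sum_tol, max_draws)
}

#' Draw a random temporal sampling function
#'
#' Generates one trial's signal-to-noise sampling function: the sum of
#' sinusoids at the basis frequencies with amplitudes drawn i.i.d.
#' uniform(0, 1) and phases i.i.d. uniform(0, 2*pi), range-normalized to
#' \[0, 0.5\] and constrained by rejection sampling so that its sum across
#' frames matches `sum_target` within `sum_tol`. Degenerate (flat) draws are
#' redrawn. Uses the R session random number generator; call [set.seed()]
#' beforehand for reproducibility.
#'
#' @param spec A [basis_spec()].
#' @param sum_target Target frame sum (default `0.25 * n_frames`, i.e. 6 for
#'   the default 24-frame spec, the mean frame sum of unconstrained
#'   range-normalized draws).
#' @param sum_tol Tolerance on the frame sum.
#' @param max_draws Redraw budget; an error is signalled if exhausted.
#'
#' @return An object of class `sampling_function`: list with `values`
#'   (SNR per frame, in \[0, 0.5\]), `amplitudes` and `phases` (the basis
#'   parameters of the pre-normalization waveform) and `spec`.
#' @examples
#' set.seed(1)
#' sf <- make_sampling_function()
#' range(sf$values)     # exactly 0 and 0.5
#' sum(sf$values)       # within 0.05 of 6
#' @export
make_sampling_function <- function(spec = basis_spec(),
                                   sum_target = 0.25 * spec$n_frames,
                                   sum_tol = 0.05,
                                   max_draws = 10000) {
  d <- sample_functions(1L, spec, sum_target, sum_tol, max_draws)
  structure(list(values = drop(d$values),
                 amplitudes = drop(d$amplitudes),
                 phases = drop(d$phases),
                 spec = spec),
            class = "sampling_function")
}

#' Fourier descriptors of a sampling function
#'
#' Returns the amplitude and phase of each basis frequency. For a
#' `sampling_function` object the stored construction parameters are
#' returned exactly (phases wrapped to (-pi, pi\]). For a bare numeric
#' series the descriptors are recovered by the discrete Fourier transform
#' evaluated at the basis frequencies, using the sine convention of the
#' generator: a component `a * sin(2*pi*f*t + phi)` yields amplitude `a`
#' and phase `phi`. Every default basis frequency completes an integer
#' number of cycles over the stimulus window, so the recovery is exact for
#' waveforms in the span of the basis.
#'
#' @param sf A `sampling_function`, or a numeric series of length
#'   `spec$n_frames`.
#' @param spec A [basis_spec()]; ignored (taken from the object) when `sf`
#'   is a `sampling_function`.
#' @return A list of class `spectral_descriptor` with `frequencies`,
#'   `amplitude` (>= 0) and `phase` (radians in (-pi, pi\]).
#' @export
fourier_descriptors <- function(sf, spec = basis_spec()) {
  if (inherits(sf, "sampling_function")) {
    amp <- sf$amplitudes
    pha <- wrap_phase(sf$phases)
    neg <- amp < 0  # not produced by the generator, but normalize anyway
    amp[neg] <- -amp[neg]
    pha[neg] <- wrap_phase(pha[neg] + pi)
    return(structure(list(frequencies = sf$spec$frequencies,
                          amplitude = amp, phase = pha),
                     class = "spectral_descriptor"))
  }
  x <- as.numeric(sf)
  if (length(x) != spec$n_frames)
    stop("series length ", length(x), " does not match spec n_frames ",
         spec$n_frames)
  n <- spec$n_frames
  # projection of the series onto e^{-i 2 pi f t} at the frame midpoints;
  # for a sine component a*sin(w t + phi) this equals (a n / 2) e^{i(phi - pi/2)}
  co <- vapply(spec$frequencies, function(f) {
    sum(x * exp(-2i * pi * f * spec$times)) * 2 / n
  }, complex(1))
  amp <- Mod(co)
  pha <- wrap_phase(Arg(co) + pi / 2)
  pha[amp < 1e-12] <- 0
  structure(list(frequencies = spec$frequencies, amplitude = amp, phase = pha),
            class = "spectral_descriptor")
}

# wrap radians to (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
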