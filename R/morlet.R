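#' Complex Morlet wavelet kernel
#'
#' A complex sinusoid under a Gaussian envelope, sampled at the display
#' refresh rate and normalized to unit energy. The envelope's standard
#' deviation is `n_cycles / (2 * pi * f)` seconds, so that roughly
#' `n_cycles` oscillation cycles fit under the envelope; fewer cycles give
#' finer temporal and coarser spectral resolution.
#'
#' @param f Center frequency in Hz.
#' @param refresh_rate Sampling rate in Hz.
#' @param n_cycles Number of cycles under the Gaussian envelope.
#' @param sd_cut Half-width of the sampled support in envelope standard
#'   deviations.
#' @return Complex vector of odd length, centered on the wavelet's peak.
#' @export
morlet_kernel <- function(f, refresh_rate = 120, n_cycles = 3, sd_cut = 4) {
  stopifnot(f > 0, n_cycles >= 1)
  sigma_t <- n_cycles / (2 * pi * f)
  half <- max(1L, as.integer(ceiling(sd_cut * sigma_t * refresh_rate)))
  t <- (-half:half) / refresh_rate
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  k / sqrt(sum(Mod(k)^2))
}

# Linear maps (one complex n_frames x n_frames matrix per basis frequency)
# taking a series to its wavelet coefficients at the frame times, under
# zero padding beyond the stimulus window. M[[j]][t, k] is the contribution
# of input frame k to the coefficient at output frame t.
morlet_operators <- function(spec, n_cycles = 3) {
  n <- spec$n_frames
  lapply(spec$frequencies, function(f) {
    kern <- morlet_kernel(f, spec$refresh_rate, n_cycles)
    half <- (length(kern) - 1L) %/% 2L
    M <- matrix(0 + 0i, n, n)
    for (tt in seq_len(n)) {
      off <- seq_len(n) - tt  # lag of input frame relative to output frame
      inside <- abs(off) <= half
      M[tt, inside] <- kern[off[inside] + half + 1L]
    }
    M
  })
}

#' Morlet time-frequency map of a series
#'
#' Convolves a series with unit-energy complex Morlet wavelets at each
#' basis frequency and returns the modulus (amplitude) of the coefficients
#' at every frame, an 11 x 24 grid under the default spec. The series is
#' treated as zero outside the stimulus window (zero padding), so no frame
#' is discarded; edge coefficients simply integrate less signal. A
#' three-cycle wavelet trades spectral for temporal precision, so a pure
#' oscillation also drives neighboring frequency rows (spectral smearing).
#'
#' @param series Numeric series of length `spec$n_frames` (finite), or a
#'   `sampling_function`.
#' @param spec A [basis_spec()].
#' @param n_cycles Cycles under the Gaussian envelope (default 3).
#' @param output `"amplitude"` (modulus, default) or `"power"` (squared
#'   modulus).
#' @return Matrix of nonnegative values, `length(spec$frequencies)` rows
#'   (frequency, Hz, in `rownames`) by `spec$n_frames` columns (frame).
#' @examples
#' spec <- basis_spec()
#' tfm <- morlet_tf(sin(2 * pi * 25 * spec$times), spec)
#' rownames(tfm)[which.max(tfm[, 12])]  # "25"
#' @export
morlet_tf <- function(series, spec = basis_spec(), n_cycles = 3,
                      output = c("amplitude", "power")) {
  output <- match.arg(output)
  if (inherits(series, "sampling_function")) {
    spec <- series$spec
    series <- series$values
  }
  x <- as.numeric(series)
  if (length(x) != spec$n_frames)
    stop("series length must equal spec$n_frames (", spec$n_frames, ")")
  if (!all(is.finite(x))) stop("series contains non-finite values")
  ops <- morlet_operators(spec, n_cycles)
  out <- t(vapply(ops, function(M) as.vector(Mod(M %*% x)),
                  numeric(spec$n_frames)))
  if (output == "power") out <- out^2
  dimnames(out) <- list(format(spec$frequencies, trim = TRUE), NULL)
  out
}

# Batch version: rows of `X` (n_trials x n_frames) -> n_trials x (n_freq *
# n_frames) amplitude matrix, columns in frequency-fastest order matching
# as.vector() of the n_freq x n_frames map.
morlet_tf_batch <- function(X, spec = basis_spec(), n_cycles = 3) {
  stopifnot(is.matrix(X), ncol(X) == spec$n_frames)
  ops <- morlet_operators(spec, n_cycles)
  nfq <- length(ops)
  n <- spec$n_frames
  out <- matrix(NA_real_, nrow(X), nfq * n)
  for (j in seq_len(nfq)) {
    A <- Mod(X %*% t(ops[[j]]))  # n_trials x n_frames
    out[, j + nfq * (seq_len(n) - 1L)] <- A
  }
  out
}
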