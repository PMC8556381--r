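# Independent oracles and small fixtures shared across the test files.
# Everything here is deliberately written by a different route than the
# package implementation (explicit loops, direct convolution, aov()), so
# agreement is evidence, not tautology.

default_spec <- basis_spec()

# Brute-force complex Morlet transform: build the kernel from its
# definition, zero-pad the series to three kernel lengths, convolve with
# an explicit O(L^2) double loop, and crop the stimulus window.
oracle_morlet_tf <- function(x, spec, n_cycles = 3, sd_cut = 4) {
  n <- length(x)
  out <- matrix(NA_real_, length(spec$frequencies), n)
  for (fi in seq_along(spec$frequencies)) {
    f <- spec$frequencies[fi]
    sigma <- n_cycles / (2 * pi * f)
    half <- max(1L, as.integer(ceiling(sd_cut * sigma * spec$refresh_rate)))
    kern <- complex(length.out = 2L * half + 1L)
    for (i in seq_along(kern)) {
      t <- (i - half - 1L) / spec$refresh_rate
      kern[i] <- complex(modulus = exp(-t^2 / (2 * sigma^2)),
                         argument = 2 * pi * f * t)
    }
    kern <- kern / sqrt(sum(Mod(kern)^2))
    pad <- 3L * length(kern)
    xp <- c(rep(0, pad), x, rep(0, pad))
    for (tt in seq_len(n)) {
      acc <- 0 + 0i
      for (i in seq_along(kern)) {
        acc <- acc + xp[pad + tt + (i - half - 1L)] * kern[i]
      }
      out[fi, tt] <- Mod(acc)
    }
  }
  out
}

# Brute-force mean-difference classification image over a feature matrix.
oracle_mean_difference <- function(feats, acc) {
  p <- ncol(feats)
  out <- numeric(p)
  for (j in seq_len(p)) {
    sc <- 0; nc <- 0; se <- 0; ne <- 0
    for (i in seq_len(nrow(feats))) {
      if (acc[i] == 1) { sc <- sc + feats[i, j]; nc <- nc + 1 }
      else             { se <- se + feats[i, j]; ne <- ne + 1 }
    }
    out[j] <- sc / nc - se / ne
  }
  out
}

# Two-way mean squares via aov(), the independent route to the ICC.
oracle_two_way_ms <- function(data) {
  long <- data.frame(value = as.vector(data),
                     rater = factor(rep(seq_len(nrow(data)), ncol(data))),
                     target = factor(rep(seq_len(ncol(data)),
                                         each = nrow(data))))
  tab <- summary(stats::aov(value ~ target + rater, data = long))[[1L]]
  list(targets = tab["target", "Mean Sq"],
       raters = tab["rater", "Mean Sq"],
       error = tab["Residuals", "Mean Sq"])
}

# Small null experiment log: sampling functions paired with labels drawn
# independently of them.
make_null_log <- function(n_trials, spec = default_spec, p_correct = 0.5,
                          participant = "obs", class = "none") {
  d <- tempsamp:::sample_functions(n_trials, spec)
  acc <- stats::rbinom(n_trials, 1L, p_correct)
  while (sum(acc) %in% c(0L, n_trials))
    acc <- stats::rbinom(n_trials, 1L, p_correct)
  experiment_log(d$values, d$amplitudes, d$phases, acc,
                 participant = participant, class = class, spec = spec)
}

# Smoothed, per-point-standardized null Gaussian field on a lattice,
# mirroring what the group pipeline feeds the Pixel test.
make_null_field <- function(shape, fwhm) {
  if (length(shape) == 1L) {
    gaussian_smooth(stats::rnorm(shape), fwhm, standardize = TRUE)
  } else {
    gaussian_smooth(matrix(stats::rnorm(prod(shape)), shape[1L]), fwhm,
                    standardize = TRUE)
  }
}
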