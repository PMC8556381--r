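test_that("basis spec validates its invariants", {
  spec <- basis_spec()
  expect_equal(spec$n_frames, 24L)
  expect_equal(length(spec$frequencies), 11L)
  expect_equal(spec$times, (seq_len(24) - 0.5) / 120)
  expect_error(basis_spec(c(10, 5)), "strictly increasing")
  expect_error(basis_spec(c(5, 65)), "Nyquist")
  expect_error(basis_spec(duration = 0.005), "at least 2 frames")
})

test_that("accepted draws are range-normalized and sum-matched", {
  set.seed(101)
  for (i in 1:20) {
    sf <- make_sampling_function()
    expect_identical(min(sf$values), 0)
    expect_identical(max(sf$values), 0.5)
    expect_lte(abs(sum(sf$values) - 6), 0.05)
    expect_length(sf$values, 24L)
  }
  # independent draws differ
  a <- make_sampling_function()
  b <- make_sampling_function()
  expect_gt(max(abs(a$values - b$values)), 0)
})

test_that("stored parameters regenerate the pre-normalization waveform", {
  set.seed(7)
  sf <- make_sampling_function()
  w <- drop(tempsamp:::basis_waveform(matrix(sf$amplitudes, 1),
                                      matrix(sf$phases, 1), sf$spec))
  # range-normalizing the regenerated waveform reproduces the stored values
  expect_equal(normalize_snr_range(w), sf$values, tolerance = 1e-12)
  # and its Fourier descriptors round-trip the stored parameters
  fd <- fourier_descriptors(w, sf$spec)
  expect_equal(fd$amplitude, sf$amplitudes, tolerance = 1e-10)
  expect_equal(fd$phase, tempsamp:::wrap_phase(sf$phases), tolerance = 1e-8)
})

test_that("range normalization is idempotent and rejects flat input", {
  set.seed(8)
  x <- rnorm(24)
  once <- normalize_snr_range(x)
  expect_equal(normalize_snr_range(once), once, tolerance = 1e-15)
  expect_identical(range(once), c(0, 0.5))
  expect_error(normalize_snr_range(rep(1, 24)), "degenerate")
})

test_that("fourier descriptors recover known components from a series", {
  spec <- basis_spec()
  # constant series has no oscillatory content
  fd0 <- fourier_descriptors(rep(0.3, 24), spec)
  expect_equal(fd0$amplitude, rep(0, 11), tolerance = 1e-12)
  # single integer-cycle sinusoid: exact amplitude and phase at 10 Hz
  x <- 0.37 * sin(2 * pi * 10 * spec$times + 1.2)
  fd <- fourier_descriptors(x, spec)
  expect_equal(fd$amplitude[2], 0.37, tolerance = 1e-12)
  expect_equal(fd$phase[2], 1.2, tolerance = 1e-10)
  expect_lt(max(fd$amplitude[-2]), 1e-12)
  expect_error(fourier_descriptors(rep(0, 23), spec), "length")
})

test_that("sum of squared amplitudes matches series variance", {
  # population variance of a zero-mean basis waveform is sum(a^2)/2,
  # checked against direct summation
  set.seed(9)
  spec <- basis_spec()
  for (i in 1:5) {
    a <- runif(11)
    p <- runif(11, 0, 2 * pi)
    w <- drop(tempsamp:::basis_waveform(matrix(a, 1), matrix(p, 1), spec))
    direct <- sum((w - sum(w) / 24)^2) / 24
    expect_equal(direct, sum(a^2) / 2, tolerance = 1e-10)
  }
})

test_that("per-frame mean SNR is 0.25 and sums stay matched over many draws", {
  set.seed(202)
  d <- tempsamp:::sample_functions(10000, basis_spec())
  expect_true(all(abs(rowSums(d$values) - 6) <= 0.05))
  expect_lt(max(abs(colMeans(d$values) - 0.25)), 0.01)
})

test_that("an exhausted redraw budget signals an error", {
  set.seed(3)
  expect_error(make_sampling_function(sum_tol = 1e-9, max_draws = 50),
               "redraw budget exhausted")
})
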