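test_that("classification-image spectra follow the DFT closed forms", {
  spec <- basis_spec()
  # impulse: equal power at all interior frequencies (DC and Nyquist use
  # the one-sided 1/n scale instead of 2/n)
  imp <- c(1, rep(0, 23))
  sp <- ci_power_phase(imp, spec)
  expect_equal(sp$frequencies, seq(0, 60, by = 5))
  expect_equal(diff(range(sp$power[1, 2:12])), 0, tolerance = 1e-12)
  # integer-cycle sinusoid: power a^2 at its own bin, none elsewhere
  x <- 0.8 * sin(2 * pi * 15 * spec$times + 0.3)
  sp2 <- ci_power_phase(x, spec)
  expect_equal(sp2$power[1, 4], 0.64, tolerance = 1e-10)
  expect_lt(max(sp2$power[1, -4]), 1e-12)
})

test_that("tf-domain images yield one spectrum per sampling frequency", {
  set.seed(71)
  log <- make_null_log(40)
  ci <- raw_classification_image(log, "tf")
  sp <- ci_power_phase(ci)
  expect_identical(nrow(sp$power), 11L)
  expect_identical(ncol(sp$power), 13L)
  ci_f <- raw_classification_image(log, "fourier")
  expect_error(ci_power_phase(ci_f), "already a spectrum")
})

test_that("icc matches the aov decomposition and its known limits", {
  set.seed(72)
  data <- matrix(rnorm(6 * 20), 6) + rep(rnorm(20, sd = 2), each = 6)
  ms <- oracle_two_way_ms(data)
  rep_ <- icc(data)
  expect_equal(unname(rep_$ms["targets"]), ms$targets, tolerance = 1e-10)
  expect_equal(unname(rep_$ms["error"]), ms$error, tolerance = 1e-10)
  expect_equal(rep_$icc, (ms$targets - ms$error) / ms$targets,
               tolerance = 1e-10)
  expect_lte(rep_$ci_low, rep_$icc)
  expect_gte(rep_$ci_high, rep_$icc)
  expect_lte(rep_$ci_high, 1)
  # identical raters agree perfectly
  x <- rnorm(20)
  expect_equal(icc(rbind(x, x, x))$icc, 1, tolerance = 1e-12)
  # anti-correlated raters can fall below -1: no lower bound
  expect_lt(icc(rbind(x, -0.9 * x))$icc, -1)
  expect_error(icc(matrix(1, 3, 5)), "zero variance")
  expect_error(icc(matrix(rnorm(4), 1)), "2 raters")
})

test_that("consistency icc ignores rater offsets and scales", {
  set.seed(73)
  data <- matrix(rnorm(5 * 15), 5) + rep(rnorm(15), each = 5)
  shifted <- data + matrix(rnorm(5, sd = 3), 5, 15)
  expect_equal(icc(3 + 2 * data)$icc, icc(data)$icc, tolerance = 1e-10)
  # per-rater offsets leave consistency unchanged but hurt agreement
  expect_equal(icc(shifted)$icc, icc(data)$icc, tolerance = 1e-10)
  expect_lt(icc(shifted, type = "agreement")$icc,
            icc(shifted, type = "consistency")$icc)
})

test_that("independent raters have near-zero icc on average", {
  # the estimator's small-sample bias is about -2/(n_targets - 3), so use
  # enough targets for "near zero" to be meaningful
  set.seed(74)
  vals <- replicate(300, icc(matrix(rnorm(4 * 100), 4))$icc)
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("leave-one-out decoding separates separable classes", {
  set.seed(75)
  centers <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  feats <- centers[rep(1:3, each = 6), ] + matrix(rnorm(18 * 3, sd = 0.1), 18)
  labels <- rep(c("a", "b", "c"), each = 6)
  res <- decode_loo(feats, labels)
  expect_equal(res$accuracy, 1.0)
  expect_identical(res$chi2$df, 4L)
  expect_lt(res$chi2$p_value, 1e-4)
  expect_error(decode_loo(feats[1:7, ], labels[1:7]), "at least 2 participants")
})

test_that("shuffled labels decode at chance on average", {
  set.seed(76)
  feats <- matrix(rnorm(16 * 6), 16)
  accs <- replicate(25, {
    labels <- sample(rep(c("a", "b"), each = 8))
    decode_loo(feats, labels)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})
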