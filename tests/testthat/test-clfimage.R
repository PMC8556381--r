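test_that("raw classification image equals the brute-force mean difference", {
  set.seed(51)
  spec <- basis_spec()
  log <- make_null_log(60)
  for (domain in c("time", "fourier", "tf")) {
    ci <- raw_classification_image(log, domain, spec)
    feats <- trial_features(log, domain, spec)
    expect_equal(as.vector(ci$values),
                 oracle_mean_difference(feats, log$accuracy),
                 tolerance = 1e-12)
  }
})

test_that("degenerate logs are rejected and singleton logs subtract", {
  set.seed(52)
  spec <- basis_spec()
  d <- tempsamp:::sample_functions(2, spec)
  log <- experiment_log(d$values, d$amplitudes, d$phases, c(1L, 0L))
  ci <- raw_classification_image(log, "time", spec)
  expect_equal(ci$values, d$values[1, ] - d$values[2, ], tolerance = 1e-12)
  log_all <- experiment_log(d$values, d$amplitudes, d$phases, c(1L, 1L))
  expect_error(raw_classification_image(log_all, "time", spec),
               "correct and one error")
  # identical correct and error sets cancel exactly
  d2 <- tempsamp:::sample_functions(3, spec)
  log_eq <- experiment_log(rbind(d2$values, d2$values),
                           rbind(d2$amplitudes, d2$amplitudes),
                           rbind(d2$phases, d2$phases),
                           c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(max(abs(raw_classification_image(log_eq, "time",
                                                spec)$values)), 0,
               tolerance = 1e-12)
})

test_that("bootstrap Z images are standard normal under the null", {
  set.seed(53)
  n_logs <- 250
  Z <- replicate(n_logs, bootstrap_z(make_null_log(100), "time",
                                     n_boot = 400)$values)
  mu <- rowMeans(Z)
  sdv <- apply(Z, 1, sd)
  expect_lt(max(abs(mu)), 3.5 / sqrt(n_logs))  # per-point null mean
  expect_true(all(sdv > 0.85 & sdv < 1.15))
  expect_equal(formals(bootstrap_z)$n_boot, 1000)
})

test_that("bootstrap Z carries its provenance and flags degeneracy", {
  set.seed(54)
  log <- make_null_log(50)
  z <- bootstrap_z(log, "time", n_boot = 200)
  expect_identical(z$scale, "z")
  expect_identical(z$meta$n_boot, 200)
  expect_identical(z$meta$n_correct + z$meta$n_error, 50L)
  # constant features make the bootstrap SD collapse
  flat <- log
  flat[tempsamp:::snr_cols(basis_spec())] <-
    matrix(0.25, nrow(log), 24)
  expect_error(bootstrap_z(flat, "time", n_boot = 100), "SD is zero")
})

test_that("gaussian smoothing preserves the mean and standardizes", {
  set.seed(55)
  x <- rnorm(24)
  expect_equal(mean(gaussian_smooth(x, 0.6)), mean(x), tolerance = 1e-10)
  expect_equal(mean(gaussian_smooth(x, 3)), mean(x), tolerance = 1e-10)
  m <- matrix(rnorm(11 * 24), 11)
  expect_equal(mean(gaussian_smooth(m, 1.5)), mean(m), tolerance = 1e-10)
  # standardization restores exact unit variance for an iid null
  S <- tempsamp:::smooth_operator(24, 1.5)
  v <- rowSums(S^2)
  expect_equal(apply(replicate(4000, gaussian_smooth(rnorm(24), 1.5,
                                                     standardize = TRUE)),
                     1, sd),
               rep(1, 24), tolerance = 0.08)
  expect_false(isTRUE(all.equal(v, rep(1, 24))))
})

test_that("the group pipeline rejects mixed or raw input", {
  set.seed(56)
  z1 <- bootstrap_z(make_null_log(40), "time", n_boot = 100)
  z2 <- bootstrap_z(make_null_log(40), "fourier", n_boot = 100)
  expect_error(group_pipeline(list(z1, z2)), "mix domains")
  raw <- raw_classification_image(make_null_log(40), "time")
  expect_error(group_pipeline(list(raw)), "Z-scored")
})

test_that("a planted shared template produces significant points at its peaks", {
  set.seed(57)
  spec <- basis_spec()
  tmpl <- sin(2 * pi * 10 * spec$times)
  cis <- lapply(1:8, function(i) {
    m <- observer_model(tmpl, gain = 6, id = paste0("o", i))
    bootstrap_z(simulate_dataset(m, 800), "time", n_boot = 400)
  })
  gr <- group_pipeline(cis, fwhm = 0.6, alpha = 0.05)
  expect_gt(sum(gr$mask == 1), 0)
  # significant points agree in sign with the planted template, and the
  # strongest response sits at a template peak
  expect_true(all(tmpl[gr$mask == 1] > 0))
  expect_true(all(tmpl[gr$mask == -1] < 0))
  expect_gt(tmpl[which.max(gr$mean_z)], 0.8)
})

test_that("contrasts are antisymmetric and null for identical groups", {
  set.seed(58)
  ga <- lapply(1:3, function(i) bootstrap_z(make_null_log(60), "time",
                                            n_boot = 150))
  gb <- lapply(1:3, function(i) bootstrap_z(make_null_log(60), "time",
                                            n_boot = 150))
  ab <- contrast_classification_image(ga, gb, seed = 99, n_boot = 200)
  ba <- contrast_classification_image(gb, ga, seed = 99, n_boot = 200)
  expect_equal(ab$meta$raw_difference, -ba$meta$raw_difference,
               tolerance = 1e-12)
  expect_equal(ab$mean_z, -ba$mean_z, tolerance = 1e-12)
  expect_identical(ab$mask, -ba$mask)
  # identical groups: zero difference everywhere, nothing significant
  aa <- contrast_classification_image(ga, ga, seed = 99, n_boot = 200)
  expect_equal(max(abs(aa$meta$raw_difference)), 0, tolerance = 1e-12)
  expect_true(all(aa$mask == 0))
  expect_error(contrast_classification_image(ga[1], gb, n_boot = 50),
               "at least 2 participants")
})

test_that("contrasting disjoint templates localizes the difference", {
  set.seed(59)
  spec <- basis_spec()
  t_a <- sin(2 * pi * 10 * spec$times)
  make_group <- function(tmpl, gain) lapply(1:6, function(i) {
    m <- observer_model(tmpl, gain = gain)
    bootstrap_z(simulate_dataset(m, 600), "time", n_boot = 300)
  })
  ga <- make_group(t_a, 6)
  gb <- make_group(rep(0, 24), 0)
  gr <- contrast_classification_image(ga, gb, n_boot = 300, seed = 17)
  expect_gt(sum(gr$mask != 0), 0)
  expect_true(all(t_a[gr$mask == 1] > 0))
  expect_true(all(t_a[gr$mask == -1] < 0))
})
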