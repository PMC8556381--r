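test_that("frame composition matches luminance and contrast across frames", {
  set.seed(21)
  target <- matrix(runif(32 * 32, 0.2, 0.8), 32)
  sf <- make_sampling_function()
  fs <- compose_frames(target, noise_level = 40, sf)
  means <- vapply(fs$frames, mean, 0)
  sds <- vapply(fs$frames, function(f) sd(as.vector(f)), 0)
  expect_lt(max(means) - min(means), 1e-6)
  expect_lt(max(sds) - min(sds), 1e-6)
  expect_true(all(vapply(fs$frames, function(f) all(f >= 0 & f <= 1), TRUE)))
  expect_length(fs$frames, 24L)
})

test_that("weight limits recover the pure components", {
  set.seed(22)
  target <- matrix(runif(16 * 16), 16)
  # all-zero weights (invariant bypassed): frames equal the noise component
  fs0 <- compose_frames(target, noise_level = 1, rep(0, 24))
  expect_equal(fs0$frames[[1]], fs0$frames[[24]], tolerance = 1e-12)
  expect_gt(sd(as.vector(fs0$frames[[1]])), 0.2)  # maximal-contrast noise
  # weight one and the null mask (level 1): frames equal the target
  fs1 <- compose_frames(target, noise_level = 1, rep(1, 24))
  expect_equal(fs1$frames[[5]], target, tolerance = 1e-12)
})

test_that("composition is deterministic given the seed and validates input", {
  target <- matrix(runif(8 * 8), 8)
  sf <- make_sampling_function()
  set.seed(5); a <- compose_frames(target, 20, sf)
  set.seed(5); b <- compose_frames(target, 20, sf)
  expect_identical(a$frames, b$frames)
  expect_error(compose_frames(target * 2, 20, sf), "\\[0, 1\\]")
  expect_error(compose_frames(target, 0, sf), "noise_level")
  expect_error(compose_frames(target, 129, sf), "noise_level")
})

test_that("staircase holds for ten trials then follows the window rule", {
  st <- staircase_state()
  expect_equal(st$level, 64L)
  expect_equal(st$step, 16L)
  for (i in 1:10) st <- staircase_update(st, i)
  expect_equal(st$level, 64L)
  # exactly 50% leaves the level unchanged
  st2 <- staircase_update(st, 11, rep(c(0, 1), 5))
  expect_equal(st2$level, 64L)
  # below 50% lowers noise contrast, above raises it
  expect_equal(staircase_update(st, 11, rep(0, 10))$level, 48L)
  expect_equal(staircase_update(st, 11, rep(1, 10))$level, 80L)
  expect_error(staircase_update(st, 11), "window")
  expect_error(staircase_update(st, 11, c(1, 2)), "0 or 1")
})

test_that("step halves on each reversal down to a floor of one", {
  st <- staircase_state()
  st <- staircase_update(st, 11, rep(1, 10))   # up, step 16
  expect_equal(st$step, 16L)
  st <- staircase_update(st, 12, rep(0, 10))   # reversal: 8
  expect_equal(st$step, 8L)
  st <- staircase_update(st, 13, rep(1, 10))   # reversal: 4
  expect_equal(st$step, 4L)
  for (i in 14:17) {
    st <- staircase_update(st, i, rep(c(0, 1)[1 + i %% 2], 10))
  }
  expect_equal(st$step, 1L)                    # floor reached
  # level clamps to the available range
  st$level <- 2L; st$step <- 16L; st$last_direction <- "down"
  st <- staircase_update(st, 20, rep(0, 10))
  expect_equal(st$level, 1L)
  st$level <- 127L; st$step <- 16L; st$last_direction <- "up"
  st <- staircase_update(st, 21, rep(1, 10))
  expect_equal(st$level, 128L)
})

test_that("a monotone simulated observer converges to half correct", {
  set.seed(31)
  accs <- replicate(6, {
    log <- simulate_staircase(1200)
    mean(log$accuracy[801:1200])
  })
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.55)
})
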