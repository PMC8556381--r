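#' @importFrom stats rnorm runif rbinom
NULL

# column-name helpers for the canonical trial-log layout
snr_cols <- function(spec) sprintf("snr_%02d", seq_len(spec$n_frames))
amp_cols <- function(spec) sprintf("amp_%02d", seq_along(spec$frequencies))
pha_cols <- function(spec) sprintf("pha_%02d", seq_along(spec$frequencies))

#' Per-trial feature matrix in a coding domain
#'
#' Re-codes the trial log's sampling functions in one of the three domains
#' entering classification images: `time` (the 24 SNR values), `fourier`
#' (the 11 construction amplitudes followed by the 11 phases) or `tf` (the
#' Morlet amplitude map, flattened frequency-fastest so that column
#' `j + 11 * (t - 1)` is frequency row `j` at frame `t`).
#'
#' @param log An `experiment_log` data frame.
#' @param domain `"time"`, `"fourier"` or `"tf"`.
#' @param spec A [basis_spec()].
#' @param n_cycles Morlet cycles (tf domain only).
#' @return Numeric matrix, one row per trial.
#' @export
trial_features <- function(log, domain = c("time", "fourier", "tf"),
                           spec = basis_spec(), n_cycles = 3) {
  domain <- match.arg(domain)
  switch(domain,
    time = as.matrix(log[, snr_cols(spec)]),
    fourier = as.matrix(log[, c(amp_cols(spec), pha_cols(spec))]),
    tf = morlet_tf_batch(as.matrix(log[, snr_cols(spec)]), spec, n_cycles))
}

new_classification_image <- function(values, domain, scale, spec, meta = list()) {
  structure(list(values = values, domain = domain, scale = scale,
                 spec = spec, meta = meta), class = "classification_image")
}

#' @export
print.classification_image <- function(x, ...) {
  dims <- if (is.matrix(x$values)) paste(dim(x$values), collapse = " x ")
          else length(x$values)
  cat("Classification image [", x$domain, ", ", x$scale, "] ", dims,
      " points\n", sep = "")
  invisible(x)
}

# shape a flat feature vector into the domain's natural layout
shape_ci_values <- function(v, domain, spec) {
  if (domain == "tf")
    matrix(v, nrow = length(spec$frequencies),
           dimnames = list(format(spec$frequencies, trim = TRUE), NULL))
  else as.numeric(v)
}

#' Raw classification image
#'
#' The weighted subtraction at the heart of reverse correlation: the mean
#' of the trial features on correct trials minus the mean on error trials
#' (weights `1/n_correct` and `1/n_error`, the only weighting whose null
#' expectation is zero under unequal counts). Positive values mark moments
#' (or frequencies) whose stimulus information helped performance, negative
#' values moments that hurt it.
#'
#' @inheritParams trial_features
#' @return A `classification_image` with `scale = "raw"`: a length-24
#'   vector (time), a length-22 vector (fourier: 11 amplitudes then 11
#'   phases) or an 11 x 24 matrix (tf).
#' @export
raw_classification_image <- function(log, domain = c("time", "fourier", "tf"),
                                     spec = basis_spec(), n_cycles = 3) {
  domain <- match.arg(domain)
  acc <- log$accuracy
  if (!any(acc == 1) || !any(acc == 0))
    stop("log must contain at least one correct and one error trial")
  feats <- trial_features(log, domain, spec, n_cycles)
  v <- colMeans(feats[acc == 1, , drop = FALSE]) -
       colMeans(feats[acc == 0, , drop = FALSE])
  new_classification_image(shape_ci_values(v, domain, spec), domain, "raw",
                           spec,
                           list(n_correct = sum(acc == 1),
                                n_error = sum(acc == 0)))
}

# internal: raw mean-difference image from a precomputed feature matrix
raw_ci_values <- function(feats, acc) {
  colMeans(feats[acc == 1, , drop = FALSE]) -
    colMeans(feats[acc == 0, , drop = FALSE])
}

#' Bootstrap Z-scored classification image
#'
#' Transforms a raw classification image into Z scores against its own
#' resampling null: on each of `n_boot` iterations the observed accuracy
#' labels are kept fixed as a multiset and paired with sampling functions
#' drawn with replacement from the log, and a random classification image
#' is computed. The mean and standard deviation of these `n_boot` random
#' images convert the observed raw image into Z scores point by point.
#' Because the label multiset is fixed, the null preserves the observed
#' accuracy rate.
#'
#' @inheritParams trial_features
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @return A `classification_image` with `scale = "z"` and bootstrap
#'   metadata (`n_boot`, per-point bootstrap mean and SD).
#' @export
bootstrap_z <- function(log, domain = c("time", "fourier", "tf"),
                        spec = basis_spec(), n_boot = 1000, n_cycles = 3) {
  domain <- match.arg(domain)
  stopifnot(n_boot >= 2)
  acc <- log$accuracy
  if (!any(acc == 1) || !any(acc == 0))
    stop("log must contain at least one correct and one error trial")
  feats <- trial_features(log, domain, spec, n_cycles)
  n <- nrow(feats)
  n_c <- sum(acc == 1)
  n_e <- n - n_c
  raw <- raw_ci_values(feats, acc)

  boot <- cpp_boot_images(feats, n_c, n_e, n_boot)  # p x n_boot
  m <- rowMeans(boot)
  s <- sqrt(rowMeans(boot^2) - m^2) * sqrt(n_boot / (n_boot - 1))
  if (any(s == 0))
    stop("bootstrap SD is zero at point(s) ",
         paste(which(s == 0), collapse = ", "),
         "; features are degenerate there")
  z <- (raw - m) / s
  new_classification_image(shape_ci_values(z, domain, spec), domain, "z",
                           spec,
                           list(n_correct = n_c, n_error = n_e,
                                n_boot = n_boot,
                                boot_mean = shape_ci_values(m, domain, spec),
                                boot_sd = shape_ci_values(s, domain, spec)))
}

# --- Gaussian smoothing ------------------------------------------------

# n x n smoothing operator: normalized Gaussian kernel of the given FWHM,
# half-sample reflective boundary. For a symmetric kernel this operator is
# doubly stochastic, so it preserves the image mean exactly.
smooth_operator <- function(n, fwhm) {
  if (fwhm <= 0) return(diag(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pos <- i + (-h):h
    # fold out-of-range positions back into 1..n (half-sample reflection)
    while (any(pos < 1L | pos > n)) {
      pos <- ifelse(pos < 1L, 1L - pos, pos)
      pos <- ifelse(pos > n, 2L * n + 1L - pos, pos)
    }
    for (j in seq_along(pos)) S[i, pos[j]] <- S[i, pos[j]] + k[j]
  }
  S
}

#' Gaussian smoothing of a classification image
#'
#' Smooths a vector or matrix with a normalized Gaussian kernel of the
#' given FWHM (in bins), separable across dimensions, with reflective
#' boundary handling so edge bins are neither discarded nor attenuated.
#' With `standardize = TRUE` each point is additionally divided by the
#' operator's row norm, the exact per-point standard deviation of the
#' smoothed field when the input bins are independent unit-variance
#' Gaussians; this keeps a null Z image unit-variance after smoothing.
#'
#' @param x Numeric vector or matrix.
#' @param fwhm Kernel FWHM in bins; scalar or one value per dimension.
#' @param standardize Restandardize to unit null variance (default FALSE).
#' @return Smoothed object of the same shape.
#' @export
gaussian_smooth <- function(x, fwhm, standardize = FALSE) {
  if (is.matrix(x)) {
    if (length(fwhm) == 1L) fwhm <- c(fwhm, fwhm)
    Sr <- smooth_operator(nrow(x), fwhm[1L])
    Sc <- smooth_operator(ncol(x), fwhm[2L])
    out <- Sr %*% x %*% t(Sc)
    if (standardize)
      out <- out / sqrt(outer(rowSums(Sr^2), rowSums(Sc^2)))
    out
  } else {
    S <- smooth_operator(length(x), fwhm[1L])
    out <- drop(S %*% x)
    if (standardize) out <- out / sqrt(rowSums(S^2))
    out
  }
}

# --- group-level analysis ----------------------------------------------

default_fwhm <- function(domain)
  switch(domain, time = 0.6, tf = 1.5, fourier = 0)

ci_geometry <- function(domain, spec, fwhm) {
  shape <- switch(domain,
                  time = spec$n_frames,
                  fourier = 2L * length(spec$frequencies),
                  tf = c(length(spec$frequencies), spec$n_frames))
  field_geometry(shape, fwhm)
}

new_group_result <- function(mean_z, z_crit, mask, alpha, fwhm, domain, spec,
                             meta = list()) {
  structure(list(mean_z = mean_z, z_crit = as.numeric(z_crit), mask = mask,
                 alpha = alpha, fwhm = fwhm, domain = domain, spec = spec,
                 meta = c(meta, list(alpha_tail = attr(z_crit, "alpha_tail"),
                                     z_rft = attr(z_crit, "z_rft"),
                                     z_bonferroni = attr(z_crit, "z_bonferroni")))),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("Group classification image [", x$domain, "], z_crit = ",
      round(x$z_crit, 3), " (alpha = ", x$alpha, ", FWHM = ",
      paste(x$fwhm, collapse = " x "), ")\n", sep = "")
  cat("  significant points: ", sum(x$mask == 1L), " positive, ",
      sum(x$mask == -1L), " negative of ", length(x$mask), "\n", sep = "")
  invisible(x)
}

#' Group averaging, smoothing and Pixel-test thresholding
#'
#' Combines individual Z-scored classification images into a group image
#' and marks its significant points. The participant images are combined
#' as a Stouffer sum (mean times the square root of the number of
#' participants), which leaves the group image unit-variance under the
#' null; the result is Gaussian-smoothed with per-point restandardization
#' (see [gaussian_smooth()]) and thresholded two-ways at the critical Z of
#' the Pixel test for the image's geometry.
#'
#' @param cis List of `classification_image` objects, all `scale = "z"`,
#'   same domain and shape.
#' @param fwhm Smoothing FWHM in bins (defaults: 0.6 for time, 1.5 for tf,
#'   0, i.e. no smoothing, for fourier).
#' @param alpha Overall family-wise alpha (default 0.05, two-way).
#' @return A `group_result`: the smoothed group Z image `mean_z`, the
#'   critical value `z_crit`, and `mask` (+1 where `mean_z > z_crit`, -1
#'   where `mean_z < -z_crit`, else 0).
#' @export
group_pipeline <- function(cis, fwhm = NULL, alpha = 0.05) {
  stopifnot(length(cis) >= 1L,
            all(vapply(cis, inherits, TRUE, "classification_image")))
  domain <- unique(vapply(cis, function(x) x$domain, ""))
  if (length(domain) != 1L) stop("classification images mix domains")
  if (!all(vapply(cis, function(x) x$scale, "") == "z"))
    stop("group_pipeline expects Z-scored classification images")
  spec <- cis[[1L]]$spec
  if (is.null(fwhm)) fwhm <- default_fwhm(domain)
  vals <- lapply(cis, function(x) x$values)
  mean_z <- Reduce(`+`, vals) / length(vals)
  g <- mean_z * sqrt(length(vals))            # Stouffer combination
  gs <- gaussian_smooth(g, fwhm, standardize = TRUE)
  geom <- ci_geometry(domain, spec, if (domain == "tf" && length(fwhm) == 1L)
    c(fwhm, fwhm) else fwhm)
  z_crit <- pixel_threshold(geom, alpha, tails = "two")
  mask <- sign(gs) * (abs(gs) > as.numeric(z_crit))
  new_group_result(gs, z_crit, mask, alpha, fwhm, domain, spec,
                   list(n_participants = length(vals)))
}

#' Contrast classification image between two groups
#'
#' Tests where processing efficiency differs between two stimulus classes:
#' the difference of the two group mean Z images is Z-scored against a
#' participant-level bootstrap null built under group-label exchange (the
#' participants of both groups are pooled in a canonical order; on each
#' iteration pseudo-groups of the original sizes are drawn with
#' replacement from the pool and their difference recorded; the null scale
#' is the root mean square of these differences, a symmetrized estimate
#' centered at zero). The contrast Z image is then smoothed,
#' restandardized and Pixel-thresholded like a group image. The raw
#' difference is exactly antisymmetric in the group order, and with equal
#' group sizes the bootstrap scale is invariant under the swap, so the
#' significance mask flips sign exactly.
#'
#' @param group_a,group_b Lists of Z-scale `classification_image` objects
#'   (one per participant), same domain and shape.
#' @param fwhm,alpha As in [group_pipeline()].
#' @param n_boot Bootstrap iterations over participants (default 1000).
#' @param seed Optional seed for the participant resampling.
#' @return A `group_result` for the difference (A minus B).
#' @export
contrast_classification_image <- function(group_a, group_b, fwhm = NULL,
                                          alpha = 0.05, n_boot = 1000,
                                          seed = NULL) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  domain <- unique(vapply(c(group_a, group_b), function(x) x$domain, ""))
  if (length(domain) != 1L) stop("groups mix domains")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("participant resampling needs at least 2 participants per group")
  spec <- group_a[[1L]]$spec
  if (is.null(fwhm)) fwhm <- default_fwhm(domain)
  if (!is.null(seed)) set.seed(seed)
  A <- t(vapply(group_a, function(x) as.vector(x$values),
                numeric(length(group_a[[1L]]$values))))
  B <- t(vapply(group_b, function(x) as.vector(x$values),
                numeric(length(group_a[[1L]]$values))))
  diff_raw <- colMeans(A) - colMeans(B)
  pool <- rbind(A, B)
  # canonical row order makes the null invariant to the group labelling
  pool <- pool[do.call(order, as.data.frame(pool)), , drop = FALSE]
  na <- nrow(A); nb <- nrow(B); np <- na + nb
  d2 <- 0
  for (b in seq_len(n_boot)) {
    ia <- sample.int(np, na, replace = TRUE)
    ib <- sample.int(np, nb, replace = TRUE)
    db <- colMeans(pool[ia, , drop = FALSE]) -
          colMeans(pool[ib, , drop = FALSE])
    d2 <- d2 + db^2
  }
  s <- sqrt(d2 / n_boot)
  if (any(s == 0))
    stop("bootstrap SD is zero at point(s) ",
         paste(which(s == 0), collapse = ", "))
  z <- shape_ci_values(diff_raw / s, domain, spec)
  gs <- gaussian_smooth(z, fwhm, standardize = TRUE)
  geom <- ci_geometry(domain, spec, if (domain == "tf" && length(fwhm) == 1L)
    c(fwhm, fwhm) else fwhm)
  z_crit <- pixel_threshold(geom, alpha, tails = "two")
  mask <- sign(gs) * (abs(gs) > as.numeric(z_crit))
  new_group_result(gs, z_crit, mask, alpha, fwhm, domain, spec,
                   list(n_a = na, n_b = nb, n_boot = n_boot,
                        raw_difference = shape_ci_values(diff_raw, domain, spec)))
}
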