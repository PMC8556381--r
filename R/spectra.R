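#' Power and phase spectra of a classification image
#'
#' One-dimensional discrete Fourier transform of a raw classification
#' image along the time axis: the whole 24-point series for a time-domain
#' image, or each of the 11 sampling-frequency rows separately for a
#' time-frequency image. Amplitudes use the one-sided convention (interior
#' bins scaled by `2/n`, DC and Nyquist by `1/n`) so that a sinusoid of
#' amplitude `a` completing an integer number of cycles yields power `a^2`
#' at its frequency. The spectral resolution is `1/duration` (5 Hz for the
#' 200 ms window), giving frequencies 0 to 60 Hz in 5 Hz steps.
#'
#' @param ci A raw-scale `classification_image` in the time or tf domain
#'   (Fourier-domain images are already spectra and are rejected). A bare
#'   numeric vector or matrix (rows transformed separately) is also
#'   accepted, with `spec` supplying the timing.
#' @param spec A [basis_spec()]; taken from the object when `ci` is a
#'   `classification_image`.
#' @return Object of class `ci_spectrum`: list with `frequencies` (Hz),
#'   `power` and `phase` matrices (rows = input rows, 1 for time domain,
#'   11 for tf), and `domain`.
#' @export
ci_power_phase <- function(ci, spec = basis_spec()) {
  domain <- "time"
  if (inherits(ci, "classification_image")) {
    if (ci$domain == "fourier")
      stop("a Fourier-domain classification image is already a spectrum")
    spec <- ci$spec
    domain <- ci$domain
    ci <- ci$values
  }
  X <- if (is.matrix(ci)) ci else matrix(ci, nrow = 1L)
  n <- ncol(X)
  if (n != spec$n_frames)
    stop("series length must equal spec$n_frames (", spec$n_frames, ")")
  nk <- n %/% 2L + 1L
  co <- t(apply(X, 1L, function(x) stats::fft(x)[seq_len(nk)]))
  if (nrow(X) == 1L) co <- matrix(co, nrow = 1L)
  scale <- rep(2 / n, nk)
  scale[1L] <- 1 / n
  if (n %% 2L == 0L) scale[nk] <- 1 / n
  amp <- sweep(Mod(co), 2L, scale, `*`)
  structure(list(frequencies = (seq_len(nk) - 1L) / spec$duration,
                 power = amp^2, phase = Arg(co), domain = domain),
            class = "ci_spectrum")
}

#' Intraclass correlation between participants
#'
#' Quantifies how well one participant's pattern of values across
#' measurement points predicts another's, using the average-measures
#' intraclass correlation from the two-way targets-by-raters ANOVA
#' decomposition. The default consistency form, ICC(3,k) =
#' (MS_targets - MS_error) / MS_targets, is bounded above by 1 and has no
#' lower bound; it is insensitive to additive and multiplicative rater
#' differences. The absolute-agreement form ICC(2,k), which penalizes
#' rater offsets, is also available. The 95% confidence interval comes
#' from the F distribution of MS_targets / MS_error (consistency) or the
#' McGraw-Wong approximation (agreement).
#'
#' @param data Numeric matrix, raters (participants) in rows, targets
#'   (measurement points) in columns; >= 2 raters, >= 3 targets.
#' @param type `"consistency"` (ICC(3,k), default) or `"agreement"`
#'   (ICC(2,k)).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `agreement_report`: list with `icc`, `ci_low`,
#'   `ci_high`, `n_raters`, `n_targets`, `type` and the mean squares.
#' @export
icc <- function(data, type = c("consistency", "agreement"),
                conf_level = 0.95) {
  type <- match.arg(type)
  data <- as.matrix(data)
  stopifnot(is.numeric(data), all(is.finite(data)))
  nr <- nrow(data)  # raters
  nt <- ncol(data)  # targets
  if (nr < 2L) stop("need at least 2 raters (rows)")
  if (nt < 3L) stop("need at least 3 targets (columns)")
  gm <- mean(data)
  tm <- colMeans(data)
  rm_ <- rowMeans(data)
  ss_t <- nr * sum((tm - gm)^2)
  ss_r <- nt * sum((rm_ - gm)^2)
  ss_tot <- sum((data - gm)^2)
  ss_e <- ss_tot - ss_t - ss_r
  df_t <- nt - 1L
  df_r <- nr - 1L
  df_e <- df_t * df_r
  ms_t <- ss_t / df_t
  ms_r <- ss_r / df_r
  ms_e <- ss_e / df_e
  if (ms_t <= 0) stop("zero variance across targets: ICC undefined")
  a <- (1 - conf_level) / 2
  if (type == "consistency") {
    est <- (ms_t - ms_e) / ms_t
    Fo <- ms_t / ms_e
    fl <- Fo / stats::qf(1 - a, df_t, df_e)
    fu <- Fo * stats::qf(1 - a, df_e, df_t)
    ci <- c(1 - 1 / fl, 1 - 1 / fu)
  } else {
    est <- (ms_t - ms_e) / (ms_t + (ms_r - ms_e) / nt)
    # McGraw & Wong (1996) interval for ICC(A,k), Satterthwaite df
    icc_a1 <- (ms_t - ms_e) / (ms_t + (nr - 1) * ms_e +
                                 nr * (ms_r - ms_e) / nt)
    aa <- nr * icc_a1 / (nt * (1 - icc_a1))
    bb <- 1 + nr * icc_a1 * (nt - 1) / (nt * (1 - icc_a1))
    v <- (aa * ms_r + bb * ms_e)^2 /
      ((aa * ms_r)^2 / df_r + (bb * ms_e)^2 / df_e)
    fstar_l <- stats::qf(1 - a, nt - 1, v)
    fstar_u <- stats::qf(1 - a, v, nt - 1)
    low1 <- nt * (ms_t - fstar_l * ms_e) /
      (fstar_l * (nr * ms_r - nr * ms_e) + nt * ms_t)
    up1 <- nt * (fstar_u * ms_t - ms_e) /
      (nr * ms_r - nr * ms_e + nt * fstar_u * ms_t)
    ci <- sort(c(low1, up1))
  }
  ci <- pmin(ci, 1)
  structure(list(icc = est, ci_low = min(ci[1L], est),
                 ci_high = max(ci[2L], est),
                 n_raters = nr, n_targets = nt, type = type,
                 ms = c(targets = ms_t, raters = ms_r, error = ms_e),
                 conf_level = conf_level),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("ICC (", x$type, ", average measures) = ", round(x$icc, 3),
      "  [", round(x$ci_low, 3), ", ", round(x$ci_high, 3), "]  (",
      x$n_raters, " raters x ", x$n_targets, " targets)\n", sep = "")
  invisible(x)
}

#' Leave-one-out class decoding from classification-image spectra
#'
#' Predicts each participant's stimulus class from their
#' classification-image power spectrum with a linear support vector
#' machine trained on all other participants (leave-one-out
#' cross-validation, one-vs-one multiclass). Features are standardized
#' with statistics from the training fold only. Significance against
#' chance is assessed with a chi-square test of independence on the
#' predicted-versus-true contingency table (df = (k - 1)^2 for k classes).
#'
#' @param features Numeric matrix, participants in rows, spectral features
#'   in columns.
#' @param labels Class label per participant (>= 2 classes, >= 2
#'   participants per class).
#' @param cost SVM regularization constant (default 1).
#' @return List with `accuracy` (fraction correct), `predicted`,
#'   `confusion` (k x k table, true in rows) and `chi2` (list: statistic,
#'   df, p_value).
#' @export
decode_loo <- function(features, labels, cost = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 participants (LOO training set ",
         "must retain all classes)")
  n <- nrow(features)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]
    mu <- colMeans(tr_x)
    sdv <- apply(tr_x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    tr_x <- sweep(sweep(tr_x, 2L, mu), 2L, sdv, `/`)
    te_x <- (features[i, ] - mu) / sdv
    fit <- e1071::svm(tr_x, droplevels(labels[-i]), kernel = "linear",
                      cost = cost, scale = FALSE)
    pr <- stats::predict(fit, matrix(te_x, nrow = 1L))
    pred[i] <- as.character(pr)
  }
  confusion <- table(true = labels, predicted = pred)
  k <- nlevels(labels)
  expd <- outer(rowSums(confusion), colSums(confusion)) / n
  ok <- expd > 0
  stat <- sum((confusion[ok] - expd[ok])^2 / expd[ok])
  df <- as.integer((k - 1L)^2)
  list(accuracy = mean(pred == labels),
       predicted = pred,
       confusion = confusion,
       chi2 = list(statistic = stat, df = df,
                   p_value = stats::pchisq(stat, df, lower.tail = FALSE)))
}

#' Power-spectrum feature matrix for decoding
#'
#' Flattens each participant's classification-image power spectrum into
#' one feature row (time domain: 13 frequencies; tf domain: 11 rows x 13
#' frequencies concatenated).
#'
#' @param cis List of raw-scale `classification_image` objects, one per
#'   participant, sharing a domain.
#' @return Numeric matrix, participants x features.
#' @export
spectrum_features <- function(cis) {
  rows <- lapply(cis, function(ci) as.vector(t(ci_power_phase(ci)$power)))
  do.call(rbind, rows)
}
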