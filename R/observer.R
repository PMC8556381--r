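#' Simulated observer with a latent temporal template
#'
#' A generative stand-in for a human participant: its probability of a
#' correct response on a trial is a logistic function of how well the
#' trial's sampling function matches a latent temporal sensitivity
#' template, `P(correct) = plogis(intercept + gain * <template, feature>)`,
#' with the feature being the trial's mean-centered SNR series (time
#' domain) or its Morlet amplitude map (tf domain). The intercept is
#' calibrated at simulation time so mean accuracy hits a target (50% by
#' default, the level the staircase holds human observers at).
#'
#' @param template Numeric weight vector over the 24 frames (time domain)
#'   or 11 x 24 matrix (tf domain), finite.
#' @param gain Nonnegative scalar scaling the template's influence;
#'   `gain = 0` gives a template-free observer responding at chance.
#' @param domain `"time"` or `"tf"`.
#' @param id,class Optional labels carried into simulated logs.
#' @return Object of class `observer_model`.
#' @export
observer_model <- function(template, gain = 1, domain = c("time", "tf"),
                           id = "obs", class = "none") {
  domain <- match.arg(domain)
  stopifnot(all(is.finite(template)), is.numeric(gain), gain >= 0)
  structure(list(template = template, gain = gain, domain = domain,
                 id = id, class = class), class = "observer_model")
}

#' Simulate a full experiment for one observer
#'
#' Draws `n_trials` independent sampling functions, computes each trial's
#' template match, calibrates the logistic intercept by root finding so
#' that the mean predicted accuracy over the drawn trials equals
#' `calibrate_to`, then draws Bernoulli accuracies. Noise level is held
#' fixed (the staircase is exercised separately by
#' [simulate_staircase()]); the log records the constant level.
#'
#' @param model An [observer_model()].
#' @param n_trials Number of trials (the reference experiment uses 1200).
#' @param spec A [basis_spec()].
#' @param calibrate_to Target mean accuracy in (0, 1).
#' @param noise_level Constant noise level recorded in the log.
#' @param n_cycles Morlet cycles (tf-domain observers).
#' @return An `experiment_log` data frame (see [read_trial_log()] for the
#'   column layout).
#' @export
simulate_dataset <- function(model, n_trials = 1200, spec = basis_spec(),
                             calibrate_to = 0.5, noise_level = 64,
                             n_cycles = 3) {
  stopifnot(inherits(model, "observer_model"), n_trials >= 1,
            calibrate_to > 0, calibrate_to < 1)
  d <- sample_functions(n_trials, spec)
  feats <- if (model$domain == "time") {
    sweep(d$values, 1L, rowMeans(d$values))  # center each trial's series
  } else {
    morlet_tf_batch(d$values, spec, n_cycles)
  }
  eta <- model$gain * drop(feats %*% as.vector(model$template))
  # calibrate the intercept: mean plogis(b + eta) is monotone increasing
  # in b, so the target is reachable iff it lies in (0, 1)
  f <- function(b) mean(stats::plogis(b + eta)) - calibrate_to
  lo <- -20 - max(abs(eta)); hi <- 20 + max(abs(eta))
  if (f(lo) > 0 || f(hi) < 0)
    stop("calibration failure: reachable mean accuracy range is (",
         signif(mean(stats::plogis(lo + eta)), 3), ", ",
         signif(mean(stats::plogis(hi + eta)), 3), ")")
  b <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  p <- stats::plogis(b + eta)
  acc <- stats::rbinom(n_trials, 1L, p)
  experiment_log(values = d$values, amplitudes = d$amplitudes,
                 phases = d$phases, accuracy = acc,
                 noise_level = rep(as.integer(noise_level), n_trials),
                 participant = model$id, class = model$class, spec = spec)
}

#' Synthesize a library of observers from class prototypes
#'
#' Instantiates the generative structure behind the package's synthetic
#' data: observers of the same stimulus class share a prototype power
#' spectrum of temporal sensitivity but carry idiosyncratic phases. Each
#' class gets a base phase vector; each observer's template is the inverse
#' transform of (sqrt(prototype power), base phase + jitter) over the
#' classification-image frequencies, so with `phase_jitter = 0` all
#' templates within a class coincide, while with large jitter they share
#' only their power spectrum.
#'
#' @param n_classes Number of stimulus classes (>= 2).
#' @param observers_per_class Observers per class (>= 2).
#' @param prototype_power Matrix `n_classes x length(spec$frequencies)` of
#'   nonnegative per-frequency power, one distinct row per class. Default:
#'   each class concentrates its power on a distinct band of two adjacent
#'   basis frequencies.
#' @param phase_jitter Standard deviation (radians) of the per-observer
#'   phase perturbation around the class base phase. The default `pi`
#'   makes phases effectively idiosyncratic.
#' @param gain Gain given to every observer (default 3, which at 1200
#'   trials and 50% accuracy supports reliable template recovery).
#' @param spec A [basis_spec()].
#' @return List of `observer_model` objects with `id` and `class` set.
#' @export
make_class_library <- function(n_classes = 4, observers_per_class = 12,
                               prototype_power = NULL, phase_jitter = pi,
                               gain = 3, spec = basis_spec()) {
  stopifnot(n_classes >= 2, observers_per_class >= 2)
  nf <- length(spec$frequencies)
  if (is.null(prototype_power)) {
    prototype_power <- matrix(0, n_classes, nf)
    for (cl in seq_len(n_classes)) {
      band <- ((2 * (cl - 1)) %% nf) + c(1L, 2L)
      band <- ((band - 1L) %% nf) + 1L
      prototype_power[cl, band] <- c(1, 0.5)
    }
  }
  stopifnot(nrow(prototype_power) == n_classes,
            ncol(prototype_power) == nf, all(prototype_power >= 0))
  if (any(duplicated(prototype_power)))
    warning("identical prototype power across classes: decoding will be at chance")
  models <- list()
  for (cl in seq_len(n_classes)) {
    base_phase <- stats::runif(nf, 0, 2 * pi)
    for (ob in seq_len(observers_per_class)) {
      phases <- base_phase + stats::rnorm(nf, 0, phase_jitter)
      tmpl <- drop(sqrt(prototype_power[cl, ]) %*%
                     sin(outer(2 * pi * spec$frequencies, spec$times) +
                           phases))
      models[[length(models) + 1L]] <-
        observer_model(tmpl, gain = gain, domain = "time",
                       id = sprintf("c%02d_o%02d", cl, ob),
                       class = sprintf("class%02d", cl))
    }
  }
  models
}
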