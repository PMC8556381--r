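#' Build an experiment log from simulated trials
#'
#' Assembles the canonical per-participant trial table: one row per trial
#' with the 24 SNR values, the 11 construction amplitudes and 11 phases of
#' the sampling function, the binary response accuracy and the white-noise
#' contrast level.
#'
#' @param values,amplitudes,phases Matrices with one row per trial
#'   (`n x 24`, `n x 11`, `n x 11` under the default spec).
#' @param accuracy Integer 0/1 vector, one per trial.
#' @param noise_level Integer vector (or scalar) of noise contrast levels.
#' @param participant,class Identifier strings stamped on every row.
#' @param spec A [basis_spec()].
#' @return Data frame of class `experiment_log`.
#' @export
experiment_log <- function(values, amplitudes, phases, accuracy,
                           noise_level = 64L, participant = "obs",
                           class = "none", spec = basis_spec()) {
  n <- nrow(values)
  stopifnot(nrow(amplitudes) == n, nrow(phases) == n, length(accuracy) == n)
  df <- data.frame(participant = participant, class = class,
                   trial = seq_len(n), accuracy = as.integer(accuracy),
                   noise_level = as.integer(noise_level))
  df[snr_cols(spec)] <- values
  df[amp_cols(spec)] <- amplitudes
  df[pha_cols(spec)] <- phases
  validate_trial_log(df, spec)
}

validate_trial_log <- function(df, spec = basis_spec()) {
  required <- c("participant", "class", "trial", "accuracy", "noise_level",
                snr_cols(spec), amp_cols(spec), pha_cols(spec))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("trial log is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!(df$accuracy %in% c(0L, 1L)))
  if (length(bad) > 0L)
    stop("non-binary accuracy value in row ", bad[1L], " (value ",
         df$accuracy[bad[1L]], ")")
  snr <- as.matrix(df[, snr_cols(spec)])
  out <- which(snr < -1e-9 | snr > 0.5 + 1e-9, arr.ind = TRUE)
  if (nrow(out) > 0L)
    stop("SNR outside [0, 0.5] in row ", out[1L, 1L], ", column ",
         snr_cols(spec)[out[1L, 2L]])
  class(df) <- c("experiment_log", "data.frame")
  df
}

#' Read or write a trial log
#'
#' Trial logs are stored as plain CSV so they stay portable and diffable.
#' Reading validates the schema and value ranges with errors naming the
#' offending column or row; a write followed by a read reproduces the log
#' (numeric values round-trip through full-precision text).
#'
#' @param path File path.
#' @param spec A [basis_spec()] describing the expected column layout.
#' @return `read_trial_log` returns an `experiment_log`;
#'   `write_trial_log` returns `path` invisibly.
#' @export
read_trial_log <- function(path, spec = basis_spec()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_log(df, spec)
}

#' @param log An `experiment_log`.
#' @rdname read_trial_log
#' @export
write_trial_log <- function(log, path) {
  df <- as.data.frame(log)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# one deterministic sub-seed per pipeline stage, kept within 32-bit range
derive_seed <- function(master_seed, stage) {
  offsets <- c(simulate = 1L, analyze = 2L, contrast = 3L, decode = 4L,
               report = 5L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master_seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

#' Read a run configuration
#'
#' Configurations are YAML key-value files; absent keys fall back to the
#' package defaults (the reference experiment's settings).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L,
    frequencies = seq(5, 55, by = 5),
    duration = 0.200,
    refresh_rate = 120,
    sum_target = 6.0,
    sum_tol = 0.05,
    n_trials = 1200,
    n_classes = 4L,
    observers_per_class = 12L,
    phase_jitter = pi,
    gain = 3,
    calibrate_to = 0.5,
    n_boot = 1000L,
    fwhm_time = 0.6,
    fwhm_tf = 1.5,
    fwhm_fourier = 0,
    alpha = 0.05,
    staircase_levels = 128L,
    staircase_step = 16L,
    n_cycles = 3
  )
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0L)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  if (cfg$alpha <= 0 || cfg$alpha > 0.5) stop("alpha must be in (0, 0.5]")
  cfg$spec <- basis_spec(cfg$frequencies, cfg$duration, cfg$refresh_rate)
  class(cfg) <- "run_config"
  cfg
}

# short deterministic fingerprint of a configuration, stamped on artifacts
config_fingerprint <- function(config) {
  flat <- config[setdiff(names(config), "spec")]
  txt <- paste(names(flat),
               vapply(flat, function(x)
                 paste(format(x, digits = 15), collapse = ","), ""),
               sep = "=", collapse = ";")
  ints <- utf8ToInt(txt)
  sprintf("cfg%08x", sum(ints * (seq_along(ints) %% 97 + 1)) %% 2147483647)
}

fwhm_for <- function(config, domain)
  switch(domain, time = config$fwhm_time, tf = config$fwhm_tf,
         fourier = config$fwhm_fourier)

write_matrix_csv <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run a full analysis workflow stage
#'
#' Drives the package end to end from a configuration, writing artifacts
#' under `out_dir`. Stages:
#' \describe{
#'   \item{simulate}{Build the synthetic class library and write one trial
#'     log per observer under `logs/`.}
#'   \item{analyze}{Per participant and domain (time, fourier, tf):
#'     bootstrap-Z classification images under `ci/`; per class and
#'     domain: group results (smoothed Z, critical Z, significance mask)
#'     under `group/`.}
#'   \item{contrast}{All pairwise class contrasts in the time and tf
#'     domains under `contrast/`.}
#'   \item{decode}{Leave-one-out class decoding from time-domain
#'     classification-image power spectra; result in `decode.json`.}
#'   \item{report}{Human-readable summary of all artifacts in
#'     `report.txt`.}
#' }
#' Every stage derives its own seed from the master seed by a fixed rule,
#' so any stage re-run with the same configuration is bit-reproducible.
#' Stages consume artifacts of earlier stages and signal an error naming
#' the missing prerequisite if run out of order.
#'
#' @param config A [read_run_config()] list.
#' @param command One of `"simulate"`, `"analyze"`, `"contrast"`,
#'   `"decode"`, `"report"`.
#' @param out_dir Artifact directory (created if needed).
#' @return Invisibly, a list describing the artifacts written.
#' @export
run_pipeline <- function(config, command = c("simulate", "analyze",
                                             "contrast", "decode", "report"),
                         out_dir = ".") {
  command <- match.arg(command)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$spec
  info <- list(command = command, seed = derive_seed(config$seed, command))
  set.seed(info$seed)

  log_dir <- file.path(out_dir, "logs")
  ci_dir <- file.path(out_dir, "ci")
  group_dir <- file.path(out_dir, "group")

  if (command == "simulate") {
    dir.create(log_dir, showWarnings = FALSE)
    library <- make_class_library(config$n_classes, config$observers_per_class,
                                  phase_jitter = config$phase_jitter,
                                  gain = config$gain, spec = spec)
    files <- character(0)
    for (m in library) {
      log <- simulate_dataset(m, config$n_trials, spec,
                              calibrate_to = config$calibrate_to)
      f <- file.path(log_dir, paste0(m$id, ".csv"))
      write_trial_log(log, f)
      files <- c(files, f)
    }
    info$files <- files
  }

  if (command == "analyze") {
    logs <- list.files(log_dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(logs) == 0L)
      stop("no trial logs found in ", log_dir, "; run the simulate stage first")
    dir.create(ci_dir, showWarnings = FALSE)
    dir.create(group_dir, showWarnings = FALSE)
    per_class <- list()
    for (f in logs) {
      log <- read_trial_log(f, spec)
      pid <- log$participant[1L]
      cls <- log$class[1L]
      for (domain in c("time", "fourier", "tf")) {
        ci <- bootstrap_z(log, domain, spec, n_boot = config$n_boot,
                          n_cycles = config$n_cycles)
        base <- file.path(ci_dir, paste0(pid, "_", domain))
        write_matrix_csv(as.matrix(ci$values), paste0(base, ".csv"))
        jsonlite::write_json(list(participant = pid, class = cls,
                                  domain = domain, scale = "z",
                                  n_boot = config$n_boot,
                                  seed = info$seed, config = config_fingerprint(config)),
                             paste0(base, ".json"), auto_unbox = TRUE)
        per_class[[cls]][[domain]][[pid]] <- ci
      }
    }
    for (cls in names(per_class)) {
      for (domain in names(per_class[[cls]])) {
        gr <- group_pipeline(per_class[[cls]][[domain]],
                             fwhm = fwhm_for(config, domain),
                             alpha = config$alpha)
        base <- file.path(group_dir, paste0(cls, "_", domain))
        write_matrix_csv(as.matrix(gr$mean_z), paste0(base, "_z.csv"))
        write_matrix_csv(as.matrix(gr$mask), paste0(base, "_mask.csv"))
        jsonlite::write_json(list(class = cls, domain = domain,
                                  z_crit = gr$z_crit, alpha = gr$alpha,
                                  fwhm = gr$fwhm,
                                  n_participants = gr$meta$n_participants,
                                  n_significant = sum(gr$mask != 0),
                                  seed = info$seed, config = config_fingerprint(config)),
                             paste0(base, ".json"), auto_unbox = TRUE)
      }
    }
    info$classes <- names(per_class)
  }

  if (command %in% c("contrast", "decode")) {
    logs <- list.files(log_dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(logs) == 0L)
      stop("no trial logs found in ", log_dir, "; run the simulate stage first")
  }

  if (command == "contrast") {
    cis <- gather_cis(log_dir, spec, config, scale = "z",
                      domains = c("time", "tf"))
    con_dir <- file.path(out_dir, "contrast")
    dir.create(con_dir, showWarnings = FALSE)
    classes <- sort(names(cis))
    for (domain in c("time", "tf")) {
      for (i in seq_along(classes)) for (j in seq_along(classes)) {
        if (i >= j) next
        gr <- contrast_classification_image(cis[[classes[i]]][[domain]],
                                            cis[[classes[j]]][[domain]],
                                            fwhm = fwhm_for(config, domain),
                                            alpha = config$alpha,
                                            n_boot = config$n_boot)
        base <- file.path(con_dir, paste0(classes[i], "_vs_", classes[j],
                                          "_", domain))
        write_matrix_csv(as.matrix(gr$mean_z), paste0(base, "_z.csv"))
        write_matrix_csv(as.matrix(gr$mask), paste0(base, "_mask.csv"))
        jsonlite::write_json(list(a = classes[i], b = classes[j],
                                  domain = domain, z_crit = gr$z_crit,
                                  n_significant = sum(gr$mask != 0),
                                  seed = info$seed, config = config_fingerprint(config)),
                             paste0(base, ".json"), auto_unbox = TRUE)
      }
    }
  }

  if (command == "decode") {
    cis <- gather_cis(log_dir, spec, config, scale = "raw",
                      domains = "time")
    feats <- NULL
    labels <- character(0)
    for (cls in sort(names(cis))) {
      feats <- rbind(feats, spectrum_features(cis[[cls]][["time"]]))
      labels <- c(labels, rep(cls, length(cis[[cls]][["time"]])))
    }
    res <- decode_loo(feats, labels)
    jsonlite::write_json(list(accuracy = res$accuracy,
                              confusion = as.data.frame(res$confusion),
                              chi2 = res$chi2, seed = info$seed, config = config_fingerprint(config)),
                         file.path(out_dir, "decode.json"),
                         auto_unbox = TRUE, digits = NA)
    info$accuracy <- res$accuracy
  }

  if (command == "report") {
    lines <- c("tempsamp run report", strrep("=", 19), "")
    gj <- list.files(group_dir, pattern = "\\.json$", full.names = TRUE)
    if (length(gj) == 0L)
      stop("no group results found in ", group_dir,
           "; run the analyze stage first")
    for (f in gj) {
      g <- jsonlite::read_json(f)
      lines <- c(lines, sprintf(
        "%s [%s]: z_crit = %.3f, %d significant point(s), n = %d",
        g$class, g$domain, g$z_crit, g$n_significant, g$n_participants))
    }
    dj <- file.path(out_dir, "decode.json")
    if (file.exists(dj)) {
      d <- jsonlite::read_json(dj)
      lines <- c(lines, "", sprintf(
        "decoding accuracy = %.3f (chi2 = %.2f, df = %d, p = %.4g)",
        d$accuracy, d$chi2$statistic, d$chi2$df, d$chi2$p_value))
    }
    writeLines(lines, file.path(out_dir, "report.txt"))
    info$report = file.path(out_dir, "report.txt")
  }

  invisible(info)
}

# recompute classification images for every log, grouped by class
gather_cis <- function(log_dir, spec, config, scale, domains) {
  logs <- list.files(log_dir, pattern = "\\.csv$", full.names = TRUE)
  out <- list()
  for (f in logs) {
    log <- read_trial_log(f, spec)
    cls <- log$class[1L]
    for (domain in domains) {
      ci <- if (scale == "z")
        bootstrap_z(log, domain, spec, n_boot = config$n_boot,
                    n_cycles = config$n_cycles)
      else raw_classification_image(log, domain, spec, config$n_cycles)
      out[[cls]][[domain]] <- c(out[[cls]][[domain]], list(ci))
    }
  }
  out
}
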