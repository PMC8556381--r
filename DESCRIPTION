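Package: tempsamp
Title: Random Temporal Sampling and Classification-Image Analysis for
    Visual Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probing oscillatory visual mechanisms with random
    temporal sampling. Generates per-trial oscillating signal-to-noise
    sampling functions (sums of 5-55 Hz sinusoids with random amplitudes
    and phases, range-normalized and sum-matched), composes stimulus frame
    sequences and runs the adaptive white-noise contrast staircase,
    simulates observers with known temporal templates, and implements the
    full classification-image analysis chain: reverse-correlation images
    in the time, Fourier and time-frequency (complex Morlet wavelet)
    domains, bootstrap Z-scoring, Gaussian smoothing, random-field-theory
    (Pixel test) significance thresholds, spectral decomposition,
    between-subject agreement via intraclass correlation, and stimulus-class
    decoding with linear support vector machines.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
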