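---
title: "Random temporal sampling: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random temporal sampling: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempsamp)
```

## The method in brief

Random temporal sampling probes *when*, and at which *temporal
frequencies*, a visual stimulus is effectively encoded. On every trial a
target image is displayed for 200 ms on a 120 Hz display (24 frames), but
its signal-to-noise ratio (SNR) oscillates over those frames according to
a random **sampling function**: the sum of sinusoids at 5--55 Hz (in 5 Hz
steps) with random amplitudes and phases. Because the sampling function is
random and independent across trials, the covariation of its shape with
response accuracy reveals the observer's temporal sensitivity profile.
This covariation is summarized by a **classification image**: the mean
feature vector of the sampling functions on correct trials minus the mean
on error trials, computed in three codings of the same functions:

* **time domain** -- SNR as a function of time since target onset (24 points);
* **Fourier domain** -- the 11 construction amplitudes and 11 phases;
* **time--frequency domain** -- the modulus of the convolution with
  three-cycle complex Morlet wavelets, an 11 x 24 grid.

Raw classification images are converted to Z scores with a bootstrap null,
averaged across participants, Gaussian-smoothed, and thresholded with a
random-field-theory criterion (the *Pixel test*) so that the family-wise
rate of false significant points is 0.05 two-ways.

## The sampling-function generator

`make_sampling_function()` draws amplitudes i.i.d. uniform(0, 1) and
phases i.i.d. uniform(0, 2$\pi$) per basis frequency. These are
maximal-entropy choices on the natural supports; nothing in the method
constrains them further, and the classification-image logic is agnostic to
the amplitude prior as long as draws are independent across trials.

The waveform is evaluated at frame midpoints $t_k = (k + 0.5)/120$ s: a
frame is displayed for a whole refresh interval, so its midpoint is the
unbiased representative time. Conveniently, every basis frequency
completes an integer number of cycles over the 200 ms window, so the
discrete Fourier transform at the basis frequencies recovers the
construction amplitudes and phases exactly (`fourier_descriptors()`).

Two normalizations are applied, in this order:

1. **Range**: the waveform is affinely mapped so its minimum is exactly 0
   and its maximum exactly 0.5. The signal weight therefore never exceeds
   the noise weight.
2. **Sum matching**: the frame sum must fall within $\varepsilon = 0.05$
   of the target $S^* = 6.0$; draws that miss are rejected and redrawn
   (budget 10 000 per accepted function).

$S^* = 6$ is the empirical mean frame sum of unconstrained
range-normalized draws ($24 \times 0.25$; the range-normalized values are
symmetric around 0.25), so rejection keeps the accepted distribution as
close as possible to the unconstrained one. About 4% of candidates are
accepted under these defaults, which makes the rejection cost negligible.
Range normalization is applied first because the exact $[0, 0.5]$ range is
a hard constraint of the stimulus composition, while the sum is matched
only to a tolerance; the opposite order could not guarantee both. Flat
(degenerate) draws carry no sampling information and are redrawn rather
than clamped.

## Stimulus composition and the staircase

`compose_frames()` builds frame $k$ as $w_k \cdot \mathrm{signal} + (1 -
w_k) \cdot \mathrm{noise}$ with $w_k$ the sampling function's SNR value.
The *signal* is the target blended with a white-noise mask whose contrast
is one of 128 staircase-controlled levels (level 1 is a null mask); the
*noise* is an independent maximal-contrast white-noise field; both fields
are drawn fresh each trial. "Signal-to-noise ratio" is implemented as the
signal *weight* itself (the noise weight being its complement): a literal
ratio bounded by 0.5 induces the same ordering of frames, and the weight
form keeps every pixel inside the displayable range.

After blending, all frames are equalized to a common mean luminance and
RMS contrast (the first frame's values). Equalization rescales each
frame's deviations around its mean; if any pixel would leave $[0, 1]$, the
contrast of *all* frames is backed off by one common factor, which
preserves the cross-frame match exactly rather than clipping (clipping
would silently break the per-frame mean equality).

The staircase starts at level 64 (the integer midpoint of 128 levels under
1-based numbering) with step 16. From trial 11 onward, the mean accuracy
of the 10 immediately preceding trials -- a sliding window, recomputed
every trial, which is the literal reading of "the 10 preceding trials" --
moves the level down when accuracy is below 0.5, up when above, and not at
all at exactly 0.5. The step halves at every direction reversal down to a
floor of 1, and the state persists across blocks. For any observer whose
accuracy decreases monotonically in noise contrast this converges to the
50% point; `simulate_staircase()` demonstrates it with a logistic
psychometric function spanning the 128 levels (slope 12 levels, threshold
at the midpoint -- a gradual, realistic psychometric; convergence is
insensitive to the exact slope).

## Morlet time-frequency maps

`morlet_tf()` uses complex Morlet kernels with $\sigma_t = n_{\mathrm{cycles}}
/ (2 \pi f)$ and $n_{\mathrm{cycles}} = 3$, sampled at the display rate
over $\pm 4 \sigma_t$ and normalized to unit energy so magnitudes are
comparable across frequencies. The series is treated as zero outside the
24-frame window; because convolution with a finite kernel under zero
padding is a linear map, the implementation precomputes one exact
$24 \times 24$ complex operator per frequency (equivalent to padding to at
least three kernel lengths and cropping, with no frame discarded). The
output is the coefficient *amplitude* by default -- classification-image
subtraction is linear in the coded feature, and amplitude keeps units
interpretable -- with squared-modulus power available via a flag. Edge
frames integrate less signal and no cone-of-influence mask is applied;
three-cycle kernels are spectrally broad, so a pure oscillation also
drives neighboring frequency rows. Both properties are inherent to the
transform and are left visible in the maps.

## Bootstrap Z and the group pipeline

`bootstrap_z()` keeps the observed accuracy labels fixed as a multiset and
pairs them with sampling functions resampled with replacement from the
log (1000 iterations by default). This preserves the observed accuracy
rate in every null iteration, which a full label permutation would also do
but a label *resampling* would not; resampling the functions rather than
permuting labels is the closest reading of random reassignment "while
allowing for repetition". The observed raw image is Z-scored against the
mean and SD of the null images point by point.

`group_pipeline()` combines participants' Z images as a Stouffer sum --
the mean multiplied by $\sqrt{n}$ -- rather than a plain mean. Under the
null each participant's Z image has unit variance, so the plain mean would
have variance $1/n$ and a threshold calibrated for a unit-variance field
would never fire; the Stouffer scaling is the combination rule that keeps
the group image unit-variance, and with it the empirical family-wise rate
matches the nominal alpha (verified by simulation in the test suite).

Smoothing uses a normalized Gaussian kernel (FWHM 0.6 bins in the time
domain, 1.5 bins in the time--frequency domain; the Fourier-domain vector
of 22 discrete descriptors is left unsmoothed) with half-sample reflective
boundaries -- the resulting operator is doubly stochastic, so the image
mean is preserved exactly and edge bins are not attenuated. Because
smoothing shrinks a unit-variance field's pointwise variance, each point
is restandardized by the operator's exact row norm afterwards; for
independent Gaussian input this restores unit variance exactly, including
at the boundary.

`contrast_classification_image()` Z-scores the difference of two group
means against a participant-level bootstrap under group-label exchange:
participants are pooled (in a canonical value-sorted order, so the null is
invariant to which group is called A), pseudo-groups of the original sizes
are resampled, and the null scale is the root mean square of the resampled
differences -- a symmetrized estimate centered at zero. The raw difference
is exactly antisymmetric in the group order; with equal group sizes the
whole mask flips sign exactly.

## The Pixel test

`pixel_threshold()` returns the smaller of two valid family-wise bounds on
the maximum of a smoothed unit-variance Gaussian field: the expected Euler
characteristic of the excursion set (with boundary resel terms, solved by
bisection) and the Bonferroni bound over the lattice points. The minimum
of two valid bounds is itself valid, and which bound wins depends on
smoothness: at FWHM 0.6 bins the lattice is effectively independent and
Bonferroni is both tighter and accurate, while at several bins of FWHM the
Euler-characteristic bound wins and tends to the single-test Gaussian
quantile. The choice was validated by simulation rather than trusted: on
20 000 simulated smoothed null fields the empirical family-wise rate is
within $\pm 0.01$ of 0.05 for both geometries the pipeline uses (24 bins at
FWHM 0.6; 11 x 24 bins at FWHM 1.5). Smoothness is passed explicitly --
the pipeline knows its own filter -- and never estimated from residuals.

## The simulated-observer generator

Real observers' responses arise from mechanisms this package cannot
observe; the synthetic generator instead *instantiates the structure the
analysis is meant to detect*, so every stage can be tested against known
ground truth. An `observer_model()` responds correctly with probability
$\mathrm{logit}^{-1}(b + g \langle \tau, x \rangle)$, where $x$ is the
trial's mean-centered SNR series (or its Morlet map), $\tau$ a latent
temporal template, and $g$ a gain. The logistic link is the simplest
monotone response rule with a calibratable operating point; $b$ is found
by root-finding at simulation time so that mean accuracy hits 50%, the
level the staircase holds humans at. The staircase itself is exercised
separately (`simulate_staircase()`); coupling it to the template observer
would entangle two mechanisms that are cleaner to test apart.

`make_class_library()` builds observers in classes: all members of a class
share a prototype *power* spectrum over the classification-image
frequencies but receive idiosyncratic phases (base class phase plus
Gaussian jitter, default dispersion $\pi$, i.e. effectively idiosyncratic).
Templates are the inverse transform of (square root of prototype power,
per-observer phase). This is the generative embodiment of the method's
central empirical structure -- power spectra of classification images that
are stable across observers while raw images and phase spectra are not --
and the analysis chain recovers exactly that dissociation from the
synthetic data (ICC of recovered power spectra above 0.9, of raw images
below 0.3, in the test suite). Default library geometry: 4 classes of 12
observers, 1200 trials each, accuracy calibrated to 50% -- the reference
experiment's layout. The default gain of 3 makes the template's projection
variance roughly unit scale, which at 1200 trials supports reliable
recovery (median correlation with the planted template about 0.97) while
keeping single-trial predictability modest; it was fixed once at that
value when the generator was written.

What the generator does *not* emulate: image-computable responses (features
are sampling functions, not pixels), reaction times, learning or fatigue
across the session, and any dependence of accuracy on the staircase level
during template simulation. Passing tests therefore show that the analysis
chain recovers the structure it assumes, not that human data contain that
structure.

## Agreement and decoding

`icc()` implements the two-way *consistency, average-measures* form,
ICC(3,k) $= (MS_T - MS_E)/MS_T$, with raters = participants and targets =
image points. This form is bounded above by 1 and has no lower bound,
which identifies it among the Shrout--Fleiss cases (single-measures forms
are bounded below by $-1/(k-1)$); the absolute-agreement form ICC(2,k) is
exposed as an option. Confidence intervals use the F distribution
(consistency) or the McGraw--Wong approximation (agreement).

`decode_loo()` predicts a participant's stimulus class from their
classification-image power spectrum with a linear SVM (one-vs-one
multiclass, cost 1), leave-one-out over participants, standardizing
features with training-fold statistics only. For time--frequency images
the 11 per-row spectra are concatenated into one feature vector.
Significance against chance uses the chi-square test of independence on
the predicted-versus-true table, whose $(k-1)^2$ degrees of freedom match
the reference analysis with four classes. The mixed-factor ANOVAs on
spectra are out of scope as computation; the spectra serialize to the tidy
long format those models need.

## Numerical choices and degenerate inputs

* Phases are wrapped to $(-\pi, \pi]$; zero-amplitude components report
  phase 0.
* Bootstrap SDs of exactly zero (constant features) raise an error naming
  the degenerate points rather than producing infinite Z.
* The DFT power convention is one-sided (interior bins scaled $2/n$, DC
  and Nyquist $1/n$), so an integer-cycle sinusoid of amplitude $a$ has
  power $a^2$ at its bin; an impulse is flat across interior bins.
* All randomness flows through R's session RNG; every pipeline stage
  derives a fixed sub-seed from the master seed, so runs are
  bit-reproducible from the configuration alone.
* Logs are plain CSV with full-precision (`%.17g`) numerics -- a
  write/read round trip is exact.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to make
Monte-Carlo error small relative to the tolerance being checked while
staying desk-scale: 20 000 simulated null fields for threshold
calibration, 5000 full null experiments (12 participants x 300 trials) for
the end-to-end family-wise rate, 10 000 draws for generator distributional
checks, 1200 trials (the reference count) for template recovery, and 50
sessions of 1200 trials for staircase convergence. Classification-image
recovery and decoding checks use 600--1200 trials per observer and 6--12
observers per class.

## Known limitations

* The Pixel test is point-wise (max-statistic); no cluster-extent
  inference is offered.
* The Euler-characteristic bound is only trusted where simulation confirms
  it; geometries far rougher than one resel per bin fall back to
  Bonferroni by construction.
* The Fourier-domain classification image subtracts mean phases linearly;
  with strongly non-uniform phase distributions a circular statistic would
  be preferable.
* Real-data headline quantities (participant ICCs, 75%/52% decoding rates)
  depend on undeposited human data and are not reproduced; the package
  validates structure, calibration and recovery on synthetic data instead.
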