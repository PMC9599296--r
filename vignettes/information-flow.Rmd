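---
title: "Directed information flow, dominant coupling modes and lifespan indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed information flow, dominant coupling modes and lifespan indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docmflow)
```

## The analysis in one paragraph

Given multichannel regional electrophysiological recordings (source-space
MEG/EEG time courses, or the synthetic stand-ins this package generates),
docmflow quantifies *directed* coupling between every pair of regions, within
and between six canonical rhythms — delta (1–4 Hz), theta (4–8), alpha1
(8–10), alpha2 (10–13), beta (13–30) and gamma (30–45 Hz) — separately for
amplitude dynamics (delay symbolic transfer entropy, dSTE, on Hilbert
envelopes vector-quantized with a Neural-Gas codebook) and phase dynamics
(histogram-based phase transfer entropy, PTE, and its normalization dPTE).
Three levels of statistics (surrogate nulls per mode; Bonferroni selection of
the dominant coupling mode, DoCM, among the 21 candidates per pair and 4-s
epoch; network-level FDR per epoch) reduce the 21 × epochs × R × R candidate
space to one dominant mode per pair and epoch. Mode occurrences, normalized
to probabilities, form a 6 × 6 comodulogram; contrasts of its within-band and
cross-band probabilities define a frequency-dependent brain age index (fBAI)
whose age trajectory is summarised by two-segment Gaussian fits; direction
indices averaged over posterior and anterior region sets give the
posterior–anterior index (PAI); graph-diffusion-distance and delay-stability
criteria filter unstable epochs.

## Signal preparation

Regional series are band-passed per rhythm with a zero-phase
forward–backward 4th-order Butterworth filter. Filter transients are
suppressed by reflecting one second of signal onto each end before
filtering and discarding it afterwards, so no recording samples are consumed
and a 5-minute recording still yields exactly 75 non-overlapping 4-second
epochs. The analytic signal (FFT construction) provides the envelope and the
instantaneous phase on the *continuous* band-passed series, which is epoched
only afterwards — computing the Hilbert transform per epoch would add edge
artifacts to every window.

When voxel-level series are available for a region, `roi_representative()`
collapses them by functional interpolation: the absolute Pearson correlation
between all voxel pairs defines per-voxel strengths (row sums of the
correlation matrix, self-correlations excluded — including the constant
diagonal would only shift all strengths equally), which are normalized to
unit-sum weights; the representative series is the weighted voxel average.
Independent component series can be screened with the artifact rule: a
component is flagged when more than 20% of its z-scored values fall outside
(−2, 2) — exactly 20% is not flagged.

## Symbolic encoding (amplitude domain)

Both envelopes of a pair are delay-embedded, stacked, and quantized by a
common Neural-Gas codebook. The Neural-Gas updates are rank-based soft-max
competitive learning with exponentially annealed neighbourhood width
(k/2 → 0.01) and learning rate (0.5 → 0.005) over 100·k adaptation steps,
codes initialized from random data rows under the run seed. The accepted
codebook is the smallest k on an ascending grid whose normalized distortion
(total quantization error over total dispersion) is below 5%; if no k
qualifies the fit signals an error, or returns the best-achieved codebook
when the caller opts in (`on_fail = "best"`, used by the pipeline where a
fixed small k is preferred for comparability). Embedding parameters can be
selected by the minimal one-step prediction error of a local-constant
(nearest-neighbour-mean) predictor over a (m, tau) grid, with ties broken to
the smallest pair.

## Directed estimators

`dste()` is the plug-in transfer entropy over symbol triplets
(target future, target past, source delayed by d samples), log base 2. The
plug-in estimate is exact relative to a brute-force triple-loop enumeration
(the test suite asserts equality). `pte()` bins instantaneous phases into
`round(exp(0.626 + 0.4 log(Ns − delta − 1)))` equal bins and applies the same
plug-in machinery; `dpte()` normalizes the two directions to [0, 1] with 0.5
meaning no preferred direction; `direction_index()` is the common
(f_ij − f_ji)/(f_ij + f_ji) normalization in [−1, 1].

The PTE prediction step matters: at a few hundred samples per second,
adjacent phase samples almost always fall in the same histogram bin, and a
one-sample step carries no directional information. The pipeline therefore
sets the analysis step per mode to half the mean period of the two rhythms
involved (about 14 samples for alpha1 at 128 Hz); `pte()` itself defaults to
delta = 1 for transparency.

## Surrogate statistics

Three null constructions are used, chosen to be calibrated on the data these
estimators actually see:

* **dSTE**: random circular time shifts of the source symbol sequence. A
  full element permutation destroys the source's autocorrelation and is
  dramatically anti-conservative on smooth envelope symbol sequences (98%
  false positives at the 5% level in our null simulations, versus 6.7% for
  rotations); rotations break the source–target alignment while preserving
  the source's own dynamics. The permutation variant remains available
  (`method = "permute"`).
* **dPTE**: mismatched-epoch pairings — dPTE between epoch i of one region
  and epoch j ≠ i of the other. Per-epoch observed values are compared
  against the raw surrogate values (this is what the DoCM layer consumes);
  the pair-level pooled p-value compares the epoch-*mean* observed dPTE
  against *means of epoch-sized surrogate groups*, since averaging the
  observed statistic but not the null would discard essentially all power.
  When more surrogates are requested than the E² − E admissible pairings,
  pairings are resampled with replacement so that enough group means exist
  for small p-values.
* **p-value conventions**: standalone tests default to the smoothed
  (1 + c)/(1 + N) convention, which can never return zero. The DoCM layer
  uses the plain exceedance proportion c/N: its Bonferroni threshold
  0.01/21 ≈ 4.8 × 10⁻⁴ is below the smallest smoothed p-value attainable
  with any practical surrogate count, so attainability requires the
  proportion convention.

Within the pipeline's amplitude domain, per-epoch surrogate values are
centred by their own epoch's null mean before pooling across epochs (epochs
differ in baseline transfer entropy; pooling uncentred nulls would force
every epoch to beat the worst epoch's baseline). The per-epoch statistic is
the preferred-direction strength max(dSTE_ab, dSTE_ba), maximised over a
small set of candidate delays: zero-phase filtering smears the lagged
dependence symmetrically in time, so a single delay underestimates it.

## Dominant coupling modes

For each pair and epoch, the 21 candidate modes (6 within-band, 15
cross-band with the slower band as modulator, ordered delta–theta …
beta–gamma) are tested at the Bonferroni-corrected level p < 0.01/21.
Scenario A: one survivor is the DoCM. Scenario B: several survivors — the
one with the highest strength wins, with ties broken toward the lowest mode
id. Scenario C: none — mode 0 and zero strength. Scenario-B strengths are
surrogate-normalized (z-scores against each mode's own null) so that modes
with different baseline TE levels compare fairly. Benjamini–Hochberg FDR at
q = 0.01 is then applied across all pairs within each epoch's network, and
the surviving assignments populate the [21 × epochs × R × R] strength /
identity / lag tensors.

Four-second epochs carry limited evidence, so the package additionally pools
each pair's per-epoch z-scores (`docm_pool()`: mean z times sqrt(E) against
the normal upper tail, same Bonferroni correction) into one pair-level DoCM.
Comodulograms default to counting these pooled pair-level modes
(`comodulogram_from = "pairs"`); counting the raw epoch-level tensor is
available as well. A practical detection floor is worth stating plainly:
rhythms whose band is only 2–3 Hz wide (alpha1, alpha2) produce envelopes
with a correlation time of ~0.3–0.5 s, i.e. only a handful of independent
fluctuations per 4-s epoch, and per-epoch transfer entropy involving them as
the modulated band sits below the surrogate floor at desk-scale sampling
rates. Recovery tests therefore plant modes whose bands are at least 3 Hz
wide; this is a property of the epoch length and estimator, not of the
implementation.

## Time-lag scan

The coupling delay of a pair is located by maximising delayed mutual
information between the two symbol sequences over a grid of signed lags
(positive: the first series drives; negative: the second). Mutual
information is symmetric in time, so its peak sits at the centre of the
lagged dependence. The delayed *conditional* transfer entropy was evaluated
as the scan statistic first and rejected: it keys on the leading edge of the
dependence, which zero-phase (acausal) band-pass and envelope smoothing
advances by roughly the envelope correlation half-width, producing a
systematic offset of several samples (a delayed-copy toy process confirms
the estimator itself is unbiased; envelope cross-correlation provides the
ground-truth centre). The profile maximum is z-scored against the profile's
mean and standard deviation, and its p-value uses max-statistics: every
surrogate (circular source rotation) is scanned over a strided version of
the same lag grid and its maximum retained, so the selection step is part of
the null — without this the best-lag p-value is anti-conservative. The
directed estimators, each maximised over the strided grid, supply the
bounded direction index; the raw profile value is reported un-normalized.
Phase-domain lags of narrowband rhythms are identifiable only up to integer
multiples of the carrier period; delay recovery is therefore validated in
the amplitude domain.

## Lifespan indices

`pai()` contrasts the average direction index over posterior versus anterior
region sets, in percent of the posterior mean; positive values mean
posterior-to-anterior flow. Significance comes from permuting the per-region
averages across regions (1000 permutations, two-sided). The optional
normalization of per-region values by their maximum before the contrast is
off by default. Region membership is fully configurable; the synthetic
cohort labels its first half posterior.

`fbai()` is the ratio of the within-band dominant-mode probability PD(k, k)
to the mean cross-band probability over k's modulated set (all strictly
faster bands; gamma never modulates). Both orientations are available: the
default places the within-band probability in the numerator, `invert = TRUE`
returns the reciprocal (the cross-over-within orientation, which rises to an
adult peak when cross-frequency coupling peaks — the orientation used for
age-trajectory recovery).

`fit_bai_curve()` fits, separately below and above the 30-year split, the
candidate family (linear, quadratic, quadratic through the origin, log,
exponential, Gaussian non-centered / centered (xo = 0) / area-normalized
(amplitude tied to 1/(sigma sqrt(2 pi))), von Bertalanffy with and without
intercept) by least squares and ranks by the coefficient of determination;
non-converging candidates are excluded. The three-parameter Gaussian
a·exp(−(x − xo)²/(2 sigma²)) is always reported and drives `predict()`.
Model *identification* under noise requires the curve to be identifiable:
when the Gaussian peak and both shoulders fall inside a segment the true
model wins the R-ranking in ≥95% of noisy simulations, whereas a Gaussian
limb that is locally parabolic over the segment is statistically
indistinguishable from a quadratic at 5% noise — the model-selection
simulations use identifiable curves, and the parameter-recovery simulations
use the broader (locally parabolic) magnitudes seen in adult cohorts.

## Stability and reliability

`gdd()` maximises over diffusion time the Frobenius distance between the
heat kernels exp(−tL) of the two networks' Laplacians (symmetrized weights;
the directed matrix is retained by the caller), scanning 20 log-spaced times
in [1e−2, 1e1] with local refinement. Null networks preserve each node's
in/out degree exactly (directed edge swaps) and its strengths within 1%
(multiplicative row/column repair, which preserves the zero pattern).
`stability_cv()` is the mean-over-SD of a pair's delays across epochs — the
*inverse* of the conventional coefficient of variation, named accordingly;
values above 10 with a significant one-tailed t-test indicate a consistent
latency, and a zero SD counts as perfectly stable. `reject_epochs()` flags
an epoch when (a) more than half of its pairwise graph distances are joint
z > 2 outliers and (b) it is the deviant epoch (>2 SD from the pair mean) in
more than 10% of region pairs failing the delay criterion. Test–retest
sessions are compared by rank-sum tests on GDD and delay-stability values,
and a subject's brain-age index enters the session average only when both
sessions lie within 0.02 of the reference fitted curve at the subject's age.

## The synthetic cohort

The generator emulates the study conditions every downstream stage assumes:
5-minute recordings (configurable) at 256 Hz default; each region a sum of
six band-limited filtered-noise carriers plus white noise; directed
couplings planted as

* **amplitude**: the target-band carrier is multiplied by
  exp(strength/2 · z), where z is the standardized source envelope delayed
  by the coupling delay (an exponential gain is positive and monotone at any
  strength; an additive gain clips at zero and saturates),
* **phase, within-band**: delayed Kuramoto-style pulling of the target phase
  toward the source phase,
* **phase, cross-band**: pulling toward the nearest harmonic of the delayed
  source phase (n:m locking) — plain frequency forcing by sin(source phase)
  is undetectable by phase TE after band re-filtering at these scales,

with the frequency deviation capped at 40% of the target bandwidth so the
entrained carrier survives re-filtering. Band delays default to 80, 45, 28,
24, 18 and 15 ms from delta to gamma (decreasing with frequency, matching
the magnitudes reported for cortical interactions). Ages spread uniformly
over 18–65; the per-subject fraction of cross-band plants follows a Gaussian
age profile peaking at 28 years (base 0.2, amplitude 0.6, SD 15 — a fast
climb from adolescence to an adult peak followed by slow decline); couplings
in the gradient bands always run posterior → anterior.

What the generator does *not* emulate: sensor physics, beamformer leakage
and volume conduction (no zero-lag mixing between regions), 1/f background
spectra, artifacts, or inter-subject variability beyond the age profile.
Passing recovery tests therefore demonstrate estimator correctness and
calibration on well-posed ground truth, not robustness to leakage — on real
source-reconstructed data, zero-lag leakage is the dominant additional
confound and is deliberately out of scope here.

## Problem sizes used by the test-suite simulations

Pair-level fixtures use 128 Hz (256 Hz for dominant-mode recovery), 12–120 s
of signal, 4-s epochs, codebooks of 4–16 symbols, embeddings m = 3 with
tau = 1–3, and 100–3000 surrogates; cohort smoke tests use 2 subjects, 3–4
regions and 24–48 s. These sizes were chosen as the smallest at which the
statistical behaviour under test (calibration bands, recovery rates) is
stable across seeds. Full-scale settings (78 regions, 75 epochs, 21 modes,
two estimators — 9,459,450 estimator evaluations per subject) are reported
by `pipeline_counts()` and are intended for cluster-scale runs.

## Known limitations

* Per-epoch detection power at 4-s epochs is modest; pair-level pooling
  (`docm_pool()`) is the recommended basis for comodulograms at desk scale.
* Modes whose modulated band is narrower than ~3 Hz are effectively
  undetectable per epoch at desk-scale sampling rates (see above).
* Phase-domain delay estimates are period-ambiguous for narrowband rhythms.
* Cross-band dPTE carries a band-asymmetry bias (its null is not centred on
  0.5); the epoch-shuffle null absorbs it, but raw dPTE values of cross-band
  pairs should not be read as direction without that reference.
* The pipeline estimates one lag per pair and mode (from the concatenated
  epochs) rather than one per epoch, trading the paper-scale lag tensors for
  desk-scale runtime; per-epoch lags are available by calling `lag_scan()`
  on epoch slices directly.
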