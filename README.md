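# docmflow

Directed information flow and dominant coupling modes for regional
electrophysiological time series, with lifespan summaries.

## What problem this solves, and for whom

Resting-state MEG/EEG source activity is rhythmic in six canonical bands —
δ (1–4 Hz), θ (4–8), α1 (8–10), α2 (10–13), β (13–30), γ (30–45) — and brain
regions exchange information both within a rhythm and across rhythms (the
slower rhythm modulating the faster one). For researchers studying
effective (directed) connectivity, this package answers, for every region
pair and 4-second epoch: *which* coupling mode (one of 6 within-band + 15
cross-band candidates) dominates, in *which direction*, with *what strength*
and *what time delay* — separately for amplitude dynamics and phase
dynamics — and turns those answers into interpretable summaries
(comodulograms, a posterior–anterior index, age-grouped time delays, and a
brain age index with two-segment Gaussian trajectories).

## The estimators at the core

**Delay symbolic transfer entropy** (amplitude domain). Both envelopes of a
pair are delay-embedded, quantized with a shared Neural-Gas codebook (the
smallest k with normalized distortion < 5%), and the plug-in transfer
entropy over symbol triplets is computed with an explicit source→target
delay d:

    dSTE_BA(d) = Σ p(a_{t+1}, a_t, b_{t+1-d}) log2 [ p(a_{t+1} | a_t, b_{t+1-d}) / p(a_{t+1} | a_t) ]

**Delay phase transfer entropy** (phase domain). The same plug-in machinery
on instantaneous phases, binned into round(exp(0.626 + 0.4·ln(Ns − δ − 1)))
histogram bins, normalized to dPTE = PTE_xy / (PTE_xy + PTE_yx) ∈ [0, 1]
(0.5 = no preferred direction). Both estimators share the direction index
Δ = (f_ij − f_ji)/(f_ij + f_ji) ∈ [−1, +1].

**Dominant coupling modes.** Per pair and epoch, surrogate nulls (circular
source rotations for dSTE, mismatched-epoch pairings for dPTE) give each of
the 21 candidate modes a p-value; the Bonferroni survivor (p < 0.01/21) with
the highest surrogate-normalized strength is the DoCM; Benjamini–Hochberg
FDR (q = 0.01) filters each epoch's network. Counts of DoCM occurrences,
normalized, form the 6×6 comodulogram (sums to one), and for a modulating
band k the frequency-dependent brain age index contrasts its within-band
probability with the mean over its modulated set.

## Worked example

Plant a single δ→δ amplitude coupling at 80 ms between two synthetic
regions, then recover its delay, direction and significance:

```r
library(docmflow)

cp <- coupling_spec(source_roi = 1, target_roi = 2, source_band = "delta",
                    target_band = "delta", domain = "amplitude",
                    delay_ms = 80, strength = 1.5)
pair <- make_coupled_pair(fs = 128, duration = 90, coupling = cp,
                          noise_sd = 0.2, seed = 1)

be <- band_epoch(rbind(pair$x, pair$y), fs = 128)   # filter + Hilbert + epochs
env_x <- as.numeric(t(be$amplitude[1, 1, , ]))      # delta envelopes
env_y <- as.numeric(t(be$amplitude[2, 1, , ]))

scan <- lag_scan(env_x, env_y, fs = 128, estimator = "dste",
                 lag_grid = seq(-30, 30), n_surr = 100, seed = 1,
                 m = 3, tau = 1, k_grid = 12)
```

which prints (via the summary line below):

    best lag: 70.3 ms (planted 78.1 ms), p = 0.0099, direction index = 0.21

i.e. the scan finds the planted delay to within one sample (the 80 ms plant
rounds to 78.1 ms at 128 Hz; 70.3 ms is 9 samples vs. the planted 10), the
positive lag and direction index say region 1 drives region 2, and the
best-lag statistic beats all 100 max-statistic surrogates. Fitting the
two-segment age trajectory of a brain age index:

```r
x   <- seq(18, 60, by = 1)
bai <- 1.45 * exp(-(x - 28.5)^2 / (2 * 15.8^2)) + rnorm(length(x), 0, 0.02)
fit_bai_curve(x, bai)
#> Two-segment brain-age-index fit (split at 30 years)
#>   below 30: best gaussian  R = 0.975 | Gaussian a = 1.44, sigma = 17,   xo = 28.8 (R = 0.975)
#>   above 30: best gaussian  R = 0.998 | Gaussian a = 1.43, sigma = 15.3, xo = 29.3 (R = 0.998)
```

The Gaussian wins the model selection on both segments and recovers the
generating parameters (a = 1.45, σ = 15.8, xo = 28.5) within the noise. For
a full cohort, `make_cohort()` + `run_pipeline()` produce per-subject DoCM
tensors, comodulograms, PAI and fBAI tables and cohort-level curve fits; see
the vignette in `vignettes/information-flow.Rmd` for the methods and their
assumptions.

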