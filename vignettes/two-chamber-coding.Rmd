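---
title: "Sparse coding and stimulus-site decoding on two-chamber MEAs"
author: "meacode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse coding and stimulus-site decoding on two-chamber MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meacode)
```

## The experimental system

Dentate gyrus (DG) and CA3 neurons can be co-cultured in two chambers of a
PDMS device placed over an 8 x 8 micro-electrode array, connected only by
micro-tunnels that admit axons but not somata. The array monitors 22
electrodes per chamber and 15 in-tunnel electrodes grouped into 8 tunnels;
every chamber electrode can also deliver stimulation. Paired-pulse stimuli
(two biphasic pulses 50 ms apart, repeated 25 times at each of 22 sites per
chamber, with a 5 s wait between pairs) evoke time-locked activity whose
spatial pattern in the *opposite* chamber carries information about which
site was stimulated. `meacode` implements the full analysis chain for such
experiments — spike detection, evoked-rate extraction, sparseness and
specificity statistics, and stimulation-site decoding — plus a synthetic
generator so that every stage can be validated against known ground truth.

## Pipeline overview

1. **Preprocessing** (`remove_stim_artifact()`, `estimate_noise_sd()`,
   `detect_spikes()`): raw 25 kHz voltage traces are corrected for the
   exponential stimulus artifact, blanked for 5 ms after each pulse, and
   scanned with a peak-to-peak threshold detector.
2. **Evoked rates** (`count_trial_spikes()`, `rate_matrix()`): spikes are
   counted in the 40 ms window beginning 5 ms after each pulse, pooled over
   both pulses and 25 trials, and divided by the total counted time
   (25 x 80 ms = 2 s), giving a site x electrode spike-rate matrix.
3. **Coding statistics** (`kurtosis_sparseness()`, `uniqueness_curve()`,
   `loglog_correlation()`): how sparse is the target representation, how
   specific is it for each stimulation site, and how tightly does tunnel
   transmission follow the source region's aggregate drive.
4. **Decoding** (`decode_experiment()`): a linear support vector machine
   classifies single trials by stimulation site, over all (or a capped
   random sample of) site subsets of size k, against the 1/k chance level.

## Spike detection

Detection follows the peak-to-peak scheme standard for dense MEA
recordings. A differential threshold of 8 x the baseline-noise SD is
applied per channel, with a 2 ms peak lifetime and a 1 ms refractory
period. Several details are deliberately pinned down because the scheme
itself leaves them open:

* **Noise SD estimator.** The "standard deviation of the baseline noise"
  is estimated by the median absolute deviation scaled to the Gaussian SD.
  MAD is the standard robust choice in spike detection: sparse large
  spikes move a plain SD by tens of percent but the MAD by almost nothing.
* **Windowing.** The peak-to-peak excursion is evaluated in a *sliding*
  (not tiled) window of one peak lifetime; an event is placed at the
  absolute extremum of any window whose excursion exceeds threshold. A tie
  between equal positive and negative extrema resolves to the earlier
  sample, making detection fully deterministic.
* **Refractoriness.** Candidate events closer than the refractory period
  merge keeping the earlier one; consecutive reported events are therefore
  separated by at least the refractory period.
* **Blanking is structural.** Samples within 5 ms of a pulse are flagged
  invalid: they can neither contribute to a window's excursion nor carry
  an event. No post-filtering is involved, mirroring the fact that the
  amplifier is genuinely saturated there.

The stimulus artifact is modelled per pulse as `A * exp(-t / tau) + C` and
fit by Levenberg-Marquardt least squares (with tau parameterised on the
log scale for positivity) on the 40 ms window that starts where blanking
ends — artifact amplitudes have decayed to near baseline by 40-45 ms. Only
the exponential component is subtracted, so the channel's DC level is
untouched. A fit that fails to converge leaves that pulse uncorrected and
is reported in the result rather than silently ignored.

## Evoked-rate conventions

* Counting windows are half-open, `[pulse + 5 ms, pulse + 45 ms)`, so a
  spike on a boundary is counted exactly once; boundaries are evaluated on
  the 1 microsecond grid of the event-table format.
* The two windows of a pair are pooled: the denominator of the spike-rate
  matrix is `trials x 80 ms` (exactly 2 s at 25 trials). Per-pulse
  resolution is available through `compute_psth()` for inspection.
* The stimulated electrode is masked (`NA`) in within-region matrices —
  its amplifier is saturated — and masked cells propagate as missingness,
  never as zero rate.
* Of the two electrodes in a tunnel, the one with the larger mean rate
  over stimulation sites is kept (better axon-electrode coupling); an
  exact tie keeps the lower electrode id.
* An electrode is *active* when its maximum rate over sites strictly
  exceeds 1.5 Hz. The maximum (rather than the mean) is used because the
  criterion gates electrodes "activated by at least one stimulation
  site"; a sparsely driven electrode would be lost under a mean rule.
* Baseline activity is estimated two ways, matching the two natural
  controls: pooled 5 ms pre-trigger windows before every pair, and a
  pre-protocol spontaneous segment (180 s by default). On synthetic data
  the two agree within sampling error, which the test suite asserts.

## The kurtosis sparseness index

For target electrode $i$, let $SR_{i,j}$ be its rate for stimulation site
$j$, and $\mu_i$, $\sigma_i$ the mean and SD of those rates across sites.
The sparseness index is

$$K = \frac{1}{N_e}\sum_{i=1}^{N_e}\left[\frac{1}{N_{stim}}
\sum_{j=1}^{N_{stim}}\left(\frac{SR_{i,j}-\mu_i}{\sigma_i}\right)^4 - 3\right]$$

Two numerical choices deserve emphasis:

* **Placement of the "-3".** The subtraction is applied per electrode,
  inside the average. The defining property of the index — zero for
  Gaussian-distributed rates — only holds under this placement; applying
  a single "-3" outside the electrode average would instead converge to
  $3 - 3/N_e$ for Gaussian data. The test suite pins the Gaussian null to
  $|K| < 0.1$ at $N_{stim} = 10{,}000$.
* **Moment-form SD.** $\sigma_i$ divides by $N_{stim}$, not
  $N_{stim}-1$, consistent with the moment normalisation of the inner sum.

Electrodes with zero rate variance leave the standardisation undefined;
they are excluded, $N_e$ is reduced accordingly, and the count of excluded
electrodes is reported. Masked cells are excluded from the per-electrode
moments.

## Uniqueness curves

For a selection depth $n$, an adjacency matrix marks, per stimulation
site, the electrodes holding the $n$ highest rates; electrodes tied with
the $n$-th value are *all* marked (ties are equally represented, so a row
may carry more than $n$ marks). The uniqueness of electrode $i$ with
column sum $s_i$ is

$$U_i = \begin{cases} 0 & s_i = 0\\ 1 - \dfrac{s_i - 1}{N_{stim} - 1} &
s_i > 0\end{cases}$$

and the regional uniqueness $\%U = 100 \cdot \bar U$ averages over all
$N_e$ electrodes, zeros included. Sweeping $n = 1..N_e$ yields the
uniqueness curve; its peak (smallest $n$ attaining the maximum) is the
number of most-active target electrodes that optimally specifies a
stimulation site. Two zero policies are provided:

* **Including zeros**: zero rates rank and tie like any other value. As
  $n \to N_e$ every electrode ends up marked for every site and the curve
  falls to an asymptote of zero.
* **Excluding zeros**: zero-rate electrodes are never marked, even when
  that leaves fewer than $n$ marks. Once $n$ exceeds each site's count of
  nonzero rates the adjacency stops changing and the curve plateaus.

Masked cells are treated as absent in the ranking (saturation is
missingness, not silence). Both policies are verified, on random small
matrices with forced ties and zeros, against a brute-force implementation
written independently from the defining formulas.

## Decoding

Features are raw per-trial evoked-count vectors over the target-region
electrodes — no normalisation, matching a pure rate-code readout. For a
subset of $k$ candidate sites, trials are split stratified per site
(floor(0.8 x trials) train, i.e. 20/5 at 25 trials), a linear-kernel SVM
is trained, and test accuracy is recorded; `decode_experiment()` sweeps
all subsets up to a cap of 26,334 — the full count of $\binom{22}{5}$ —
beyond which distinct subsets are sampled uniformly.

Design decisions here:

* **What is a "subset"?** Subsets are of stimulation *sites* (the
  classes); features always use all target electrodes. This is the only
  reading consistent with chance levels of 1/k (50, 20, 10, 7% for
  k = 2, 5, 10, 15) and with the $\binom{22}{k}$ subset counts. An
  electrode-subset mode would condition on features instead and has no
  1/k chance interpretation, so the site reading is the default.
* **Classifier.** The linear-kernel SVM with default parameters is libsvm
  (via `e1071::svm`): C = 1, one-vs-one multiclass, no feature scaling
  (`scale = FALSE`). These are the defaults of the library family this
  analysis ecosystem standardises on, rather than a tuned choice;
  no hyper-parameter search is performed anywhere.
* **Reproducibility.** Each subset's stratified split is seeded by a hash
  of the master seed and the subset members, so single subsets can be
  re-run in isolation and whole experiments are bit-reproducible.
* **Null calibration.** `permute_labels = TRUE` permutes site labels
  before the split; the resulting mean accuracy must sit at 1/k, and the
  test suite holds the k = 5 null to within 2 percentage points of 20%
  over 200 subsets.

## The synthetic generator

`synth_config()` encodes the study conditions as defaults: 22 sites per
chamber, 25 trials, 50 ms inter-pulse interval, 5 s inter-pair wait,
baseline rates 22.2 Hz (DG) and 11.2 Hz (CA3), evoked rates 86.5 and
55.7 Hz, and 84% DG-to-CA3 directionality. Ground truth is drawn once per
seed; everything downstream is deterministic given the config.

Structure of the generated code:

* **Within-region** responses are broad: every electrode of the
  stimulated chamber is driven at its regional evoked rate, with a
  mean-preserving log-normal dispersion (sdlog 0.25) across
  (site, electrode) pairs.
* **DG to CA3** is sparse and specific: each DG site drives exactly
  `sparseness_m` CA3 electrodes (default 4, within the 3-6 range such
  arrays show), drawn with a configurable overlap between sites'
  responsive sets (default 0.25). Responsive amplitudes are *graded*,
  log-normal with sdlog 0.7 around the regional evoked mean: evoked rates
  on real arrays span decades (rate matrices are displayed on log scales),
  and a graded, tail-dominated amplitude distribution is also what makes
  the kurtosis index respond monotonically to `sparseness_m` — a
  two-level on/off code would make intermediate sparseness bimodal, where
  kurtosis is no longer informative.
* **CA3 to DG** is broader (twice `sparseness_m` electrodes by default)
  and weaker: the drive above baseline scales by
  `(1 - directionality)/directionality` (about 0.19 at the default 0.84),
  so the reverse direction carries less information, as anatomy predicts.
* **Tunnels** carry a noisy scaled copy of the source region's aggregate
  drive (mass action). A per-site excitability factor (log-normal,
  sdlog 0.5, normalised to mean 1 so regional means stay calibrated)
  spreads the sites' overall drive; against the small tunnel noise
  (sdlog 0.15) this produces the high source-tunnel log-log correlation
  of the native direction, while the sparse CA3 map — which deliberately
  does not scale with site excitability — stays uncorrelated with tunnel
  throughput.
* **Counts are Poisson** around the ground-truth means, per trial and
  window. Poisson is the maximum-entropy default for counts; no claim is
  made about the true trial-noise law of cultured networks.
* **Event tables.** Evoked event times are placed uniformly within the
  two counting windows, which keeps the event-level and count-level views
  of an experiment exactly consistent (an early-latency placement at
  2-5 ms would fall inside the blanking window and silently break that
  consistency). Spontaneous background is generated where the pipeline
  can see it: a pre-protocol segment (default 180 s) for the spontaneous
  baseline estimator and the 10 ms before each pair for the pre-trigger
  estimator. The silent 5 s inter-pair gaps are not populated — they
  would add millions of events that no analysis stage reads.
* **Raw traces** add Gaussian noise of configurable SD, a biphasic 1 ms
  spike template with 10 x SD peak-to-peak amplitude (comfortably above
  the 8 x SD threshold) whose absolute extremum sits at the event time,
  and an exponential artifact at every pulse.

What the generator does **not** emulate: biophysical membrane dynamics,
synaptic plasticity across trials (response extinction or facilitation),
bursts, electrode impedance variation, or correlated (non-Poisson)
trial-to-trial variability. Passing tests therefore demonstrate that the
pipeline recovers planted structure under idealised variability, not that
real recordings satisfy these assumptions.

## Problem sizes and test design

The package validates itself at sizes chosen to keep the full suite in
the low minutes on a single core while retaining statistical power: full
22-site/25-trial protocols for rate realism, chance calibration (200
subsets) and direction comparisons (20 replicate networks); compressed
protocols (2-6 sites, 5-10 trials, 0.5 s waits) wherever only structure
matters; 10,000 stimulation sites for the Gaussian kurtosis null; and
brute-force oracle comparisons on matrices up to 6 x 6, where exhaustive
reimplementation from the defining formulas is transparent.

## Known limitations

* The artifact model is a single exponential per pulse; ringing or
  double-exponential tails would leave residuals (failed fits are
  reported, not hidden).
* Uniqueness averages over all 22 target electrodes, including inactive
  ones — restricting to active electrodes would shift the curve upward;
  the all-electrode convention follows the defining average over $N_e$.
* Decoding uses rate features only; latency (temporal-code) features are
  out of scope.
* `n_combinations()` is exact; note that the full count of
  $\binom{22}{15}$ is 170,544 — occasionally misprinted as 170,554.
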