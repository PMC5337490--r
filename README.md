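# meacode

Analysis of information transmission between two co-cultured neural
populations — dentate gyrus (DG) and CA3 — connected by axonal
micro-tunnels over a 60-electrode array (MEA60). Paired-pulse stimulation
at 22 sites per chamber (25 trials, 50 ms inter-pulse interval) evokes
spatial response patterns in the opposite chamber; `meacode` quantifies how
**sparse** those patterns are, how **specific** they are for each
stimulation site, and how well they **decode** the site's identity. It is
aimed at electrophysiologists analysing paired-chamber MEA experiments and
at modellers who need a tested, fully synthetic reference pipeline.

## What it computes

Starting from raw 25 kHz traces (or pre-detected spike events) plus a
stimulation log and an electrode layout:

* **Spike detection** — peak-to-peak threshold at 8 × the baseline-noise
  SD (MAD-estimated), 2 ms peak lifetime, 1 ms refractory, with
  exponential stimulus-artifact subtraction (`A e^{-t/τ} + C` per pulse)
  and a structural 5 ms post-pulse blanking window.
* **Evoked spike-rate matrices** — spikes in `[pulse + 5 ms, pulse + 45 ms)`
  pooled over both pulses and 25 trials, divided by the 2 s of counted
  time; rows are stimulation sites, columns electrodes; the stimulated
  electrode is masked. Includes tunnel-electrode selection (keep the
  stronger of each pair), a strict 1.5 Hz activity criterion, two baseline
  estimators, and PSTHs.
* **Kurtosis sparseness index** —
  `K = (1/Ne) Σ_i [ (1/Nstim) Σ_j ((SR_ij − μ_i)/σ_i)⁴ − 3 ]`,
  zero for Gaussian-distributed rates; large when electrodes are driven
  hard by few sites and quiet otherwise.
* **Uniqueness curves** — per selection depth n, an adjacency matrix marks
  the n highest rates per site (ties expand; zeros either rank or are
  excluded); electrode uniqueness is `1 − (s−1)/(Nstim−1)` for column sum
  s, averaged into a regional `%U(n)`; the curve's peak gives the number
  of most-active electrodes that optimally specifies a stimulus site.
* **Stimulation-site decoding** — linear SVM on raw per-trial count
  vectors, stratified 80/20 split, over all site subsets of size k (capped
  at 26,334 = C(22,5), sampled uniformly beyond), against the 1/k chance
  level, with a permuted-label null.
* **Synthetic experiments** — `synth_config()` / `generate_ground_truth()`
  emulate the study conditions (baseline 22.2/11.2 Hz, evoked
  86.5/55.7 Hz, a sparse site-specific DG→CA3 map of 3–6 electrodes,
  84% directionality, Poisson trial noise, optional raw traces with spike
  templates and artifacts) with every planted structure recoverable.

## Worked example

```r
library(meacode)

layout <- mea_layout()                      # 22 DG + 22 CA3 + 15 tunnel electrodes
cfg    <- synth_config(seed = 42)           # full 22-site x 25-trial protocol
truth  <- generate_ground_truth(cfg)
sim    <- simulate_trial_counts(truth)

sr  <- rate_matrix(sim$counts$dg)           # stimulation in DG
ca3 <- region_rates(sr, layout, "CA3")      # responses in the target chamber

kurtosis_sparseness(ca3)
#> <kurtosis_result> K = 7.302 over 22 electrodes (0 degenerate excluded)

uniqueness_curve(ca3, "include_zeros")
#> <uniqueness_curve> include_zeros: peak %U = 90.5% at n = 3 (of 22)

tun <- select_tunnel_electrode(region_rates(sr, layout, "TUNNEL"), layout)
dg  <- region_rates(sr, layout, "DG")
loglog_correlation(rowMeans(dg, na.rm = TRUE), rowMeans(tun))
#> <loglog_correlation> r = 0.99 (p = 3.91e-19, n = 22, 0 dropped)
loglog_correlation(rowMeans(ca3), rowMeans(tun))
#> <loglog_correlation> r = 0.34 (p = 0.123, n = 22, 0 dropped)

ten <- trial_count_tensor(unclass(sim$counts$dg)[, , colnames(ca3)])
decode_experiment(ten, k = 5, max_subsets = 100, seed = 1)
#> <decoding_result> k = 5: mean accuracy 94.8% over 100 subsets (chance 20.0%, +74.8 points)
decode_experiment(ten, k = 5, max_subsets = 100, seed = 1, permute_labels = TRUE)
#> <decoding_result> k = 5: mean accuracy 19.2% over 100 subsets (chance 20.0%, +-0.8 points)
```

Reading the numbers: the high kurtosis (K ≈ 7) says CA3 electrodes are
strongly driven by few DG sites — a sparse code. The uniqueness curve
peaks at n = 3: the three most active CA3 electrodes per site specify the
stimulation site best. Source (DG) activity tracks tunnel transmission
almost perfectly on log-log axes (mass action), while the sparse CA3
pattern does not. The SVM identifies the stimulated site far above the
20% chance level, and collapses to chance when labels are permuted — the
decoded information is real, not an artifact of the protocol.

A thin command-line front end over the same functions is included at
`inst/scripts/meacode-cli.R` (subcommands `simulate`, `detect`, `rates`,
`coding`, `decode`).

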