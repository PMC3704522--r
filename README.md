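# CaMAM

Quantification of sarcoplasmic-reticulum (SR) calcium handling and
mitochondrial plasticity in cultured myotubes. The package covers the three
measurement families such studies report, plus the statistics used to compare
groups:

- **Calcium-transient kinetics** from Fluo-4 fluorescence traces after
  caffeine application: response latency, time to peak, amplitude, maximal
  rise rate (ΔF/ΔT), and the 25/50/90 % clearance times t₂₅, t₅₀, t₉₀ with
  right-censoring when a recording ends before recovery completes.
- **Mitochondrial morphometry and SR contacts**: per-mitochondrion 2-D size
  (length × width, via minimum-area enclosing rectangles on segmented
  images, or from EM-style measurement tables), a rule-based fused-network
  classifier, and the SR:mitochondrial contact-site frequency — the ratio of
  mitochondria lying within a contact distance of SR to all mitochondria
  scored.
- **Line-scan colocalization**: dual-channel intensity profiles along a
  segment (e.g. Tom20 vs PDI) with their Pearson correlation.
- **Group statistics**: unpaired two-tailed Student's t-test (pooled
  variance), one-way ANOVA, and the two-sided Fisher's exact test, with
  mean ± SE group summaries and censoring-aware exclusion counts.

Because such microscopy data are rarely deposited, the package ships
synthetic generators with exact ground truth — an idealized transient
(baseline, latency, linear rise, single-exponential recovery), EM-style
object tables, and two-channel rod/blob images — so the entire pipeline is
testable end to end.

## The transient model

A noiseless trace follows

```
F(t) = F0                                 t <  t_on
F(t) = F0 + s·(t − t_on)                  t_on ≤ t < t_peak
F(t) = F0 + A·exp(−(t − t_peak)/τ)        t ≥  t_peak
```

with `t_on = t_app + latency`, `t_peak = t_on + riseDuration` and amplitude
`A = s·riseDuration`. Every reported metric has a closed form: ΔF/ΔT = s,
and the clearance times are `t_q = τ·ln(1/(1−q))` (so t₅₀ = τ·ln 2,
t₉₀ = τ·ln 10). The analysis never uses the ground truth; it measures the
sampled, noisy trace and is validated against the closed forms.

## Worked example

```r
library(CaMAM)

## a fused-phenotype transient: late onset, steep rise, slow clearance
tr <- simulateTrace(baselineF0 = 500, tApp = 30, latency = 14,
                    riseSlope = 245, riseDuration = 9,
                    decayTau = 114 / log(2), noiseSd = 45, seed = 1)
round(unlist(analyzeTransient(tr)[c("response_time_s", "time_to_peak_s",
  "amplitude_fau", "max_rate_fau_per_s", "t25_s", "t50_s", "t90_s")]), 2)
#>    response_time_s     time_to_peak_s      amplitude_fau max_rate_fau_per_s
#>              14.42              10.08            2257.70             266.67
#>              t25_s              t50_s              t90_s
#>              40.62             108.25             345.50
```

The analysis recovers the generating parameters from the noisy trace: a
14 s caffeine response time, ~10 s to peak, an amplitude near the true
2205 fau, ΔF/ΔT near the true 245 fau/s, and t₅₀ near the true 114 s.

```r
## EM-style morphometry: control vs rapidly stimulated myotubes
ctrl <- simulateEMObjects(50, 0.2, 0.4, 0.15, 0.25, contactFraction = 0.04, seed = 2)
efs5 <- simulateEMObjects(50, 0.8, 1.0, 0.6, 0.8,  contactFraction = 0.94, seed = 3)
sizeStats(ctrl)$meanSize2d   #> 0.060  (um^2)
sizeStats(efs5)$meanSize2d   #> 0.626  (um^2)
contactSites(ctrl)           #> 2 / 50 within 30 nm  (frequency 0.040)
contactSites(efs5)           #> 47 / 50 within 30 nm (frequency 0.940)
fisherExact(matrix(c(2, 48, 47, 3), 2, byrow = TRUE))
#> Fisher exact (two-sided), statistic = 0.003193, p = 4.867e-22
```

A tenfold size difference and a 4 % vs 94 % contact frequency are exactly
the kind of contrast the contact-site Fisher test resolves (p ≪ 0.001).

`runPipeline(pipelineConfig(), demoPipelineSpec())` chains the stages —
simulate, analyze, summarize, test — and writes a metrics CSV plus a JSON
report; identical config and seed give byte-identical outputs.

## Documentation

The methods vignette (`vignettes/camam-methods.Rmd`) describes the transient
model and its assumptions, every tunable threshold with its default and
rationale, what the synthetic generators do and do not emulate, numerical
conventions, and known limitations.
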