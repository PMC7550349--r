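# oflphys

Simulation and analysis pipeline for two-phase **observational fear learning
(OFL)** experiments with electrodermal and startle-EMG outcome measures.

In this paradigm an *observer* watches a *demonstrator* undergo differential
fear conditioning: one conditioned stimulus (CS+) is paired with an aversive
shock (US) on half of its presentations, the other (CS−) never is. In the
subsequent *direct expression* (DE) phase the observer faces the CSs directly,
without shocks, so any differential responding must have been acquired
socially. The package implements everything needed to exercise that analysis
end to end without access to laboratory recordings:

* **Design generation** — pseudo-random CS sequences (no more than two
  repeats), 50% reinforcement with the first and last CS+ always reinforced,
  9 s CSs, 10–15 s intertrial intervals, a 0.8 s five-pulse shock train 7.5 s
  after CS+ onset, and startle probes on half the CSs (6.0/6.5/7.0 s onsets)
  and a quarter of the ITIs — exported as BIDS-style events tables.
* **Synthetic 2 kHz physiology** — EDA as tonic level + drift + Bateman-type
  biexponential SCR kernels with lognormal amplitude variability;
  orbicularis-oculi EMG as Gaussian baseline plus Hann-windowed band-limited
  startle bursts, with condition-dependent effect sizes that can be switched
  off subject-by-subject (contingency-aware vs unaware observers).
* **SCR scoring** — tonic/phasic decomposition (sparse non-negative driver
  deconvolution solved by proximal gradient, or a running-median fallback),
  trough-to-peak amplitude `max[0,6) − mean[−2,0)` s around stimulus onset,
  0.2 µS response floor, US trials scored only when probe-free, within-subject
  `log(1 + SCR/SCRmax)` normalization, condition means with zeros included,
  and the fewer-than-5-non-zero-DE-responses exclusion rule.
* **FPS scoring** — 28–500 Hz 4th-order Butterworth band-pass (zero-phase),
  rectification, 40 Hz FIR smoothing (delay-compensated), peak-minus-baseline
  magnitude in the 20–120 ms window after probe onset (floored at zero),
  within-subject T-scores (mean 50, sd 10), and the ≤5-non-zero-responses
  exclusion rule.
* **Contingency awareness** — classification from a coded questionnaire
  (forced choice correct *and* consistent with the rule report or the highest
  shock-probability rating), plus Likert rating summaries.
* **Group statistics** — paired *t* tests with Cohen's *d*, repeated-measures
  and mixed-design ANOVAs (Type III, sum-to-zero contrasts, partial η²,
  Greenhouse–Geisser ε reported for 3-level factors), Bonferroni post-hocs,
  and Kruskal–Wallis tests.

## Worked example

```r
library(oflphys)

report <- run_pipeline(pipeline_config(n_subjects = 35, seed = 2026))
#> simulating 35 observers (seed 2026)
#> classified 12/35 observers as contingency-aware
#> SCR: 30 analyzed, 5 excluded (< 5 non-zero DE responses)
#> FPS: 35 analyzed, 0 excluded

m <- report$scr$mixed_de
m[grepl(":", m$effect), c("statistic", "df1", "df2", "p", "effect_size")]
#>   statistic df1 df2            p effect_size
#>      89.31    1  28      3.3e-10        0.76
```

The pipeline simulates a cohort (each observer gets fresh OFL/DE timelines,
2 kHz EDA/EMG channels and questionnaire answers), scores both measures,
classifies awareness and runs the full analysis battery. In the run above the
DE-phase stimulus × contingency-awareness interaction on normalized SCRs is
recovered — contingency-aware observers respond more to the CS+ than to the
CS−, unaware observers do not — and the FPS phase effect (stronger startle in
DE than OFL, here 55.99 vs 47.00 T-score units, *d* = 3.76) comes out as
expected, because the synthetic generator injects exactly those effects.

The same run as a step-by-step workflow, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_design.R   # events tables + design summary
Rscript analysis/02_score_cohort.R      # simulate + score + classify (35 obs)
Rscript analysis/03_group_stats.R       # group-level statistics
```

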