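---
title: "Scoring and simulating observational fear learning psychophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and simulating observational fear learning psychophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical decisions
behind `oflphys`. The package covers a two-phase observational fear
conditioning experiment: an observational learning (OFL) phase in which the
observer watches a demonstrator receive shocks paired with one of two
conditioned stimuli, and a direct expression (DE) phase in which the observer
faces the stimuli without shocks. Outcome measures are the skin conductance
response (SCR) and the fear-potentiated startle (FPS) eyeblink reflex.

## Experimental design generation

`build_timeline()` generates one phase of the protocol:

* CS order is pseudo-random with at most two consecutive presentations of the
  same CS. The sampler is constructive with feasibility pruning — at each
  position it only considers labels from which a valid completion exists — so
  it never emits an invalid sequence and never dead-ends. It does not sample
  the valid orderings exactly uniformly (choice probabilities are proportional
  to remaining counts); for design generation uniformity is irrelevant, and
  the test suite verifies membership in the exhaustively enumerated valid set.
* Reinforcement: `round(ratio × n_CS+)` trials, ties-to-even (so 24 × 0.5 = 12
  exactly, and the behavior is defined for odd counts), always including the
  first and the last CS+ presentation.
* Intertrial intervals are uniform on 10–15 s. Every phase also starts with a
  lead-in fixation of one ITI draw so that the first trial has a pre-stimulus
  baseline window.
* Startle probes land on half of the CS trials. The protocol literature does
  not state a per-type balance, so the package balances exactly: equal probe
  counts on CS+ and CS−, because unbalanced probing would confound the FPS
  condition means. Within the CS+ trials, probes are additionally stratified
  over reinforced/unreinforced trials, and the ITI probes are stratified the
  same way — an ITI probe invalidates the preceding trial for US scoring, so
  without stratification the scoreable US and no-US trial counts would drift
  apart. Probe onsets on CS trials are drawn from {6.0, 6.5, 7.0} s; ITI probe
  onsets are uniform on 2.0–4.5 s after fixation onset, which the 10 s minimum
  ITI keeps clear of the next CS.
* The shock train is modeled as a single US event of five 1 ms pulses at
  200 ms latency; `us_train_duration()` reports its span (0.8 s at defaults)
  to one decimal, and the event starts 7.5 s after CS+ onset.

All event times are generated on a 1 ms grid — the resolution of a typical
stimulus-presentation timer — which makes the 3-decimal events TSV a lossless
serialization (verified by a byte-identity round-trip test). Time intervals
are half-open, `[onset, onset + duration)`, everywhere.

## Synthetic physiology

The generator (`synth_params()`, `render_eda()`, `render_emg()`) exists so the
entire scoring and inference chain can be exercised, with known ground truth,
on signals that share the statistical structure of real recordings.

**EDA.** Tonic level (5 µS) plus a slow linear drift (0.05 µS/min) plus white
Gaussian measurement noise (sd 0.01 µS), with event-locked SCRs superposed as
a peak-normalized biexponential (Bateman-type) kernel, rise τ = 0.75 s and
decay τ = 3.0 s, placed 1.5 s after event onset. With this latency the kernel
peak falls ≈2.9 s after stimulus onset, comfortably inside the 0–6 s scoring
window. Response amplitudes are lognormal around their condition mean with a
coefficient of variation of 0.4 — SCR amplitudes are non-negative and
right-skewed, so multiplicative rather than additive variability — and a CS
evokes no response at all with probability 0.1. Condition means (µS): observed
US 0.8 (never omitted — the social US reliably evokes a response in every
observer); OFL-phase CSs 0.15; DE-phase CS+/CS− 0.30/0.18 for aware observers
and 0.18/0.18 for unaware ones. The US response is attached to the US onset,
and an additional US-scale response is injected at the CS+ onset of reinforced
trials, so that a CS-anchored US scoring convention (see below) also sees the
reaction. The rendering kernel is renormalized to a discrete peak of exactly 1
on the sample grid, so an injected amplitude is recovered exactly at the peak
sample (the superposition and single-event tests assert this to 1e-9).

**EMG.** Gaussian baseline noise (sd 0.01 mV) plus one burst per startle
probe: white noise band-limited to 30–300 Hz (a realistic orbicularis-oculi
burst spectrum, inside the scorer's 28–500 Hz passband), Hann-windowed over
100 ms, starting 35 ms after probe onset. Each burst is calibrated so that its
rectified-and-smoothed envelope peak equals `phase gain × condition boost ×
lognormal(1, cv = 0.4)`; the calibration uses the same filter-rectify-smooth
definition as the scorer, so a noise-free burst scores within a few tenths of
a percent of its nominal gain. Phase gains: 0.10 mV (OFL) and 0.14 mV (DE) —
startle is globally potentiated when the observer expects shocks. Aware
observers additionally get boosts of 1.25 (CS+) and 1.15 (CS−) relative to
fixation in the DE phase; unaware observers and the OFL phase have all boosts
at 1.

**Questionnaire.** Aware observers produce a correct forced choice backed by a
correct rule report (60% of them) or by a uniquely-highest CS+ probability
rating; unaware observers produce one of three patterns (wrong forced choice,
inconsistent rule + ratings, or tied ratings), all of which the classifier
maps to unaware. Likert ratings of the demonstrator are drawn identically for
both groups around medians {6, 6, 8, 4, 7} — the generator encodes no group
difference, matching the observation that perception of the demonstrator does
not differ by awareness.

**What the generator does not emulate:** respiration and movement artifacts,
electrode drift and drop-outs, habituation of SCR or startle across trials,
inter-subject variability in kernel shape or burst latency, and any timing
jitter of the demonstrator's reaction (the observer's US-response latency is a
free parameter of the generator, fixed at the SCR latency, not inferred from
data). Passing the recovery suites therefore shows the pipeline is correct and
well-calibrated under the generative model, not that it is robust to every
artifact of laboratory recordings.

## SCR scoring

`decompose_eda()` separates tonic and phasic activity. The default
`convex_sparse` method models the phasic component as a non-negative sudomotor
driver convolved with the biexponential kernel and solves the L1-penalized
non-negative least-squares problem with FISTA (proximal gradient), followed by
an unpenalized refit on the recovered support to remove shrinkage bias. The
tonic baseline is a low-quantile estimate: the 25th percentile over 10 s
blocks, linearly interpolated, re-estimated once after the driver explains the
response bumps (a low quantile is insensitive to strictly-positive transients,
which is what keeps responses out of the baseline). The solve runs on a 10 Hz
grid — electrodermal activity is band-limited far below that — and components
are interpolated back to the recording rate; the driver/kernel non-negativity
makes the phasic component non-negative by construction. The
`highpass_baseline` fallback (running median minus signal, positive part) is a
documented approximation for quick work; both methods satisfy
`eda = tonic + phasic + residual` exactly.

Scoring follows the trough-to-peak convention: amplitude = max of the phasic
series over `[onset, onset + 6)` s minus its mean over `[onset − 2, onset)` s;
amplitudes below 0.2 µS (including negative differences) count as no response
(zero). The baseline is computed on the phasic component — the subtraction
exists to avoid scoring spontaneous fluctuations, which live in the phasic
component. Responses to the observed US are scored only on CS+ trials with no
probe during the CS *and* none in the following ITI (the conservative reading
of "no probes during and after"), with the identical window anchored at CS
onset; unreinforced CS+ trials are scored the same way as the no-US control.
Anchoring at CS onset rather than US onset is a documented choice — the
condition labels of the group analysis treat the US response as part of the
reinforced-CS+ trial — and the generator injects a CS-onset response on
reinforced trials so this convention has signal to find; US-onset anchoring
would be the one-line alternative.

Normalization is `log(1 + SCR/SCRmax)` with the natural logarithm (the base
only rescales all values by a constant, so every contrast is invariant to this
choice), where `SCRmax` is the subject's largest scored response across all
trials of both phases. Condition means include zeros. Subjects with fewer than
5 non-zero DE-phase responses are excluded ("less than 5": exactly 5 is kept).

## FPS scoring

The EMG chain is band-pass (28–500 Hz, 4th-order Butterworth), rectify,
smooth (40 Hz low-pass FIR). The band-pass is applied forward-backward
(zero-phase), preserving burst latency relative to the scoring windows at the
cost of squaring the magnitude response (an effective 8-pole rolloff); the
FIR smoother is a Hamming design (order 100, ≈53 dB stopband) normalized to
unit DC gain and applied with exact group-delay compensation. Each probe is
scored as max over `[probe + 20 ms, probe + 120 ms)` minus mean over
`[probe − 100 ms, probe)`, floored at zero.

T-scores (`50 + 10·(x − mean)/sd`, sample sd with n−1; group contrasts are
invariant to the n vs n−1 choice) are computed within subject over **all
probed trials pooled across both phases**, zeros included. Pooling is the
critical interpretive choice: normalizing per phase would erase the DE-vs-OFL
phase comparison by construction. Habituation-phase probes (not rendered by
default) would be excluded from the reference distribution. Zero-variance
degenerate input maps every trial to 50 with a warning. Subjects with 5 or
fewer non-zero responses over the whole experiment are excluded ("5 or less":
exactly 6 is kept); the visually-identified "noisy recording" exclusion of the
original procedure is operationalized as more than 25% of trials with a
baseline-window RMS above 5× the cohort median.

## Contingency classification and statistics

An observer is contingency-aware iff the forced choice names the CS+ and
either the rule report names the CS+ or the CS+ has the *uniquely* highest
shock-probability rating (a tie is not "highest"). Missing ratings with no
rule report classify as unaware with a warning.

Group analyses delegate to base R and `car` behind the package's interface:
paired *t* tests (`d` = mean difference / sd of differences), repeated-
measures and mixed ANOVAs via the multivariate linear model with
`car::Anova(type = 3)` and sum-to-zero contrasts (the same machinery the
common mixed-ANOVA front ends use), with partial η² = SS/(SS + SS_error) per
effect. No sphericity correction is applied to 2-level within factors (it is
the identity there); for the 3-level FPS stimulus factor the
Greenhouse–Geisser ε and adjusted p are reported alongside the uncorrected
test, which uses integer dfs. Between-group Cohen's *d* uses the pooled sd
without small-sample correction. Confidence intervals are 95%, on the raw
mean-difference scale. Bonferroni correction multiplies each p by the number
of contrasts, capped at 1. Degenerate inputs are defined rather than left to
chance: identical paired samples return t = 0, p = 1, d = 0 (zero variance
with a non-zero mean difference is an error); an all-constant ANOVA table
returns F = 0, p = 1; an all-constant Kruskal–Wallis input returns H = 0,
p = 1.

## Monte-Carlo problem sizes

The recovery and calibration suites use sizes chosen so every check has
essentially unit analytic power while the whole test suite stays fast:

* Type-I error calibration of the mixed-ANOVA interaction: 2,000 null
  replicates at n = 14/21 (the study's group split), acceptance band
  0.035–0.065 around the nominal 0.05 (±3 binomial standard errors).
* SCR pattern recovery: 10 replicate cohorts of 10 aware + 10 unaware
  observers. The injected DE differential corresponds to a subject-level
  paired d ≈ 4 (aware) and an interaction d ≈ 3, so per-cohort detection
  power is ≈1 at this size.
* FPS pattern recovery: 8 replicate cohorts of 96 aware observers. The
  weakest injected direction (CS− vs fixation, boost 1.15) measures a
  subject-level d ≈ 0.6, giving per-cohort power > 0.998 at n = 96; the phase
  effect and CS+ contrast are far stronger.
* Property suites: 2,000 generated sequences for the run-length invariant,
  ≥5,000 ITI draws for the uniformity KS test, 100 seeded trials for the
  scoring-oracle equivalences.

## Known limitations

* The sparse deconvolution recovers isolated response amplitudes to within a
  few percent, but densely overlapping responses (the reinforced OFL trials)
  are attributed slightly conservatively (≈5–15% low in the noise-free test),
  which is immaterial for the floored, normalized condition contrasts the
  analysis uses.
* The quantile tonic baseline assumes responses are sparse relative to the
  10 s block length; recordings with near-continuous electrodermal activity
  would inflate it.
* The mixed ANOVA requires complete, balanced within-subject cells and at
  least two subjects per group; it refuses (rather than imputes) anything
  else.
* Synthetic recordings share one kernel shape and burst spectrum across
  subjects; parameter-recovery results should be read as calibration of the
  pipeline, not as evidence about biological variability.
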