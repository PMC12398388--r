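---
title: "phaseConn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phaseConn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseConn)
```

This vignette documents the statistical procedure the package implements,
the assumptions behind it, the parameters a user might want to move, and
the design choices that were genuinely open — with the reasoning, so a
maintainer does not have to reconstruct it.

## The analysis chain

phaseConn analyses emotion-regulation EEG experiments with four task
conditions — passive viewing of neutral (NatNeutral) and negative
(NatNegative) images, cognitive reappraisal (Reappraise) and expressive
suppression (Suppress) — recorded from a 30-channel 10/20 scalp montage and
epoched from −1.0 to 4.0 s around stimulus onset at 500 Hz, with 8–15
retained trials per condition. Two continuous traits per participant,
attachment anxiety and avoidance (ECR-12 style, 1–7), enter as moderators.

The chain is: window → multitaper cross-spectra → debiased wPLI per band →
baseline contrasts → percentile mask → ROI metrics → mixed-effects
moderation models.

### Spectral estimation

Epochs are windowed to 0.3–4.0 s post-stimulus (`selectWindow`), the
interval of sustained emotional processing after early perceptual
components. The 3.7 s window is analysed as a single segment — no
sub-windows, no zero-padding, so bins sit at the native 1/3.7 ≈ 0.27 Hz
spacing and no interpolation artifacts are introduced. The only detrending
is a per-trial, per-channel mean removal; anything stronger would touch the
delta band.

DPSS (Slepian) tapers implement spectral smoothing of ±2 Hz: the taper
count follows the standard multitaper-FFT rule `K = floor(2·T·W) − 1`,
giving 13 tapers at the default window. Tapers are computed from the
symmetric tridiagonal form of the concentration problem and cached; they
are unit-energy, so per-taper summed power over all bins equals the tapered
signal energy (the Parseval property the tests assert). Coefficients are
the exact DFT of the tapered signal evaluated only at the requested bins
via BLAS matrix products — equal to `stats::fft` output (tested) but much
faster in R when the window length has a large prime factor, which every
3.7 s window has (37).

### The connectivity estimator

For a channel pair, pooling the per-(trial, taper) cross-spectral
observations `X = c_a · conj(c_b)` — tapers are treated as exchangeable
with trials, matching how half-bandwidth smoothing is conventionally pooled
into phase statistics — the debiased weighted Phase Lag Index is

$$\widehat{\mathrm{wPLI}^2} \;=\;
\frac{\left(\sum_j \mathrm{Im}\,X_j\right)^2 - \sum_j (\mathrm{Im}\,X_j)^2}
     {\left(\sum_j |\mathrm{Im}\,X_j|\right)^2 - \sum_j (\mathrm{Im}\,X_j)^2},$$

the closed form of the pairwise double sum over ordered observation pairs
(`bruteForceWpli` evaluates that double sum directly and is the test
oracle). Three properties matter:

* zero-lag mixing contributes `Im X = 0`, so instantaneous volume
  conduction is suppressed by construction;
* the estimator is unbiased for squared wPLI and **may be negative** in
  finite samples. Negative values are deliberately not clamped — the
  downstream positive-percentile threshold discards them anyway, and
  clamping would re-introduce the small-sample bias the estimator removes;
* when every observation is purely real (pure zero-lag), the denominator is
  zero and the estimate is undefined. Undefined bins propagate as NaN, are
  excluded from band averages, and are counted (`nUndefined`).

Band values are the arithmetic mean of per-bin estimates over bins whose
centre falls inside the band (inclusive). Averaging estimates, rather than
estimating on pooled bins, keeps each bin's debiasing intact; the
alternative convention would mix bins with different phase-lag geometries.
A compiled accumulation (`engine = "cpp"`) computes the same numbers as the
per-bin R path without materialising cross-spectral arrays; the tests pin
the two paths together exactly.

### Masking and ROI metrics

Per participant and band, condition matrices are contrasted against the
NatNeutral baseline (reported as Negative, Reappraise, Suppress). The
threshold is the q-th percentile (default 95) of all strictly positive
ΔwPLI entries pooled across participants, conditions and pairs within the
band, using midpoint-position order statistics `p_k = (k − 0.5)/n` with
linear interpolation — the convention of MATLAB's `prctile`, which the
brute-force oracle in the tests reimplements from the definition. Pooling
individual-level deltas is the default (`mask.pooling = "individual"`);
pooling the group-mean matrices instead is available as
`mask.pooling = "group"` because the two readings are both defensible and
give different thresholds.

Masking is hard: entries strictly greater than the threshold are kept,
everything else is zeroed (ties at the threshold are excluded — the pair
must *exceed* the cut). Per band, the suprathreshold pair lists of the
three contrasts are unioned, and each participant's ROI metric is the mean
of their **own** ΔwPLI over masked pairs with at least one endpoint in the
ROI (frontal: 16 electrodes; central: 7). Participant values are not
re-thresholded: the group mask anchors individual metrics, which keeps the
outcome defined for participants whose individual deltas are subthreshold
and avoids per-participant selection noise. A pair with both endpoints in
the ROI counts once. If no masked pair touches an ROI the metric is missing
and logged, and the corresponding models are skipped.

### Mixed-effects moderation models

Per band × ROI × attachment dimension:

$$\Delta\mathrm{wPLI}_{ij} = \beta_0 + \beta_1\,\mathrm{Condition}_{ij}
 + \beta_2\,\mathrm{Attachment}_i + \beta_3\,(\mathrm{Condition}\times\mathrm{Attachment})_{ij}
 + b_{0i} + \varepsilon_{ij}$$

with a participant random intercept, fitted by **maximum likelihood**
(lme4, `REML = FALSE`): AIC, BIC and likelihood-ratio comparisons across
fixed-effect structures are only valid under ML. Negative is the reference
condition, so the reported terms are "Condition: Reappraise",
"Condition: Suppress" and their interactions. Attachment is mean-centred
within each table, making the condition contrasts interpretable at average
attachment; on a 1–7 item-mean scale the raw zero is meaningless.
Wald tests use the normal reference by default; a residual-df t reference
is available (`dfMethod = "residual"`) and differs negligibly at
N = 60 × 3 observations. The normal/ML combination is very mildly
anticonservative (measured type-I rate ≈ 0.055–0.065 at the default
simulation settings, within the tolerance the tests assert).

FDR control is Benjamini–Hochberg over one family per attachment predictor:
all non-intercept fixed effects pooled across bands and ROIs. The family
definition is configurable in spirit — it is applied in `runPipeline` and
trivially re-computed from the effects table for any other grouping —
because published analyses are rarely explicit about it.

`likelihoodRatioTest` compares nested ML fits (`deviance(nested) −
deviance(full)` against χ² with the parameter-count difference); identical
models return statistic 0 and p = 1 by convention, and deviance differences
in (−10⁻⁶, 0) are clamped to zero as optimizer noise.

### Behavioural utilities and power

Arousal ratings are gated per condition with Shapiro–Wilk (flagging
non-normality at p < .05), compared with a midrank tie-corrected Friedman
test — the 0/0 case of fully tied columns is defined as χ² = 0, p = 1 —
and followed by Dunn's post-hoc z tests whose rank-sum-difference variance
is accumulated per participant as `2·s²ᵢ·k/(k−1)` from the midrank variance
s²ᵢ (reducing to `n·k(k+1)/6` without ties), with Bonferroni-style
adjustment capped at 1. Paired Cohen's d uses the difference-score
convention `mean(x−y)/sd(x−y)`; a (near-)constant difference is a
degenerate-input error rather than an infinite d.

The RM-ANOVA power calculator uses the noncentral-F formulation with
`df1 = (k−1)ε`, `df2 = (N−1)(k−1)ε` and noncentrality
`λ = f²·N·k·ε/(1−ρ)` — the G*Power convention for within-subject factors,
with ρ = 0.5 and ε = 1 as surfaced defaults. At k = 3, f = 0.20, α = .05
and target power .85 the smallest adequate N is 48; at N = 60 the minimal
detectable effect size is f ≈ 0.18.

## The synthetic cohort generator

Since no public recordings accompany this design, the generator is
first-class, tested code. It emulates exactly the features the analysis is
sensitive to:

* **Coupling** is a shared sinusoid per edge and trial: frequency uniform
  within the edge's band, uniform trial phase, the second channel shifted
  by a base lag (never 0 or π, so the imaginary cross-spectrum is non-zero)
  plus wrapped-normal phase jitter. Shared sinusoids with controllable
  jitter were chosen over AR models as the simplest mechanism whose wPLI is
  analytically predictable.
* **Strength model**: coupling strength κ = logistic(intercept +
  condition offset + condition slope × centred attachment), centred at the
  scale midpoint 4 so a participant's κ does not depend on the cohort
  around them. The jitter map σ(κ) = π(1 − κ) spans near-uniform phase
  (κ = 0, wPLI ≈ 0) to a perfectly constant lag (κ = 1, wPLI² = 1)
  monotonically — the monotonicity the tests verify by Monte Carlo.
* **Background**: independent 1/f noise per channel (spectrally shaped
  white noise, exponent 1), scaled by a single SNR knob defined as
  oscillation RMS over noise RMS (default 1).
* **Volume conduction**: a real channels × channels matrix applied after
  source placement — instantaneous, zero-lag leakage only. No leadfield
  realism is attempted or intended.
* **Design**: 15 trials per condition by default with optional dropout to
  8–15 emulating artifact rejection; 500 Hz; epochs −1..4 s. The generator
  itself accepts any trial count ≥ 2 — its own calibration properties need
  hundreds of trials — while the 8–15 range is the documented study
  condition.
* **Seeding**: one master seed; per-participant streams at fixed offsets,
  so extending a cohort never reshuffles existing participants.
* **Attachment scores**: exact rejection-sampled truncated normals on
  [1, 7] (item-mean convention, chosen for interpretability over item
  sums — only the scale of β₂/β₃ depends on this, not the tests).

What it does **not** emulate: event-related potential morphology, ocular or
muscular artifacts, electrode drift or impedance changes, non-stationary
coupling within a trial, and anatomically realistic mixing. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
for oscillatory phase coupling under linear instantaneous leakage — not
that any particular neural claim holds in real recordings.

The demonstration ground truth (`defaultCouplingEdges`) plants the pattern
the models are meant to detect: two theta edges from frontal to posterior
sites with a Reappraise offset (+2 on the logistic scale) and a negative
anxiety slope (−0.7 per scale unit), and two beta edges from central sites
with a Suppress offset (+1.5) and a positive avoidance slope (+0.7). These
magnitudes were fixed once, at values a moderate-SNR EEG study could
plausibly produce, before any recovery test was run.

## Numerical choices and degenerate inputs

* Percentile: R `quantile` type 5 ≡ midpoint convention; asserted against a
  from-the-definition oracle.
* NaN policy, everywhere: undefined estimates are excluded from averages
  and counted/logged, never silently imputed.
* Thresholding uses strict `>`; a threshold above the maximum yields an
  empty mask, which downstream stages treat as "band skipped".
* No positive deltas in a band, a constant sample in the Shapiro gate,
  zero-SD difference scores, an all-identical Friedman matrix, fewer than
  two observations for the wPLI estimator — all are explicit errors or
  defined degenerate results, tested.
* EDF+ serialization quantizes to 16 bits over a symmetric physical range
  (affine digital map), so round-trip error is below one quantization step;
  trials are data records with `TRIAL k` annotations.
* Pipeline reports are written with full-precision JSON and no timestamps;
  a rerun under the same configuration is byte-identical (timings go to a
  separate JSONL log). Artifact caching for `--resume` is keyed by an MD5
  hash of the canonical configuration JSON.

## Problem sizes used by the test suite

The replicate simulation studies (end-to-end recovery of the planted
interaction signs, and the full-pipeline null for type-I control) run the
study design at a reduced size chosen for tight iteration: N = 60
participants on a 12-channel montage, 8 trials per condition at 200 Hz,
theta and beta bands. These sizes preserve every structural feature of the
full design (four conditions, baseline contrasts, percentile masking over
all pairs, both ROIs, 13 tapers at the 3.7 s window) while making a
20-cohort recovery study and a 40-cohort null study a matter of minutes.
The full 30-channel, 500 Hz, 15-trial configuration is the package default
(`validateConfig(list())`) and is exercised by the demonstration and unit
tests at smaller cohort sizes.

## Known limitations

* Scalp-level only: no source reconstruction, by design; interpretation of
  "frontal"/"central" is topographic, not anatomical.
* Single-window spectra: no time-resolved (sliding-window) connectivity;
  the whole 0.3–4.0 s interval is one estimate.
* Random intercepts only; random condition slopes, Satterthwaite or
  Kenward–Roger degrees of freedom, and Bayesian alternatives are out of
  scope.
* Graph-theoretic summaries (degree, modularity) and cluster-based
  permutation corrections are not provided.
* The EDF+ writer/reader covers this package's cohort files (EDF+C, 16-bit,
  one record per trial), not the format's full generality.
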