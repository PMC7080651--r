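---
title: "Prestimulus alpha power and response time: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prestimulus alpha power and response time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prealpha)
```

## The scientific question

Occipital alpha oscillations (7–14 Hz) in the seconds before a stimulus
index preparatory attention: on trials where prestimulus alpha power is
low, responses tend to be fast. In healthy older adults this within-subject
coupling between single-trial prestimulus alpha power and response time
(RT) is weakly positive; in mild cognitive impairment (MCI) it is reduced
or absent. `prealpha` implements the full analysis chain that measures this
coupling in an Eriksen flanker task — single-trial spectrograms, a
fast/slow median split, a within-subject Spearman correlation carried to
the group level through the Fisher z transform, mixed-design ANOVAs, and a
nested cross-validated SVM that asks whether the derived features separate
MCI from healthy controls (HC) — together with a synthetic-cohort generator
whose coupling strength is analytically controlled, so every stage can be
validated against known ground truth.

## The synthetic cohort generator

No public dataset accompanies the design this package models, so the
generator is a first-class part of the package rather than a test fixture.
Each subject contributes `trials × channels × samples` epochs (default
120 trials, 8 channels, 500 Hz, −2000…+1000 ms around stimulus onset).

**Coupling by Gaussian copula.** For each trial a latent standard-normal
pair $(u_i, v_i)$ is drawn with Pearson correlation
$r = 2\sin(\pi\rho/6)$, which is exactly the latent correlation that
produces a population Spearman correlation of $\rho$ after any monotone
marginal transforms. $u_i$ maps through the lognormal quantile to the
trial's alpha amplitude $a_i$ and $v_i$ maps affinely to its RT. The
coupling therefore targets the *true* per-trial alpha power $a_i^2$
directly — Spearman correlation is invariant to squaring a positive
amplitude — and the generative rank correlation is known exactly rather
than estimated. Trials with RT below 150 ms are redrawn as pairs
(truncation by resampling), which preserves the copula's rank structure
where clipping would not.

**Defaults are the study conditions.** Condition RT means and SDs are
498/55 ms (congruent) and 538/58 ms (incongruent); error rates are
6%/7% (HC) and 5%/10% (MCI) per condition; coupling defaults are +0.10
(HC) and −0.03 (MCI); cohorts default to 28 subjects per group with 60
trials per condition. Neuropsychological scores (MMSE plus ten tests over
five cognitive domains) are drawn normal with group-specific means and
SDs reflecting a community-recruited MCI sample, and the 1.5-SD
domain-dysfunction rule is provided as a labeling function
(`classify_mci()`), with strict inequality at the cutoff and sign-flipped
comparison for the timed tests (TMT-A/B, Stroop) where higher is worse.
Published normative tables are external data, so the default norms are a
synthetic stand-in set to the generated HC distribution.

**Free parameters chosen once.** Where neither the task design nor the
emulated study pins a value, a single realistic choice was made and kept:
per-trial alpha amplitude lognormal with median 1 µV and `sdlog` 0.4
(alpha rhythm comparable to the broadband background, trial-to-trial
amplitude spread of roughly ±2× — typical of occipital alpha); 1/f
background noise at 1 µV RMS per channel with spectral exponent 1;
non-occipital channels carry the alpha waveform attenuated to 0.3× so that
average re-referencing is non-degenerate. "Low noise" in the recovery
studies means `noise_amp = 0.3`. The noise is independent across channels:
there is no volume-conduction model, no evoked-potential morphology, and
no artifact synthesis (an external artifact mask is honored at exclusion).
Consequently a passing recovery test shows that the pipeline's statistics
are faithful on data whose spectral and coupling structure matches the
generative model — it does not certify performance under real-world
artifacts, spatially correlated noise, or non-stationary alpha.

## Preprocessing

Epochs are re-referenced to the average of all channels, band-pass
filtered 1–30 Hz, and baseline-corrected by subtracting the mean of the
−2000…0 ms interval per trial and channel. The filter is a zero-phase
windowed-sinc (Hamming) FIR applied by FFT convolution with exact
group-delay compensation; because a single windowed-sinc cannot have
different transition widths at its two edges, the kernel is the difference
of two low-pass kernels, giving a transition bandwidth of
`min(max(0.25·lo, 2), lo)` Hz at the low edge (1 Hz at `lo = 1`) and
`0.25·hi` Hz at the high edge (7.5 Hz at `hi = 30`), each edge at its
−6 dB point. Epoch ends are treated as zero-padded; the outermost
half-kernel width is therefore attenuated, which cannot touch the
prestimulus region of interest.

Trials are excluded if no response occurred within the response window
(250 ms stimulus + 2000 ms post-stimulus fixation = 2250 ms from onset,
configurable), if the response was incorrect, if an artifact mask flags
them, or if RT falls outside the per-condition closed interval
mean ± 2 SD computed in a single pass over valid-response trials. Error
rates are computed over all valid-response trials; RT summaries over
included trials only. A condition left with fewer than 4 included trials
signals an unusable subject rather than producing degenerate statistics.

## Single-trial spectrograms

The windowed Fourier transform uses a fixed 300 ms symmetric Hanning
window — 150 samples at 500 Hz, centered on each output time point
(sample 75, 0-based, of the window) on a 2 ms output grid — zero-padded to
500 samples so the frequency grid has exactly 1 Hz spacing
($\Delta f = f_s/N_{\text{pad}} = 500/500$), and retains bins 1–30 Hz.
The spectrogram is $P(t,f) = |F(t,f)|^2$. No taper gain compensation is
applied, so absolute power is convention-dependent; every downstream
statistic (median-split difference, rank correlation, ANOVA on
within-subject cells) is invariant to a per-subject scale factor, and the
tests check relative, not absolute, power.

Two numerically identical engines exist: a per-segment padded FFT (the
definition, kept as the reference) and an FFT filterbank that evaluates
the same sums as one convolution per retained frequency bin. The filterbank
is the production path — it is an order of magnitude faster when only the
8 alpha bins × 351 prestimulus time points are needed — and the test suite
pins both engines to a naive $O(N^2)$ DFT oracle at $10^{-10}$ relative
error. Prestimulus alpha power is the mean of $P(t,f)$ over
−1000…−300 ms × 7–14 Hz (inclusive bounds on both axes: 351 × 8 grid
points), computed per channel and averaged over Oz, O1, O2 (equal counts,
so this equals pooling).

## The coupling statistics

Within each condition's included trials, the median RT defines the
fast/slow split; "fast" is strict (`RT < median`), so median-tied trials
fall in the slow bin. The split is per condition — the speed × congruency
ANOVA crosses the two factors, so pooling conditions would confound the
speed bins with congruency — but a pooled-median variant is exposed as a
configuration switch. The per-subject coupling statistic is the Spearman
correlation between single-trial alpha power and RT over all included
trials of a condition (both bins pooled), carried through
$z = \tfrac12\ln\frac{1+r}{1-r}$. The Fisher transform's variance theory
is exact for Pearson correlations, not Spearman; it is applied to the
Spearman coefficient here because that is the procedure being modeled —
fidelity over orthodoxy. Coefficients at ±1 (degenerate simulated
subjects) raise an error unless clamping at ±(1−10⁻⁷) is requested
explicitly; nothing is clamped silently.

### A quantified limitation: exclusion attenuates the coupling

The ±2 SD RT exclusion range-restricts RT, and restriction of range
shrinks rank correlations. At a generative coupling of 0.4 with 60 trials
per condition, the mean recovered Fisher z sits about 0.04 below
$z(0.4) = 0.424$; removing the exclusion step removes the bias entirely
(the coupling test suite demonstrates both facts). This is a property of
the modeled procedure, not an implementation artifact: any analysis that
trims RT tails before correlating will under-estimate a strong coupling by
roughly this margin. At the weak couplings typical of real data (|ρ| ≈ 0.1)
the bias is negligible, but recovery checks at strong couplings must not
expect agreement much tighter than this attenuation.

## Group-level inference

The mixed-design ANOVA is the classical univariate split-plot
decomposition (subjects random, factors fixed) computed through `aov`
error strata on balanced data, with partial
$\eta^2 = SS_{\text{effect}}/(SS_{\text{effect}} + SS_{\text{error}})$
taken within each effect's own stratum. The Greenhouse–Geisser epsilon is
estimated generally — box epsilon on orthonormalized effect contrasts of
the pooled within-group covariance — even though every within factor in
this design has two levels, where $\varepsilon = 1$ identically and the
corrected p equals the classical one; the general path is exercised by a
three-level test case. Effects with zero sum of squares report F = 0
rather than 0/0. Post-hoc contrasts are paired or independent t-tests with
Bonferroni correction over the family actually tested (the simple effects
of one interaction form one family). Cohen's d uses the pooled SD for
independent contrasts — consistent with d ≈ t·√(2/n) at equal group sizes
— and the SD of differences for paired ones. Feature-by-neuropsychology
correlations are Pearson, computed within each group separately, because
pooling groups with different means would manufacture correlation out of
the group difference.

## The SVM protocol

Classification (HC vs MCI, all 15 features) and regression
(neuropsychological scores from the 9 electrophysiological features) use
RBF-kernel SVMs via LIBSVM (`e1071`). The protocol — not the optimizer —
is the implemented contribution: feature rescaling to 0–1, exhaustive
feature-subset enumeration, and (C, γ) grid search all sit *inside* each
outer training fold of a stratified 10-fold cross-validation repeated
(by default) 100 times, with inner 10-fold accuracy (classification) or
MSE (regression) as the selection criterion and ties broken toward the
smaller subset, then smaller C, then smaller γ. Per repetition, outer-fold
predictions are pooled into one confusion matrix and ROC; aggregates are
means with percentile (2.5/97.5) 95% confidence intervals over
repetitions. Undefined rates (zero denominators) are NA, never 0.

Cross-validated R² is reported in two conventions: the squared Pearson
correlation between pooled out-of-fold predictions and observations
(primary; always in [0, 1]) and 1 − SSE/SST (which can be negative out of
sample). The default search lattice is C ∈ 2^{−5,−3,…,15},
γ ∈ 2^{−15,−13,…,3}; full enumeration over all 2¹⁵−1 subsets at that grid
is combinatorially explosive, so the subset iterator is capped by
`max_size` (analyses in this package use single-feature subsets with a
coarse 3 × 3 grid and 5–10 repetitions, which keeps a full run in minutes
on one core; all caps are arguments, not constants). A deliberately leaky
variant — scaler and subset fitted once on all data — exists behind
`leak = TRUE` solely so the test suite can demonstrate that leakage
inflates null accuracy; it should never be used for inference.

## Determinism and numerics

One cohort seed fans out deterministically to per-subject streams
(`child_seed`, an affine map modulo 2³¹−1), so cohort composition does not
depend on evaluation order, and each CV routine seeds its own stream;
identical configuration and seed give bit-identical reports. FFT lengths
are padded to 5-smooth sizes. The filterbank and segment spectrogram
engines agree to 10⁻¹⁰ relative error; re-referencing and filtering
commute to the same tolerance (both are linear). Tie handling is explicit
everywhere it matters: average ranks in the Spearman correlation, ½ credit
in the rank-based AUC, median ties to the slow bin, model-selection ties
to the simpler model.

## Problem sizes used in the shipped analyses

The analysis drivers and verification runs use: full statistical cohorts
at 28 + 28 subjects × 120 trials (the emulated study's size); coupling
recovery at 20 subjects × 120 trials per target; ANOVA calibration with
500 replicate null studies of 10 + 10 subjects × 40 trials on the
coupling core (waveform synthesis adds nothing to that question); and CV
sanity checks at 56 subjects with 10 repetitions. The on-disk demo cohort
is 6 + 6 subjects × 60 trials to keep the written artifact small.
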