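---
title: "Methods: graded vs discrete repertoires and situation encoding"
author: "vocrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded vs discrete repertoires and situation encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocrep)
```

This vignette documents the models and procedures implemented in
**vocrep**, the assumptions behind them, the tunable parameters and their
defaults, and the design choices made where the methodology was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific problem

Two recurring questions in bioacoustics motivate the package. First,
whether a species' vocal repertoire is *discrete* (calls fall into
well-separated types) or *graded* (variation is continuous and any typology
is a convenient simplification). Second, how much information calls carry
about the *situation of emission* — and whether a coarse call-type label
carries almost as much of it as the full quantitative acoustic description.
The package operationalises both questions for a study design in which
calls are recorded in several situations of known biological significance,
from multiple individuals nested in litters, and situations carry an
expert-rated emotional valence.

## Acoustic measurement model

All spectral quantities derive from short-time Fourier analysis with a
Hamming window, FFT length 1024 samples, and 87.5 % overlap. At the 44.1
kHz default sampling rate this gives a 43 Hz frequency grid, a 23 ms
analysis window and a ~3 ms hop. These are conventional settings for
mammal calls in the 0.1–10 kHz band: the bin width resolves the pitch
contrasts of interest while the window remains much shorter than a call.

Whole-call spectra are the average magnitude spectrum over all analysis
frames lying fully inside the annotated segment (half-open `[start, end)`
in seconds, zero-based from the file start). Averaging over frames rather
than transforming the entire call at once keeps the frequency grid fixed
across calls of different lengths.

Per call, eight variables:

* `pf` — centre frequency of the maximum-amplitude bin (ties to the
  lowest bin);
* `q50` — the frequency at which cumulative spectral *energy* (squared
  amplitude) first reaches half the total. First-crossing with no
  interpolation, so the value is always an existing bin centre and is
  bin-exactly testable; it shifts by exactly m bins when the spectrum is
  translated m bins.
* `ent` — Wiener entropy, the ratio of geometric to arithmetic mean of
  the amplitude spectrum (0 for one component, 1 for a flat spectrum).
  Raw Wiener entropy grows with analysed bandwidth, which confounds
  comparisons between low and high calls. The bandwidth correction used
  here computes the ratio on the spectrum truncated at 2·q50 — a
  deliberately simple rule that uses only in-call quantities. The
  commercial software this measure is usually taken from documents a
  "scaled to q50" value without giving its formula; our truncation rule
  is a documented stand-in, and the raw full-band value is kept alongside
  (`ent_raw`).
* `q50start`, `q50end`, `q50min`, `q50maxloc` — frequency-modulation
  measures from eleven measurement positions spaced regularly over the
  call (the start, then steps of call-length/10). The first and last
  positions sit on the call edges where the analysis window leaks into
  silence, so only the nine interior windows are retained, indexed 1..9.
  Each retained window is measured as the q50 of the single 23 ms frame
  centred on it. q50 rather than pf is tracked per window because peak
  frequency jumps erratically between noisy frames. Ties in `q50maxloc`
  go to the earliest window.
* `dur` — the annotated duration, exactly `end − start`.

Variables are centred and scaled to unit variance (sample sd, n−1
denominator — so `var()` of a standardized column is exactly 1) before
clustering and discriminant analysis; the transform is stored so held-out
calls can be projected onto the same scale. Pairs of variables correlated
above |r| = 0.9 are screened greedily: the later-listed member of the
first offending pair is dropped, repeatedly, and the dropped pairs are
reported.

## Repertoire discreteness

k-means clustering is run for K = 2..15 on the standardized variables.
Because no initialization policy is canonical, the package uses 50 random
restarts per K (initial centroids drawn from the data without
replacement, seed-controlled), keeps the lowest-WSS solution, and repairs
empty clusters by reseeding from the farthest point. Two validity indices
summarize the curve: `EtaK = 1 − WSS_K/WSS_1` and
`PreK = 1 − WSS_K/WSS_{K−1}`, with `WSS_1` the total sum of squares about
the grand mean. They satisfy the identity
`1 − EtaK(K) = Π_{j≤K} (1 − PreK(j))`, which the tests verify to 1e-9.
To guarantee WSS is non-increasing in K (so PreK ≥ 0), each K
additionally tries an initialization built from the previous solution's
centers plus the farthest point; Lloyd iteration from that start can only
improve on WSS at K−1.

The package deliberately does **not** adjudicate a single "true" K: the
validity curve is reported, and the 2- and 5-cluster solutions are both
named and carried forward, since both granularities are in use in the pig
literature. Naming is by cluster means in natural units: at K = 2 the
higher-q50 cluster is HF; at K = 5 the two highest-q50 clusters split by
mean frequency modulation (q50end − q50start) into HFm/HFs, the most
tonal (lowest-entropy) of the remaining three is LFt, the most modulated
of the last two is LFm, and the rest is LFs. Other K get generic names
with a warning. Representative calls are the members nearest their
centroid (ties to the lowest index — all tie-breaks in the package are
deterministic so that runs are reproducible).

## Classification and its null distributions

The discriminant model is the Gaussian equal-covariance (linear)
classifier: class means, pooled within-class covariance, priors, argmax
of the linear discriminant score with exact ties going to the class
listed earlier. When the predictors are the call-type indicator matrix
(one 0/1 column per type; each row a single 1) the pooled covariance is
singular by construction, so a small ridge (1e-8) is added to its
diagonal.

Cross-validation is the holdout method: a random half-split, re-drawn (at
most 100 times) until every class appears in both halves; fit on the
calibration half, evaluate on the validation half. Significance comes
from label permutation: class labels are permuted across calls and the
*entire* holdout procedure is repeated per permutation (fresh split each
time, i.e. labels are permuted before splitting), giving a chance level
(the null mean) and `p = (1 + #{null ≥ observed}) / (n_perm + 1)` — the
add-one convention that avoids zero p-values.

Two properties of this null are worth knowing. First, the chance level is
*not* 1/G or the sum of squared class proportions: because the validation
half is the complement of the calibration half, label frequencies in the
two halves are anti-correlated and the null accuracy sits systematically
below the naive value (the test suite verifies the package agrees with an
independent `MASS::lda`-based holdout under the null). This is exactly
why a permutation-derived chance level, rather than an analytic one, is
the right comparison. Second, priors default to training class
frequencies, which matches how chance levels depend on class imbalance in
this design; `prior = "uniform"` is available.

**pDFA.** With several calls per animal, call-level permutation
overstates significance whenever individuals differ vocally. The
individuality-controlled test permutes at the subject level:
subject-to-class assignments are shuffled respecting the number of
subjects per class, every call inherits its subject's permuted class, and
the holdout statistic is recomputed. Animals recorded in two situations
are split into subject-situation pairs (with a message), preserving the
nesting the permutation scheme requires; classes with a single subject
are unpermutable and raise an error. The test suite verifies both
validity (rejection rate within the binomial band of the nominal 5 %
over 200 null datasets) and the contrast that motivates the method: with
injected subject effects and no class effect, the naive test inflates
while pDFA does not.

**Multi-call accuracy.** The leave-sample-out simulation asks how
accuracy grows with the number of calls available: for each situation, n
calls are drawn without replacement (drawing without replacement is a
choice; the source methodology does not specify it), summarized by the
mean of their standardized features or by their call-type proportions,
and the one-sample-per-situation batch is classified by a discriminant
fitted on all remaining calls. Ten draws form one repetition; means and
normal 95 % confidence intervals are taken over twenty repetitions.
Situations with fewer calls than the largest n are excluded with a
warning. Priors here default to *uniform*, unlike the single-call
analyses: each batch contains exactly one sample per situation by
construction, so the prior over situations really is uniform. With
frequency priors the log-prior differences between rare and common
situations overwhelm the shrunken margins of averaged samples (whose
within-class scatter — inflated by the multimodality of mixed-type
situations — no longer matches the single-call covariance the model was
fitted on), and small situations get systematically misassigned.

MANOVA (Wilks λ with Rao's F approximation, via `stats::manova`) tests
multivariate mean differences between situations.

## Situation structure and valence

Per-situation profiles are either mean acoustic variables (natural
units; standardized column-wise before computing distances) or call-type
proportions. Profiles are clustered by Ward's minimum-variance criterion
on Euclidean distances (`hclust` method `ward.D2`, whose merge heights the
tests verify against a hand-coded Lance–Williams recursion), and the tree
is exported as Newick through **ape**.

The call type × situation table is tested against independence with the
Pearson chi-square when all expected counts are at least 5, otherwise
with a Monte-Carlo permutation test (2000 replicates by default) holding
both margins fixed. Associations are interpreted through Pearson
residuals `(obs − exp)/√exp`, flagged at the conventional evidence tiers
|r| > 2 and |r| > 4.

Valence enters as the mean expert negativity rank per situation (rank 1 =
most negative). Per-situation acoustic means are correlated with the mean
rank by Spearman's rho — exact permutation p-values for ≤ 11 situations
without ties, the t approximation otherwise — and the eight tests are
Benjamini–Hochberg adjusted as one family. Call-type proportions are
regressed on the rank with a logit-link binomial family whose dispersion
is estimated from Pearson's chi-square (quasi-binomial), situations
weighted by their call totals; slopes are tested by a drop-in-deviance F
test with S − 2 residual degrees of freedom (9 at 11 situations, a
2-parameter model), and adjusted across types as one family. Which tests
share an FDR family is not canonical; the package keeps families
per-analysis. Complete separation (a type entirely absent or universal)
is flagged in the output rather than silently dropped.

## The synthetic-call generator

The generator is first-class, tested code, and defines the conditions
under which the pipeline is exercised. It emulates, structurally, an
11-situation piglet study: the packaged design (`piglet_situations()`)
carries the per-situation call/piglet/litter counts of that design (1513
calls from 84 recorded piglets in 34 litters; situations grouped into
life-threatening, nursing and general social categories).

Five latent call-type prototypes (LFs, LFm, LFt, HFs, HFm) are specified
qualitatively: HF types higher-pitched and longer than LF; LFs lowest and
least modulated; LFt the most tonal; HFm strongly upward-modulated. Calls
are generated in feature space as prototype mean + litter offset + piglet
offset + residual Gaussian noise; offsets are shared by all calls of an
animal (litter), so individual non-independence is available to the pDFA
contrast. Random-effect scales are expressed as multiples of the
within-type feature sd (defaults 0.5 and 0.25). Each piglet belongs to
one litter and one situation; litters are nested within situations in the
generator (in a real study litters can span situations — a simplification
that does not affect the statistics exercised here). Generated features
are clamped to physically admissible ranges (positive frequencies and
durations, entropy in [0,1], `q50maxloc` rounded to 1..9,
`q50min ≤ min(q50start, q50end)`).

The default within-type sds are broad on purpose. The emulated repertoire
is *graded*: neighbouring types overlap heavily, and — in line with the
screening step being a real part of the pipeline — the default spreads
keep every pairwise feature correlation below the 0.9 threshold, so all
eight variables survive screening (the strongly collinear pitch family
would otherwise collapse). A `sd_scale` multiplier shrinks the spreads
for recovery experiments; the tests use `sd_scale = 0.1`, at which the
smallest between-type distance exceeds six within-type sds (checked
explicitly in the suite).

Situation-specific type mixtures are configuration. The defaults follow
the qualitative field picture (HF types concentrated in life-threatening
situations, LFt around nursing, LFs/LFm in the social situations) and are
deliberately *realistic*: several situations share nearly the same
mixture. A consequence worth stating is that with such mixtures the
situations are only partly distinguishable from call types no matter how
separated the types are — 11-way multi-call accuracy plateaus well below
100 %. Recovery experiments that need full distinguishability therefore
use a documented favorable-condition mixture set (pairwise clearly
distinct mixtures) in the test helper, while the package defaults stay
realistic.

Waveform synthesis exists to exercise the acoustic front-end end-to-end:
a harmonic stack (amplitudes 1/h, harmonics above 0.95 Nyquist dropped)
whose fundamental sweeps linearly between two frequencies, energy-mixed
with white noise by the prototype's tonal fraction, edge-tapered and
embedded in silence, deterministic given the seed. It makes no attempt at
realistic vocal-tract modelling or amplitude calibration; what it
guarantees — and what the tests assert — is that extraction recovers the
controlled parameters: tones localize to one 43 Hz bin, durations are
exact, sweep direction is recovered from `q50end − q50start`, and noise
is more entropic than tone.

The expert panel is simulated by perturbing a true negativity ordering
with one pass of adjacent transpositions (swap probability per pair;
0 reproduces the truth exactly). The default true ordering places
castration most negative and after-nursing most positive, matching the
qualitative consensus for these situations.

What passing tests on this generator do *not* show: robustness to
recording noise, channel effects, segmentation errors, non-Gaussian
within-type variation, or age/context drift within situations. The
generator emulates the study's *structure* (counts, nesting, mixtures,
individual effects), not pig acoustics.

## Numerical choices and problem sizes

Deterministic tie-breaks everywhere (lowest index / earliest class);
first-crossing q50 without interpolation; ridge 1e-8 for indicator LDA;
add-one permutation p-values; holdout split retried at most 100 times;
Monte-Carlo chi-square with both margins fixed; BH step-up for FDR. All
randomness flows through explicit integer seeds, and per-stage seeds in
the pipeline are derived from one master seed by fixed offsets, so reruns
are bit-identical.

The test suite runs its heavier simulations at sizes chosen to make the
properties sharp but cheap: permutation-validity at 200 null datasets ×
199 permutations on 48-call datasets; recovery at the full 1513-call
design with Kmax = 8 and 20 restarts; the accuracy curve on the grid
n ∈ {1, 2, 5, 10, 20} with 10 draws × 20 repetitions. The acceptance
script runs the complete default pipeline (Kmax = 15, 50 restarts, 1000
permutations, n = 1..20).

## Known limitations

* The entropy bandwidth correction is a stand-in for an undocumented
  commercial formula; `ent` values are internally consistent but not
  comparable to that software's output.
* The quasi-binomial F-test's residual df (S − 2) presumes the
  2-parameter model; with other model structures the reported df would
  need adjusting.
* pDFA assumes subjects are exchangeable within class under the null;
  strongly unbalanced calls-per-subject weaken the permutation symmetry.
* The generator's Gaussian feature model cannot produce the skewed,
  bounded distributions of real spectral measures; clamping introduces
  small point masses at the physical floors for very broad settings.
* Fundamental-frequency (F0) measurement is out of scope: it is
  unreliable in noisy calls, and none of the implemented analyses use it.
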