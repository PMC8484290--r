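---
title: "Uncertainty-guided review of automated sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-guided review of automated sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated sleep stagers assign one of five stages — W (wake), REM, N1, N2,
N3 — to every 30-s epoch of a night's EEG. Even good stagers are wrong on a
meaningful fraction of epochs, and a clinician cannot tell *which* epochs
without re-scoring everything, which defeats the purpose of automation.
`sleepuq` implements a clinician-in-the-loop alternative: a probabilistic
stager emits, for every epoch $t$, a posterior
$p = [p_W, p_{REM}, p_{N1}, p_{N2}, p_{N3}]$ rather than a bare label; the
entropy of that posterior measures how much the model is actually deciding
between alternatives; and only the epochs whose entropy exceeds a threshold
are routed to a human. The package bundles the whole loop — a synthetic
polysomnography (PSG) simulator, feature extraction, two stagers,
uncertainty measures, review policies, and agreement scoring — so the
method can be studied end-to-end without access to clinical recordings.

## Uncertainty from posteriors

For a posterior $p$ on the 5-simplex the Rényi entropy of order
$\alpha > 0$ is

$$S_\alpha(p) = \frac{1}{1-\alpha}\,\log_2 \sum_{i=1}^{5} p_i^{\alpha},$$

with the Shannon entropy $S(p) = -\sum_i p_i \log_2 p_i$ as the
$\alpha \to 1$ limit, the collision entropy at $\alpha = 2$, and the
min-entropy $-\log_2 \max_i p_i$ at $\alpha = \infty$. All are reported in
bits and range from 0 (a one-hot posterior, total confidence) to
$\log_2 5 \approx 2.32$ (uniform, total confusion). The family is
non-increasing in $\alpha$, which the test suite checks on random simplex
draws along with the bounds.

The default flagging rule marks an epoch for review when its Shannon
entropy **strictly** exceeds 1 bit. One bit is exactly the entropy of a
posterior torn between two equally likely stages with the rest negligible
($p = [0,0,0,0.5,0.5]$), i.e. the point where the model is genuinely
undecided between two readings of the epoch; an epoch at exactly 1 bit
stays automated. Posterior variance (population variance of the five
masses) is also provided. The package treats it as a *concentration*
measure — it is maximal at one-hot posteriors and zero at uniform, the
opposite polarity of entropy — because the stage codes are nominal: a
variance over the stage *indices* would pretend W and N3 are numerically
far apart, which is meaningless. It therefore never shares the entropy
threshold.

Numerical conventions: rows off the simplex by at most $10^{-6}$
(floating-point drift) are renormalized, anything worse is rejected with
the epoch index in the message; $0 \log 0 = 0$; zero masses are dropped
before exponentiation so that orders $\alpha < 1$ stay finite; orders
within $10^{-9}$ of 1 are routed to the exact Shannon branch. Note that the
routing window is *not* a continuity tolerance: $S_\alpha$ has an $O(1)$
derivative in $\alpha$ at 1, so $|S_{1\pm10^{-4}} - S_1|$ is itself of
order $10^{-4}$, and the tests assert continuity at that scale.

## The stagers

**KDE-emission HMM.** Six log band powers per epoch (below) feed a hidden
Markov model over the five stages. Transition probabilities are label
bigram frequencies from the training nights with add-one pseudocounts;
the initial distribution is the smoothed unigram frequency. We smooth the
initial vector too, although plain frequencies would be the textbook
estimator, because a stage absent from training would otherwise get a
structural zero that forbids it at the first epoch even though its
emission model falls back to uniform. Emissions are per-stage Gaussian
product-kernel density estimates with per-dimension Scott bandwidths
($h_j = \hat\sigma_j n^{-1/(d+4)}$), floored at $e^{-700}$ so a far-out
epoch cannot poison the decoder with $-\infty$. Posteriors are the exact
smoothed marginals $P(\text{stage}_t \mid \text{all epochs})$ from the
forward–backward algorithm, run in the log domain with per-step
log-sum-exp; the test suite proves the implementation against exhaustive
enumeration over all $5^T$ paths for $T \le 5$ on random models
(max $|\Delta| < 10^{-10}$).

The hard hypnogram is the per-epoch arg-max of the smoothed marginals,
ties broken toward the lowest stage code. A Viterbi path would be the
other defensible reading; we prefer the marginal arg-max because the
entropy of the *same* per-epoch posterior then measures the uncertainty of
the *same* decision that produced the label, keeping label and flag
consistent. Viterbi decoding is deliberately not offered.

**MLP.** A multilayer perceptron with hidden layers [32, 64, 32], ReLU
activations and a five-way softmax head, trained with Adam (step $10^{-3}$,
mini-batches of 32, 200 passes) on features standardized by training-set
statistics. The network is implemented in-package with plain matrix
algebra: it is a few thousand weights on six-dimensional inputs, and a
hand-rolled trainer keeps the fit bit-reproducible from a single seed.
Training requires at least two classes and refuses otherwise.

## Features

Raw single-channel EEG is bandpass filtered 0.1–50 Hz with a zero-phase
forward–backward Butterworth filter (order 4 per pass), then each
non-overlapping 30-s epoch gets a multitaper PSD using 7 DPSS (Slepian)
tapers at time–bandwidth product 4 — standard sleep-EEG practice; the
paperless parameters are package defaults, exposed in the call. The PSD is
integrated over six bands (0.5–4, 4–8, 8–12, 12–16, 16–30, 30–50 Hz),
floored at $10^{-12}$, and logged, so silent epochs yield finite features.
Epochs are half-open sample windows $[kL, (k+1)L)$; a trailing partial
epoch is dropped with a warning.

The DPSS tapers are computed from the standard tridiagonal matrix that
commutes with the concentration operator, via Lanczos iteration with full
reorthogonalization (a dense eigendecomposition at $n = 7500$ samples per
epoch would be impractical, and the tridiagonal form is also the
better-conditioned route, since the concentration eigenvalues themselves
cluster within $10^{-6}$ of 1). Tests verify orthonormality and agreement
with a dense concentration-matrix eigendecomposition at small $n$, plus a
Parseval-style check that white-noise band powers integrate to the
in-band share of the variance.

## The synthetic cohort

The simulator defines the study conditions under which everything is
tested. Ground-truth hypnograms come from a first-order Markov chain with
a strongly diagonal base transition matrix (self-transitions 0.80–0.92,
off-diagonal mass on physiologically ordered moves such as W↔N1, N1→N2,
N2↔N3) started mostly awake; the matrix is a stylized package constant,
not fitted to any cohort. A `fragmentation` parameter mixes the base
matrix toward a uniform one, `(1-w)T + wU`, emulating the increasingly
fragmented architecture of severe obstructive sleep apnea without
modelling respiration; no apnea events or AHI are simulated.

EEG is synthesized per epoch by shaping white Gaussian noise in the
frequency domain: each stage has a relative band-power profile over
delta/theta/alpha/sigma/beta (alpha+beta-rich W, theta-dominant REM, mixed
N1, sigma-rich N2, delta-dominant N3), a flat broadband noise floor
(variance 0.4) is added, and each epoch's band powers are multiplied by
lognormal jitter (sd 0.6 on the log scale). The jitter is the simulator's
single most consequential realism choice: real band powers vary
severalfold between epochs of the same stage, and without that
within-stage variability the stagers are near-perfect and no epoch is
ever uncertain — the phenomenon under study would vanish. N1's profile
deliberately overlaps its neighbours, as it does for human scorers. All
randomness derives from one integer seed through per-stream derived
seeds, so hypnogram, EEG, reviewer and MLP draws are independently
reproducible.

What the simulator does *not* emulate: artifacts, arousals,
non-stationary drift within epochs, age/medication effects, and any
respiratory signal. Passing tests therefore demonstrate that the
uncertainty-review machinery behaves as designed on plausible
stage-structured EEG — not that any particular clinical accuracy would be
attained on real recordings.

The default study design mirrors a severity-stratified cohort at desk
scale: four training nights (fragmentation 0, 0.15, 0.3, 0.5) pooled to
fit the stager, and ten test nights spanning fragmentation 0–0.5, each of
960 epochs (8 h) at 250 Hz.

## Review policies and evaluation

Four scorings are compared per night: **automated**; **automated +
review** (a simulated reviewer revisits flagged epochs — corrects a wrong
epoch with probability `reviewer_accuracy`, default 0.85 in the cohort
study, and corrupts an already-correct one with probability
`reviewer_error_rate`, default 0.1, since human re-scoring is itself
imperfect); **automated + clinically relevant review** (flags are first
filtered to epochs whose two most probable posterior stages form a
clinically relevant pair); and **automated + substitution** (flagged
epochs take the ground-truth label — the ceiling any reviewer could
reach, which provably never lowers per-epoch accuracy).

The relevance filter gates on the model's top-2 posterior stages, not on
truth: truth is what review is trying to establish, so only the
posterior is available "a priori" at review time. The default relevant
set is all ten unordered pairs minus {W, N1} and {N1, N2} — the
light-sleep confusions that are ambiguous even between experts — and is a
documented package default, not a clinical standard.

Agreement is scored by Cohen's Kappa
$K = (p_o - p_e)/(1 - p_e)$; certainty-stratified 5×5 confusion matrices
(row percentages by true stage; empty rows are `NA`, not zero; epochs
exactly at threshold land in the certain stratum, consistent with strict
flagging); entropy distributions by correctness and by true stage (mean ±
population SD and a kernel density over $[0, \log_2 5]$); and a paired
*t* test across nights for method comparisons, with an `NA` sentinel when
all differences vanish. Confusion percentages are stored at full
precision and only rounded for display.

## What the tests and the acceptance script compute

The suite asserts, among ~600 checks: the two analytic entropy anchors
(1 bit, $\log_2 5$ bits); forward–backward equality with the exhaustive
oracle; the Rényi bounds/ordering/continuity properties; on the simulated
10-night cohort, that substitution never scores below automated on any
night, that relevance filtering never raises burden, that mean entropy of
incorrect epochs exceeds that of correct epochs and flagged accuracy is
below unflagged accuracy, and that a reviewer with error rate 0.5 lowers
kappa below automated on at least one night. `scripts/acceptance.R`
re-runs the cohort from a command-line seed and writes the computed
kappas, burdens, entropy means and the paired-t p value as JSON; every
number it reports is computed in that run.

## Known limitations

Simulated EEG is stationary Gaussian within an epoch; KDE emissions treat
epochs as exchangeable given the stage; the reviewer model is a two-
parameter caricature of human scoring; hypnogram CSV is the only signal
metadata carried end-to-end (EDF ingest is not implemented). The entropy
threshold of 1 bit is a design constant of the method, interpretable but
not optimized; different stagers, features or populations may warrant a
different operating point.
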