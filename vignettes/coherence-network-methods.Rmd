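---
title: "Coherence networks, Surprise thresholding and state decoding for event-related LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence networks, Surprise thresholding and state decoding for event-related LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nclnet)
```

nclnet quantifies how the functional network spanned by a multichannel LFP
array reorganizes around a behavioural event — here, the moment an animal
detects a target. This vignette is the package's account of the models and
the choices behind them: what is estimated, with which parameters and why,
what the synthetic generator does and does not emulate, and where the design
was genuinely open.

## The signal model and preprocessing

Raw signals are taken as channels × samples at 30 kHz (or directly at the
1 kHz analysis rate). Conditioning follows standard LFP practice, every
filter zero-phase (forward–backward), so event-related timing is preserved:

* **Broadband restriction 1–250 Hz**, 4th-order Butterworth. The filter
  order is a convention choice; 4th order is the common LFP default and is
  stable at these edges. A transfer-function realization of this filter is
  numerically unusable at a 1 Hz edge on a 30 kHz rate, so all Butterworth
  filters here are designed as zero–pole cascades of biquad sections, which
  reproduce the textbook magnitude response to ~1e-15.
* **50 Hz notch**, 2nd-order IIR with quality factor 30 (≈1.7 Hz stop
  width): narrow enough to leave 45 and 55 Hz within 1 dB.
* **Decimation to 1 kHz** behind a 4th-order anti-alias low-pass at
  0.4 × the target rate — a conservative guard band.
* **Five-band decomposition**: delta 1–4, theta 5–12, beta 13–30, slow
  gamma 31–45, fast gamma 55–80 Hz. The 45–55 Hz gap deliberately straddles
  the power line.

Epochs cover the half-open window [event − 1 s, event + 1 s), exactly 2000
samples at 1 kHz with the event at offset 1000. Events without full context
are dropped with a warning rather than zero-padded.

## Sliding-window multitaper coherence

Each epoch is tiled by 256-sample windows advancing by 128 samples: 14
windows, whose midpoints put 7 before and 7 after the event. Assigning the
straddling middle window by its midpoint is the one convention that yields
a balanced 7 + 7 split; windowing each 1 s half separately would give only
6 per side.

Within a window, coherence between every channel pair is estimated by the
multitaper method with time–bandwidth nw = 3 and k = 5 Slepian tapers — the
standard variance/resolution compromise for windows this short (the 256-tap
DPSS family is computed from the tridiagonal eigenproblem and cached). The
magnitude-squared coherence uses taper-averaged auto- and cross-spectra and
is averaged over the frequency bins falling inside the band (bin spacing
fs/256 ≈ 3.9 Hz), giving one scalar per pair per window: a 16 × 16
symmetric, unit-diagonal adjacency.

Short-window multitaper coherence is biased upward for independent signals
(roughly like 1/k); the package treats this as a property to verify, not to
correct, since all downstream contrasts are pre vs post under identical
estimator settings. The tests pin the floor empirically and check it
decreases with taper count.

## Surprise-guided threshold selection

Sparsification scans 100 candidate thresholds. "0 to 1 evenly divided into
100 tiers" is realized as the interior grid τ = i/101, i = 1..100, which
avoids the degenerate endpoints (τ = 0 keeps everything; τ = 1 keeps
nothing under the strict-inequality rule). At each τ, every trial × window
matrix is binarized and its community structure scored by discrete
hypergeometric Surprise: the −log₁₀ probability of at least the observed
number of intra-community edges if the graph's m edges were placed
uniformly among its M node pairs. The variant is the cumulative-tail form
of the Surprise literature; the asymptotic approximation is out of scope.
The tail is evaluated in log space, so S is stable far beyond the range
where the raw tail underflows.

The partition scored is the one found by a greedy Surprise maximizer —
singletons, then repeatedly the single merge or single-node relabel that
most increases S — because S should score the structure it is optimized
for, not a modularity-based surrogate. Equal-gain moves are broken by a
seeded RNG, re-seeded per matrix so results are invariant to the order in
which trials and subjects are stacked. Exhaustive enumeration over all
partitions at n ≤ 8 provides the test oracle; the greedy matches the global
optimum in well over 80% of random instances and never exceeds it.

The selected threshold is the argmax of grand-mean S across all windows,
trials and subjects of a band, ties resolved toward the smaller τ (more
edges retained). Scoring one aggregate matrix per trial would be an equally
defensible granularity; per-window scoring with grand averaging is adopted
because it matches the per-window feature tables downstream. The
percolation profile (mean largest-component fraction vs τ) is computed and
exported as a diagnostic only — the operative selection rule is the S
maximum, and no further coupling between the two methods is imposed.

## Network features and statistics

At the band's optimal τ each window graph contributes one row: average node
degree k̄ = 2m/N (isolated nodes stay in the graph, so N is the channel
count) and modularity Q of a greedy modularity-maximal partition (same
move set and tie-break policy as the Surprise search; if the search ends
below the all-in-one partition's Q = 0, that partition is returned
instead). Features are computed on the binarized graphs, matching the
sparsified-network construction, not on the weighted matrices.

Pre/post comparison is a two-group one-way ANOVA per (subject, band,
feature) — with two groups this is exactly the squared pooled t, which the
tests verify to 1e-9 — marked `**`, `*`, `n.s.` at 0.01/0.05. No
multiple-comparison correction is applied; cells are reported individually.
Each trial × window value is one observation by default, matching the
120 × 7 decoding granularity; a trial-mean pooling switch is provided for
analyses that prefer trials as the sampling unit. Summaries report mean ±
sample SD
(n − 1) to two decimals in a bands × before/after × subjects layout.

## Decoding

Per subject, each (trial, condition) contributes a row of the 7 per-window
values of a feature (120 × 7), or 14 columns for degree ⊕ modularity;
subjects stack to 480 rows. Three decoders run under stratified ten-fold
CV:

* **margin** — linear-kernel SVM, cost 1;
* **recurrent** — a single-layer tanh recurrent classifier (16 hidden
  units) reading the 7 windows as a temporal sequence (2 input channels
  when combined), sigmoid readout, trained 50 epochs with Adam at lr 1e-2,
  minibatch 16, fixed initialization seed;
* **tree** — CART, depth ≤ 5, minimum leaf 5.

Hyperparameters are small-data defaults chosen once for reproducibility,
not tuned. Standardization is fit on training folds only, preventing fold
leakage. Folds are stratified by condition (plain "ten-fold" leaves this
open; stratification keeps classes balanced); pooled folds across subjects
are the default, with subject identity available in the row metadata for
grouped variants. ROC curves pool held-out scores across folds — decision
values for the margin decoder, positive-class probabilities otherwise —
and AUC follows the half-tie trapezoid convention.

## The synthetic cohort: what it does and does not emulate

No public recordings exist for this paradigm, so the generator is a
first-class module. Per band it draws one latent band-limited Gaussian
source (band-pass filtered white noise, unit SD), mixed identically into
every channel with gain g_pre, switching instantaneously to g_post for the
second after each event — the instantaneous switch matches the binary
pre/post contrast being tested. Channels add private white noise
(sd 1 by default) and a common 50 Hz sinusoid (amplitude 1) to exercise the
notch. Defaults are the study conditions: 4 subjects × 60 valid trials × 16
channels, 1 s + 1 s epochs, and a planted beta coupling increase 0.3 → 0.8
with all other bands held at 0.3. The 0.3/0.8 pair is the package's chosen
"clearly detectable but not saturated" effect; no real-data coherence
magnitudes are published to calibrate against, and none is attempted.
Subject s derives its seed as master + s − 1: reproducible yet distinct.

What passing tests on this cohort demonstrate: the estimator chain recovers
planted coupling changes in the right direction (degree up, modularity
down, beta-band ANOVAs significant, decoders above chance). What they do
not demonstrate: performance on real NCL data — the generator has no 1/f
background, no spikes, no artifacts, no behavioural variability, and its
trials are already valid by construction. Real-data quantities (per-bird
means, p-values, AUC values) are therefore out of reach by design.

## Numerical and scale choices

* Strict inequality at binarization; τ grid interior to (0, 1).
* Zero-variance channels yield zero coherence with a warning; edgeless
  graphs give S = 0 and Q = 0 by convention (all logged).
* Degenerate ANOVAs (zero within-group variance) resolve to p = 1 or p = 0
  by the sign of the mean difference, with warnings.
* Tests and the acceptance study generate cohorts directly at 1 kHz — the
  generator's fast path — keeping the full study (4 × 60 trials, 100-tier
  sweep over ~3360 window graphs, nine cross-validated decoders) at a few
  minutes on one CPU; the 30 kHz path (broadband filter + decimation) is
  exercised on short signals. Monte-Carlo suites use 8–20 seeded
  replicates and 200–500 null simulations, sizes chosen to keep binomial /
  KS checks informative at α = 0.01.
* The community searches are implemented in C++ (Rcpp) because the
  threshold sweep scores hundreds of thousands of graphs; R-side exhaustive
  oracles keep the compiled code honest.

## Known limitations

Directed or lagged connectivity, weighted-graph Surprise, consensus or
multilayer thresholding, artifact rejection and clustering-coefficient /
path-length analyses are out of scope. The recurrent decoder is a compact
Elman-style network, not an LSTM; with 7-step sequences there is no long
dependency for gating to help with, and its role — exploiting temporal
order that the margin and tree decoders ignore — is preserved. Window
overlap (step = half window) means adjacent windows share data; windows are
nonetheless treated as independent observations, consistent with the
feature-matrix construction.
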