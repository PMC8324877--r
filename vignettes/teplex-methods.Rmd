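---
title: "Rule-resolved transfer entropy and the multiplex brain network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-resolved transfer entropy and the multiplex brain network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teplex)
```

## The model

`teplex` treats each brain region's BOLD time course as a stream of
discrete events. After per-region z-scoring (population S.D., so the
transform is idempotent), a symmetric threshold maps the signal to
three states: activation (1) when the signal exceeds the positive
threshold, deactivation (−1) below the negative threshold, and
null-activation (0) in between. Deactivation is kept distinct from
null-activation so that anti-phase interactions remain visible. Four
thresholds — 0.25, 0.50, 0.75 and 1 S.D. — trade event abundance
against event sharpness; the selection statistics are anchored at the
1 S.D. level, where only clear excursions survive.

For an ordered region pair (A, B) the transfer entropy with one-step
histories (k = l = 1),

$$T_{A \to B} \;=\; \sum_{a,b,c \in \{-1,0,1\}}
  \hat p(B_{n+1}{=}c,\, A_n{=}a,\, B_n{=}b)\,
  \ln \frac{\hat p(B_{n+1}{=}c \mid A_n{=}a, B_n{=}b)}
           {\hat p(B_{n+1}{=}c \mid B_n{=}b)},$$

is estimated with plug-in frequencies over the $T-1$ transitions and
decomposed into its $3^3 = 27$ summands. Each summand, indexed by the
state triple $(A_n, B_n, B_{n+1})$, is a *rule*: a concrete,
falsifiable causal hypothesis about how the source's state shifts the
target's next state away from what the target's own past predicts. The
package asserts (and tests to $10^{-10}$) that the unclamped rule
contributions sum exactly to the brute-force transfer entropy.
Negative contributions are clamped to zero — they indicate
misinformative state combinations, which are outside the model's scope
— and a rule whose antecedent pair never occurs contributes exactly
zero. The one-step history makes the comparison term a first-order
Markov prediction; with a repetition time of 2 s per volume, one step
spans 2 s of hemodynamics, so the estimated interactions are slow by
electrophysiological standards (a stated limitation, not a defect of
the estimator).

### Statistical screening

All temporal structure, and hence all information transfer, is
destroyed by independently permuting each region's time order, while
the per-region state marginals are preserved exactly. This
reshuffling null (default 100 replicates) backs two tests at the
highest threshold:

* a group-level right-tail Welch test of the per-subject rule sums
  against the null sums, Bonferroni corrected across the 27 rules;
* per-subject right-tail Welch tests of pair-level values against the
  pooled null pair statistics, Bonferroni corrected across all tests
  performed, yielding the fraction of subjects significant per rule.

On real BOLD data the core rules also show strictly increasing total
TE and across-subject MSE over the four thresholds; the package
computes both flags, and by default a rule is selected only when both
trends hold *and* the group test passes (`trend = "both"`). The trend
flags are a property of real signals in which genuine events sharpen
as the threshold rises. The synthetic generator's memoryless
background does not reproduce that phenomenon — on simulated data the
flags reflect finite-sample bias, not coupling — so every synthetic
analysis in this package (including the bundled demo) uses
`trend = "none"` and relies on the null-based test alone. With eight
or more synthetic subjects the group test is well calibrated (measured
family-wise false-positive rate ≈ 2.5% at nominal 5%); with four or
fewer the skewed, clamped sums make the small-sample Welch
approximation anti-conservative, which is why the type-I test
conditions use eight subjects.

### The functional taxonomy and the multiplex hierarchy

The eight core rules pair up under a global sign flip and map onto
four functional classes — ActS, ActO (activate the target to the
same/opposite state as the source) and TfS, TfO (turn the target off
from the opposite/same state). The mapping is fixed; `label_rules()`
refuses anything outside the eight. Pearson correlation of the rules'
subject-mean link profiles followed by average-linkage clustering on
$1 - r$ recovers the nesting empirically: sign partners join first,
then the same-state (G1) and opposite-state (G2) groups.

Each class matrix — the ordered-pair sum of its two rules' local TE at
the chosen threshold — is one α layer of a directed weighted multiplex
(row = source, column = target, zero diagonal). Entrywise sums give
the β layers S = ActS + TfS and O = ActO + TfO, and the γ layer
T = S + O; the hierarchy identity T = ActS + TfS + ActO + TfO is
asserted to $10^{-12}$. Layer descriptors are the total weight and the
off-diagonal connection density (denominator $N(N-1)$, because
self-transfer is undefined).

### Network indexes

**Reciprocity.** The raw weighted reciprocity between layers $W^{[1]}$
and $W^{[2]}$ is the min-overlap ratio
$r = \sum_{i \ne j} \min(W^{[1]}_{ij}, W^{[2]}_{ji}) \big/
\sum_{i \ne j} (W^{[1]}_{ij} + W^{[2]}_{ji})/2$ — the fraction of
weight mirrored by reverse links; the single-layer case is ordinary
weighted reciprocity and the two-layer case multireciprocity. The
reciprocity index rescales $r$ against a null ensemble,
$(r - r_0)/(1 - r_0)$ above the null mean $r_0$ and $(r - r_0)/r_0$
below, landing in $[-1, +1]$ with sign semantics reciprocation /
independence / avoidance. The exact published normalization lives in
supplementary material that is not available; this two-branch form
preserves the documented range and sign contract and is the one the
tests pin down.

**Triads.** Closed three-node subgraphs come in two kinds — Cycle
(i→j→k→i) and Flux (source→middle, middle→sink, source→sink) — with a
layer assigned to each link. The order (0, 1, 2) is the number of
distinct layers minus one. Cycle assignments are canonicalized under
cyclic rotation; Flux positions are functionally distinguishable, so
every assignment counts. The resulting census — 4/4, 12/36, 8/24
Cycle/Flux patterns at orders 0/1/2 over the four α layers, 2/2 and
2/6 over β, 1/1 over γ — is what `scripts/acceptance.R` recomputes. An
instance requires all three links nonzero in their assigned layers and
no reciprocal link within the union of the pattern's layers (double
links are not allowed; the exclusion is enforced within the pattern's
own layers, the narrowest reading of the rule). Instance intensity is
the geometric mean of the three weights, coherence the geometric over
the arithmetic mean (in $[0, 1]$ by AM–GM); the network level sums
instance intensities and averages coherences. Because subgraph indexes
are global descriptors, the pipeline computes them per subject and
tests the across-subject distribution against pooled per-subject
weight randomizations (right-tail Welch, Bonferroni within each
kind × order family); a single-network empirical-tail variant
(`subgraph_significance()`) is also provided. The ordered-triple scan
is implemented in C++ (it is $O(N^3)$ per pattern) and is verified
against an exhaustive R oracle on all networks with $N \le 7$.

**Centrality.** A node is central in a layer, per strength kind (in /
out / total), when its strength is strictly above the layer's third
quartile (linear-interpolation quantile). Across the layers of one
hierarchy level, the presence fraction classifies nodes as local
(≤ 0.25), intermediate (0.25–0.75] or multiplex (> 0.75) central
nodes; a node central nowhere is unclassified. The bands partition
(0, 1] without gaps, which the tests assert explicitly.

**Modularity.** Newman's directed form with strengths,
$Q = \frac{1}{m}\sum_{ij}\bigl[W_{ij} - s_i^{\mathrm{in}}
s_j^{\mathrm{out}}/m\bigr]\,\delta(c_i, c_j)$, is maximized by a
seeded, deterministic Louvain-style search (local moves with
lowest-index tie-breaking, then aggregation). $Q$ of the
single-community partition is exactly zero, the implementation matches
a double-loop oracle to $10^{-12}$ and agrees with igraph's directed
modularity. Significance re-optimizes on randomized matrices: uniform
off-diagonal weight permutation for dense averaged matrices (the
pipeline's group-level case), in-strength-preserving within-column
permutation for sparse subject-level layers. Centrality and modularity
run on across-subject mean matrices; reciprocity and triad indexes run
per subject — mirroring the global/local split of the reference
procedure.

## Scrubbing

Framewise displacement above 0.2 mm flags a scan; flags are dilated
one scan back and two forward (4 scans × TR 2 s = 8 s), and a subject
with more than 30 bad scans (> 60 s) is excluded. Scrubbed scans are
spliced out of the time axis, and — a choice the source leaves open —
transitions bridging a splice are excluded from the TE counts, since a
transition across a gap is not a 2-s step. Boundary convention
throughout: strictly above the threshold counts, the boundary itself
does not.

## The synthetic generator

The generator is a test harness, not a model of brain dynamics. Each
node draws i.i.d. states from a baseline triple (default
(0.2, 0.6, 0.2) over (−1, 0, 1), keeping suprathreshold events sparse
as after 1-S.D. ternarization); a planted coupling
(source, target, rule, p) overrides the target's next draw with the
rule's consequent, with probability p, whenever the rule's antecedent
pair holds. Couplings onto one target with jointly satisfiable
antecedents and different consequents are rejected as conflicting.
Known analytic limits anchor the estimator: under copy dynamics
$B_{n+1} = A_n$ with A uniform on {0, 1}, the rule (1,0→1) contributes
exactly $0.25 \ln 2$; under a single such coupling the stationary
target marginal shifts to $P(B{=}1) = 3/5$ and the same rule's limit
is $0.2 \ln(4/3)$ — both reproduced to 0.01 at $10^5$ steps and
cross-checked by a frequency-counting oracle.

The continuous wrapper renders state $s$ as $1.5 s$ plus Gaussian
noise, so z-scoring and 1-S.D. thresholding invert it; with noise
S.D. ≤ 0.2 and the sparse default baseline, recovery exceeds 99%
(with a uniform state baseline the recovery margin shrinks, because
the row S.D. grows toward the ±1.5 amplitudes). What the generator
deliberately does not emulate: hemodynamic convolution, autocorrelated
noise, head motion, and the increasing-with-threshold TE/MSE trends of
real BOLD. Passing tests therefore demonstrate correctness of the
estimators and metrics, not realism of the dynamics.

The random multiplex generator draws each unordered dyad's state
(both / one / no direction) from a density and a reciprocity bias in
$[-1, 1]$: at +1 every link is reciprocated, at −1 (density ≤ 0.5)
none is; infeasible density/bias pairs are rejected rather than
silently clipped.

## Numerical and design choices

* Natural logarithm throughout; plug-in estimates with no pseudocounts;
  zero-denominator conditionals contribute zero (they can only occur
  with zero numerator).
* The Bonferroni family is always the number of tests actually
  performed and is reported in the selection object.
* The null ensemble stores replicate pair sums and streaming
  pair-level moments; the full replicate tensor is kept only when it
  fits comfortably in memory (it is asserted against small cases in
  the tests).
* Randomization p-values use $(1 + k)/(1 + n)$, so they are never
  exactly zero; with a single replicate the attainable values are
  {0.5, 1}.
* Degenerate (zero-variance) test inputs fall back to a direct
  location comparison, flagged in the output.
* All seeded operations snapshot and restore the caller's RNG state;
  stage seeds derive deterministically from one master seed.

## Problem sizes

The test suite works at deliberately small scales chosen for
exhaustive verifiability: oracle comparisons on sequences up to length
500 (100 cases), analytic limits at $10^5$ steps, triad oracles on all
networks with at most 7 nodes (100 cases), planted-rule recovery at 15
nodes × 5000 steps over 10 seeds, type-I checks over 20 seeds with 8
subjects each, and community recovery on 24-node three-block networks.
The bundled demo runs the full pipeline at the reference acquisition
scale — 10 subjects × 90 regions × 240 volumes — twice, to assert
byte-identical reports under a fixed seed.

## Limitations

Histories longer than one step (k, l > 1), continuous (kernel or
nearest-neighbour) TE estimators, misinformation (negative TE)
analysis, open triad motifs, subgraphs beyond three nodes, interlayer
coupling links and overlapping communities are out of scope. The
dataset-dependent magnitudes of the reference analysis (which depend
on a specific cohort) are not reproduced; the package reproduces the
machinery, its combinatorial invariants and its analytic limits.
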