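# teplex

State-resolved transfer-entropy rules and multiplex network analysis of
resting-state fMRI ROI time series.

## The problem

Functional connectivity measured by temporal correlation is symmetric:
it cannot say whether region A drives region B or the reverse, and it
collapses qualitatively different interactions (co-activation,
anti-activation, silencing) into a single number. `teplex` implements a
directed, state-resolved alternative for researchers working with
region-level BOLD time series:

1. **Ternarization.** Each region's z-scored signal is reduced to
   events — activation (1), deactivation (−1), null-activation (0) —
   by symmetric thresholds at 0.25, 0.50, 0.75 and 1 S.D.
2. **Interaction rules.** For an ordered region pair (A, B), the
   transfer entropy with one-step histories (k = l = 1),

   T(A→B) = Σ p(B_{n+1}, A_n, B_n) · ln [ p(B_{n+1} | A_n, B_n) /
   p(B_{n+1} | B_n) ],

   is decomposed into its 3³ = 27 summands, one per state triple
   (A_n, B_n, B_{n+1}). Each summand — a "rule" — quantifies one
   concrete causal hypothesis (e.g. *A active + B silent → B active*),
   estimated by plug-in frequencies and clamped at zero. Rules are
   screened against a time-reshuffling null that preserves each
   region's state marginals exactly.
3. **Functional taxonomy.** The eight surviving rules pair up (by
   global sign flip) into four classes: **ActS** / **ActO**
   ((de-)activate the target to the same / opposite state as the
   source) and **TfS** / **TfO** (turn the target off when source and
   target are in opposite / the same state).
4. **Multiplex network.** The four class matrices are the α layers of
   a directed weighted multiplex on the 90 regions (8100 ordered-pair
   slots per layer); β aggregates S = ActS + TfS and O = ActO + TfO,
   and γ their total T. The network is characterized by weighted
   reciprocity and multireciprocity (normalized to [−1, 1] against
   null models), a Cycle/Flux triad-motif census scored by intensity
   (geometric-mean weight) and coherence (geometric / arithmetic mean),
   strength-quartile centrality classes (local / intermediate /
   multiplex), and Newman's directed weighted modularity
   Q = (1/m) Σ [W_ij − s_i^in s_j^out / m] δ(c_i, c_j), all with
   randomization-based significance.

A synthetic-data module generates ternary dynamics with planted
rule-driven couplings, continuous BOLD-like wrappers and random
multiplex networks, so the entire pipeline is testable without any
external dataset.

## Worked example

Plant the ActS rule (1,0→1) on five node pairs, estimate and select
rules, build the multiplex and score it:

```r
library(teplex)

cps <- lapply(1:5, function(i) coupling(2*i - 1, 2*i, rule_spec(1, 0, 1), 0.9))
subjects <- lapply(1:8, function(s) {
  states <- generate_ternary_dynamics(
    generator_config(16, 600, baseline = c(0.2, 0.6, 0.2),
                     couplings = cps, seed = 100 + s))
  wrap_continuous(states, amplitude_sd = 0.25, seed = 200 + s)
})

tensor <- build_rule_tensor(subjects)            # pair x rule x threshold TE
null   <- reshuffle_null(subjects, n_replicates = 100, seed = 1)
rule_selection(tensor, null, trend = "none")
#> <rule_selection> 1 rule(s) selected at alpha = 0.05 (trend: none)
#>    1,0>1

nets <- lapply(build_rule_layers(tensor, subject_reduction = "per-subject"),
               add_hierarchy)
layer_descriptors(nets)
#>   layer level    weight  weight_sd   density  density_sd
#> 1  ActS alpha 1.5078326 0.07908082 0.7234375 0.024289252
#> 2   TfS alpha 0.7237720 0.05756124 0.7359375 0.018221725
#> 3  ActO alpha 1.0993325 0.11681518 0.7343750 0.022132134
#> 4   TfO alpha 0.7654355 0.04833973 0.7588542 0.034173743
#> 5     S  beta 2.2316046 0.09066935 0.9260417 0.013684005
#> 6     O  beta 1.8647680 0.13548162 0.9343750 0.018865386
#> 7     T gamma 4.0963727 0.11955537 0.9994792 0.001473139

pat <- enumerate_triad_patterns("ActS", 0, "Flux")
score_subgraph(nets[[1]], pat[1, ])
#> <subgraph> Flux ActS/ActS/ActS  instances 31  I = 0.1519  C = 0.6799

weighted_reciprocity(nets[[1]]$layers$ActS, n_null = 100, seed = 2)
#> <reciprocity> r = 0.3513  RI = +0.0523  p = 0.1782 (null n = 100)
```

The selection correctly singles out the planted rule; only about a
third of the ActS layer's weight is mirrored by reverse links (raw
ratio r), and after normalization against a strength-preserving null
the reciprocity index is indistinguishable from independent behaviour
(RI ≈ 0, p = 0.18), as expected for this generator. The 31 Flux
instances have coherence 0.68: their three link weights are of
comparable size.

`run_demo(seed, out_dir)` runs the whole pipeline at the reference
acquisition scale (10 subjects × 90 regions × 240 volumes) and writes
every table with a hashed manifest. A command-line wrapper is installed
at `inst/cli/teplex-pipeline.R` with `simulate`, `run` and `demo`
subcommands.

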