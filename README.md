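# scanmarkov

Markov-chain analysis of eye-tracking fixation sequences over areas of
interest (AOIs).

## The problem

In visual-search eye-tracking paradigms — for example toddlers viewing
displays that contain one face among several objects — each recorded
fixation falls into one of three gaze states:

- **FACE**: the fixation hit the face AOI,
- **OBJECT**: it hit one of the object AOIs,
- **NO_STIMULUS**: it stayed on the monitor but inside no AOI.

Treating the per-display fixation sequence of each participant as a
realisation of a first-order Markov chain, a group of participants (say,
toddlers with autism spectrum disorder, ASD, versus typically developing
toddlers, TD) is summarised by a 3×3 row-stochastic **transition matrix**
*P*, where *p·ᵢⱼ* is the probability that a fixation in state *i* is
followed by one in state *j*. The package estimates, compares and
visualises these chains:

- **MLE** of the transition matrix from pooled transition counts:
  *p̂ᵢⱼ = nᵢⱼ / Σᵤ nᵢᵤ*, with per-cell standard errors
  (*seᵢⱼ = p̂ᵢⱼ/√nᵢⱼ*, or the binomial form √(p̂(1−p̂)/nᵢ·)) and
  normal-approximation confidence intervals truncated to [0, 1].
- **Steady state**: the stationary vector π with πP = π, Σπ = 1 — the
  long-run occupancy of the three gaze states — with parametric
  multinomial-bootstrap percentile intervals.
- **Markov-property test**: likelihood-ratio G² of first- vs second-order
  dependence from pooled state triples.
- **Divergence (homogeneity) test** in the Kullback tradition: with
  pooled estimate p̂⁰, the statistic 2 Σ_g Σᵢⱼ n⁽ᵍ⁾ᵢⱼ ln(p̂⁽ᵍ⁾ᵢⱼ/p̂⁰ᵢⱼ)
  compares two groups' chains on a chi-square scale (df = 8 for two
  3-state groups under the default convention).
- **Per-cell difference flags** (disjoint confidence intervals),
  **departure probabilities** (1 − p̂ᵢᵢ), baseline demographics
  (summary-statistics t-test, Fisher's exact test), and a fully seeded
  **synthetic study generator** (2 groups × 18 participants × 32 displays
  by default) so the whole pipeline is testable without any recordings.

Intended users: researchers analysing AOI fixation exports (e.g. Tobii
fixation tables) who want a tested, scriptable implementation of this
chain-comparison workflow.

## Worked example

```r
library(scanmarkov)

# Reference chains for the two toddler groups
ref <- gaze_reference_matrices()
steady_state(ref$TD)$pi
#>        FACE      OBJECT NO_STIMULUS
#>   0.2492780   0.6513148   0.0994072
steady_state(ref$ASD)$pi
#>        FACE      OBJECT NO_STIMULUS
#>   0.1869965   0.5857307   0.2272727

# Simulate a study-scale dataset, rebuild sequences, re-estimate
events <- simulate_study(sim_config(seed = 20,
  fixations_per_display = list(kind = "fixed", mean = 50)))
seqs   <- build_sequences(events)
fit    <- estimate_transition_matrix(count_transitions(seqs, group = "ASD"))
round(fit$p_hat, 2)
#>             FACE OBJECT NO_STIMULUS
#> FACE        0.36   0.48        0.15
#> OBJECT      0.15   0.70        0.15
#> NO_STIMULUS 0.14   0.37        0.49

# Compare the two groups' chains
div <- divergence_test(count_transitions(seqs, group = "TD"),
                       count_transitions(seqs, group = "ASD"))
tidy(div)
#> # A tibble: 1 × 5
#>   statistic    df   p.value method                            convention
#>       <dbl> <dbl>     <dbl> <chr>                             <chr>
#> 1     1290.     8 3.89e-273 Kullback divergence test of chai… paper_compatible
```

The TD chain spends its long run mostly on objects (≈0.65) and faces
(≈0.25) and rarely off-stimulus (≈0.10); the ASD chain shifts mass to the
no-stimulus state (≈0.23). The divergence test rejects homogeneity of the
two chains decisively at this sample size.

Baseline demographics from published summaries:

```r
t_test_summary(29.7, 4.84, 18, 30.7, 3.04, 18)$statistic  # -0.742
fisher_exact_2x2(matrix(c(4, 14, 7, 11), 2, byrow = TRUE))$p.value  # 0.471
```

Pipeline commands (`run_simulate()`, `run_estimate()`, `run_compare()`,
`run_baseline()`) write JSON/TSV bundles plus a run manifest; a thin CLI
wrapper lives at `inst/cli/scanmarkov.R`.

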