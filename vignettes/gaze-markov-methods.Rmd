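---
title: "Modelling AOI fixation sequences as Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling AOI fixation sequences as Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanmarkov)
```

## The model

Each fixation event recorded by an eye tracker during a display is coded
into one of three gaze states — `FACE`, `OBJECT`, `NO_STIMULUS` — by the
priority rule "face hit beats object hit beats no hit". The per-display
sequence of coded states for one participant is treated as a realisation
of a first-order, time-homogeneous Markov chain on these three states.
Pooling every participant of a group gives one chain per group, described
by a 3×3 row-stochastic transition matrix \(P\) with entries
\(p_{ij} = \Pr(\text{next state } j \mid \text{current state } i)\).

Assumptions worth making explicit:

- **First-order dependence.** The next fixation's state depends only on
  the current one. This is testable, and `verify_markov_property()` is the
  test: a likelihood-ratio \(G^2\) comparing second-order conditional
  distributions \(\hat p(k \mid i,j) = n_{ijk}/n_{ij\cdot}\) against
  first-order ones \(\hat p(k \mid j) = n_{\cdot jk}/n_{\cdot j \cdot}\),
  over state triples pooled within display blocks.
- **Pooling across participants.** One chain summarises a whole group;
  there are no per-participant random effects. This matches the
  group-level reporting convention of the applied literature the package
  follows, and is a real limitation for heterogeneous groups.
- **No transitions across displays.** A central fixation cross separates
  displays and resets gaze, so sequences are segmented per display and
  pairs never bridge the boundary.
- **Self-transitions are data.** Consecutive fixations in the same AOI
  are separate events and count as \(i \to i\) transitions; collapsing
  runs would empty the diagonal, which in real gaze data carries most of
  the signal (object-to-object refixation probabilities near 0.7).

## Estimation

With pooled counts \(n_{ij}\), the MLE is the row-relative frequency
\(\hat p_{ij} = n_{ij} / \sum_u n_{iu}\). Two standard-error conventions
are implemented:

- `se_mode = "paper"` (default): \(\widehat{se}_{ij} = \hat p_{ij} /
  \sqrt{n_{ij}}\). This is the form quoted alongside the MLE in the
  applied reports this package mirrors. It is unusual (it shrinks with
  the cell count rather than the row total, and is undefined at
  \(n_{ij} = 0\), where we set it to 0 with a degenerate interval), but
  published tables appear to rest on it, so it is the default and is
  labelled in every output.
- `se_mode = "binomial"`: \(\sqrt{\hat p_{ij}(1-\hat p_{ij}) /
  n_{i\cdot}}\), the row-multinomial form a statistician would expect.

Intervals are the normal approximation \(\hat p \pm z \cdot
\widehat{se}\), truncated to \([0,1]\) — consistent with the symmetric
brackets of published transition tables. Published tables do not state
which convention produced their intervals; both are exposed so either can
be reproduced.

## Steady state

The stationary vector solves \(\pi P = \pi\), \(\sum_i \pi_i = 1\). The
solver replaces one row of the singular system \((P^\top - I)\pi = 0\)
with the normalisation constraint and solves directly; power iteration is
available as an independent cross-check (`method = "power"`). Before
solving, irreducibility is verified by boolean reachability on the
positive-entry graph; a reducible chain is an error, never a silent pick
among multiple stationary vectors. The solution is validated against
\(\max_i |(\pi P - \pi)_i| < 10^{-10}\).

Published steady-state tables carry confidence intervals without naming a
method. We chose a **parametric multinomial bootstrap**: each origin row
of the count matrix is resampled as \(\text{Multinomial}(n_{i\cdot},
\hat p_{i\cdot})\), the chain is re-estimated, its stationary vector
recomputed, and percentile intervals taken (default 2000 draws, seeded).
We make no claim that this reproduces any published interval widths; the
test suite checks per-component coverage near the nominal level instead.

## Group comparison

`divergence_test()` implements the Kullback-style homogeneity test: with
the pooled estimate \(\hat p^0\) from the summed counts, the statistic is
\[
2 \sum_{g} \sum_{i,j} n^{(g)}_{ij}
\ln\!\frac{\hat p^{(g)}_{ij}}{\hat p^{0}_{ij}},
\]
with \(0 \ln(0/x) \equiv 0\) (a pooled cell can only be zero when both
group cells are), referred to a chi-square upper tail.

**Degrees-of-freedom conventions.** The classical likelihood-ratio
counting gives \((G-1)\,m(m-1) = 6\) for two groups of three states, and
\(m(m-1)^2 = 12\) for the order test. Applied reports built on the
`markovchain` package instead print \((G-1)(m^2-1) = 8\) and \(m^3 = 27\).
Both conventions are implemented; `"paper_compatible"` is the default so
reported dfs match the applied literature, and `"standard"` is used
wherever calibration matters (the statistic is identical; only the
reference distribution changes). The package's own type-I-error
simulations use the standard counting, which is the calibrated one; the
paper-compatible df is deliberately conservative.

Per-cell group differences are flagged by `cell_difference_flags()` when
the two groups' intervals for a cell are disjoint — the rule behind the
asterisks of published comparison tables. Disjointness depends on the
interval convention, so flags inherit whatever `se_mode` produced the
fits.

## The synthetic study generator

`simulate_study()` emulates the study design the analysis assumes, so the
whole pipeline is testable without recordings: two groups (`TD`, `ASD`)
× 18 participants × 32 five-second displays. Choices and their
rationale:

- **Ground truth**: the reference group matrices of
  `gaze_reference_matrices()`, whose stationary vectors are ≈(0.25, 0.65,
  0.10) and ≈(0.19, 0.59, 0.22).
- **Fixations per display**: truncated Poisson, mean 10, minimum 2. Only
  the 5 s exposure and the ≥100 ms fixation criterion are documented
  upstream; ~10 fixations of 300–500 ms fill 5 s plausibly, and the
  floor of 2 guarantees at least one transition per display. Acceptance
  checks depend on this only through total transition counts.
- **Initial state per display**: the group chain's stationary
  distribution, because the central fixation cross between displays
  carries no AOI information; any probability vector can be configured.
- **Object AOIs**: displays 1–16 carry 3 object AOIs and 17–32 carry 5,
  a fixed stand-in for the counterbalanced 4-item/6-item display sets;
  an `OBJECT` fixation hits one uniformly chosen object column.
- **Seeding**: one global seed is split into per-(group, participant,
  display) child seeds by a Lehmer-style integer mix modulo
  \(2^{31}-1\), so enlarging the design never perturbs previously
  generated units, and the simulate → write → read → estimate chain is
  bit-reproducible.

What the generator does **not** emulate: fixation durations tied to
oculomotor dynamics, saccade kinematics, pixel coordinates and AOI
geometry, participant heterogeneity (every participant of a group shares
the group's matrix), or drift of the chain over the session. Passing
recovery and calibration tests on this generator therefore shows the
estimators and tests are correct under the model's own assumptions — not
that real toddler gaze is first-order Markov or homogeneous across
children.

## Numerical choices and problem sizes

- Stochasticity checks use tolerance \(10^{-8}\) (user matrices must be
  cleaner, \(10^{-9}\), in simulation configs); stationary residuals must
  pass \(10^{-10}\); estimates row-sum to 1 within \(10^{-12}\).
- Zero rows (a state never departed) are hard errors naming the state,
  both in estimation and in the divergence test.
- Ties/degeneracies: multi-AOI hits resolve FACE > OBJECT with a warning;
  a zero margin in the 2×2 Fisher table returns p = 1 with a warning.
- Simulation sizes were fixed as part of the test design: 200,000
  transitions for long-run recovery (MC error ≈ 0.003 per cell, well
  inside the ±0.01 bands rounded published inputs justify); 200
  replications × 2,000 transitions per group for the divergence test's
  type-I and power checks; 200 × 5,000 for the order test's calibration;
  100 × 3,000-transition datasets for bootstrap coverage. The recovery
  test of the full study pipeline lengthens displays to 50 fixations so
  the rarest origin state (≈10% occupancy) accumulates enough
  transitions for a 0.02 band.

## Known limitations

- The printed \(\chi^2\) statistics of the motivating applied study
  (order tests 36.2/35.9, divergence 28.1) cannot be recomputed without
  the raw sequences, which were never deposited; the package matches the
  df conventions and the qualitative behaviour (decisive rejection at
  study-scale sample sizes) instead.
- The "paper" standard error is reproduced as printed, not endorsed; use
  `"binomial"` for new analyses.
- Only two-group comparisons are implemented; no stationarity-over-time
  test; no continuous-time chains; no higher-order fitting (higher order
  is only tested against).
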