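---
title: "From gating states to water flux: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gating states to water flux: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aquaflux` quantifies how the conformations of pore-lining residues
modulate single-file water permeation through aquaporin channels, with
the *E. coli* aquaglyceroporin GlpF as the built-in system. This
vignette explains the model and procedure, the tunable parameters and
their defaults, what the synthetic generators do and do not emulate,
and the numerical choices a maintainer should know about.

## Counting permeation events

Water oxygens are tracked through a cylinder aligned with the membrane
normal (z), of length 2.2 nm and radius 1.5 nm, centred on each
protomer's centre of mass after every frame has been superposed onto
the reference structure by a mass-unweighted Kabsch fit of the
transmembrane-bundle C-alpha atoms (residues 7-35, 41-63, 69-79,
83-119, 145-167, 178-196, 204-217, 232-255 per chain). Each frame
assigns each water one of four compartments: `below` or `above` the
axial slab, `inside` (within slab and radius), or `outside_radius`.

An event is a strict cap-to-cap traversal: one cap, then at least one
`inside` frame, then the opposite cap. Touching `outside_radius` voids
the ongoing attempt (the state machine resets to the last cap visited);
revisiting the entry cap restarts the transit clock, so the entry time
is the first `inside` frame of the successful attempt. Events are
timestamped at exit, which gives every event a unique window when flux
is counted in disjoint half-open windows. By convention the periplasm
sits at negative z and direction +1 means a below-to-above crossing.

The 1.5 nm cylinder is deliberately generous, so a water can pass
around the protein yet stay inside it. The published analysis corrected
such mis-assignments with an unpublished script; this package
operationalises the correction as a *containment filter*: an event is
discarded if its radial excursion exceeds `r_sf` (default 0.4 nm)
anywhere in the single-file slab `|z| <= z_sf` (default 0.8 nm). Both
criteria are configurable, and removed events are retained in an
attribute for reporting. On synthetic trajectories with planted
crossings, half-crossers and radial escapees, the filtered counter
recovers the planted count exactly.

Whether windowed flux should be the total bidirectional event count or
the directional difference is genuinely ambiguous at equilibrium; the
magnitudes reported for GlpF (tens of events per 100 ns) match total
counts, so `total` is the default and `net` is exported alongside it.

## Gating-state classification

Nine residues carry built-in state definitions (`gating_registry()`):

* **W48** - dihedral CA-CB-CG-CD1 on [-180, 180): `blocked`
  [-180, 0), `restricted` [0, 70), `open` [70, 180). The crystal-like
  open state sits at 103 degrees.
* **R206** - the torsion of the four atoms CA-CB-CG-CZ on [0, 360)
  (the atoms are deliberately non-consecutive; the descriptor is the
  torsion of the four points), seven bins with edges 0, 50, 115, 160,
  210, 240, 290, 360; the crystal-like state is [290, 360) (311 degrees
  in the crystal).
* **F200-P196** (0.37 nm), **A201-W48** (0.35), **M202-L21** (0.4),
  **N203-I187** (0.3), **N68-V52** (0.45), **H66-I183** (0.35),
  **V173-L75** (0.4) - minimal side-chain distances with one threshold
  each; below threshold (strict) is the in-pore/near/blocking state,
  at or above is the reference.

Distances default to heavy atoms from C-beta outward, because the
crystal structure that calibrates the thresholds has no hydrogens; a
hydrogen-including policy is available since a simulation-topology
mindist tool would typically include them, which can shift values by
roughly 0.05-0.1 nm. Thresholds are strict on the "less than" side and
bins are half-open `[low, high)`, so a value exactly at a threshold
belongs to the upper bin. Classification of the reference structure
yields the reference (open) state for all nine residues - the crystal
is the open pore.

The packaged reference structure is *synthetic*: the experimental
deposition is not redistributable inside the package, so
`synthetic_reference_structure()` builds the sixteen needed residues
from idealised internal coordinates and calibrates them to the
published crystal geometry (W48 dihedral 103 degrees, R206 dihedral 311
degrees, M202-L21 distance 0.82 nm, all descriptors in the open state).
Geometry checks against it therefore validate the measurement and
classification code, not the deposition itself.

## Interval pairing

Property windows of 5 ns are paired with 5 ns flux windows lagged by
3 ns (2 ns overlap), encoding that conformation precedes transport; the
lag matches mean transit times of roughly 3 ns. The stride between
pairs is not stated by the study; the package default of 10/3 ns is
back-computed so a 2000 ns analysis range yields exactly 599 pairs,
which together with 24 pores (3 variants x 2 replicas x 4 chains)
reproduces the published 14,376 rows. Pairs advance while the
*property* window fits inside the analysis range; the two trailing flux
windows then overhang the end by up to the lag and are clipped there.
The alternative rule (requiring the full pair to fit) gives 598
windows, contradicting the published count; this choice is recorded in
the scheme metadata. Overlapping pairs induce autocorrelation between
rows; following the original analysis, no correction is applied, which
is a known limitation of the row-level uncertainty.

Phase fractions per window are computed by cumulative state counts, so
assembling 24 x 599 rows over nine residues takes seconds. For each
residue with k states only k-1 phase-percentage columns enter the model
(fractions sum to one); the reference (open) state is dropped. A
diagnostic mode keeps all k columns to verify closure.

## The state-flux model

Flux counts are overdispersed relative to Poisson, so the likelihood is
negative binomial with mean `mu` and shape `phi`
(variance `mu + mu^2/phi`), log link:

    log mu_ij = alpha + sum_{r,p != ref} beta_{r,p} x_{r,p,ij} + u_j,
    u_j ~ Normal(0, sigma_u).

The varying intercept `u_j` absorbs baseline permeability differences
between pores; pore identity (variant x replica x chain) is the
grouping unit, with variant recorded as metadata (an optional fixed
effect can be added through the formula interface; whether the original
analysis included it at the population level is not determinable from
the text). Priors are weakly informative: `alpha ~ t(3, log mean(y),
2.5)`, `beta ~ Normal(0, 2.5)`, `sigma_u ~ half-t(3, 0, 2.5)`, and
`1/sqrt(phi) ~ Exponential(1)` - a standard set whose influence is
negligible at 14,376 rows.

### Sampling

The posterior is sampled by independence Metropolis-Hastings built on a
Laplace approximation: the joint mode of (alpha, beta, u, log sigma_u,
log phi) is found by bounded BFGS with analytic gradients, the
curvature at the mode gives a multivariate Student-t proposal (df 8,
covariance matched to the Laplace covariance, widened by 1.4 along
log sigma_u whose marginal is right-skewed and weakly funnel-coupled to
the u's), and each of the default 2 chains runs 2000 iterations of
which 1000 are warmup. Each iteration applies the independence kernel
five times, which keeps the lag-1 autocorrelation low at the fixed
iteration budget. The centred parameterisation is used throughout: with
hundreds of windows per pore the group deviations are well identified
and the posterior is close to Gaussian, which is the regime this
sampler is designed for. With few observations per group (a handful of
windows per pore) the Laplace proposal degrades; acceptance rates and
diagnostics make that visible rather than silent.

Convergence is checked per parameter with split-Rhat (each chain
halved, classic between/within variance ratio) and effective sample
size (coda's spectral estimator), with thresholds Rhat <= 1.01 and
ESS >= 400 - current MCMC practice; the original study names the
measures but no cutoffs. `phi` is reported honestly as weakly
identified (low ESS) when the data are effectively Poisson.

The log of the group scale and of the shape are kept in a bounded box
during optimisation (`log phi <= 14`), because for underdispersed
counts the likelihood is flat in the shape and the mode would otherwise
run away; the upper bound is operationally Poisson. Degenerate input
(all-zero counts) is rejected with a diagnostic rather than fitted.

Tests cross-check the fit against glmmTMB's marginal-likelihood
estimates on the same data (coefficients agree to well under 0.1 on the
log scale at small scale) and verify that predictions are invariant to
which state is chosen as the reference encoding. glmmTMB is only ever
an oracle in tests, never the implementation.

### Prediction

`predict_state_flux()` sets the target residue fully into one state
(phase fraction 1), holds other residues at the dataset-mean phases
(policy `"mean"`; `"reference"` pins them open instead - the original
text does not state its conditioning, so the policy is explicit and
configurable), fixes the group effect at `u = 0` (a typical pore), and
summarises the posterior of `exp(linear predictor)` as waters per flux
window with a 2.5/97.5 percentile interval.

## Synthetic data: what it emulates and what it does not

`simulate_state_traces()` draws, per residue and pore, a
continuous-time Markov chain with exponential dwell times sampled on
the 10 ps frame grid. With a uniform embedded jump matrix the
stationary occupancy of a state is proportional to its mean dwell, so
per-state dwells are `k * base_dwell * pi_s` for target occupancies
`pi`. Defaults use wild-type-like occupancies (mostly-open pore, e.g.
58.4% for the crystal-like R206 state, 20% M202 in-pore) and a 10 ns
base dwell, the scale of temporary flipping events. Residues are
independent by construction: the real system's couplings (e.g. F200
flipping compensated by A201) are deliberately out of scope, so
recovery tests validate the *model*, not the biology.

`simulate_flux_counts()` inverts the statistical model with planted
truth; defaults put states on the published per-state flux scale
(open about 4.6 waters per 5 ns, strongly blocked states near 1,
`sigma_u = 0.2`, `phi = 10`), keeping synthetic counts in a realistic
regime. `simulate_toy_trajectory()` plants complete crossings (about
2 ns transits at radius 0.15 nm), half-crossers, radial escapees
(radius 0.9 nm: inside the cylinder, outside containment) and bulk
decoys; it is a counting fixture with exact ground truth, not a
physical water model - there is no single-file exclusion, no
protein, and its noise scales are chosen so planted paths cannot
accidentally cross compartment boundaries.

Every generator is reproducible bit-for-bit given `(seed, spec)`.

## Problem sizes and what passing means

The test suite validates operations at desk scale (single pores, tens
to hundreds of ns) and the end-to-end guarantees at the study's design
size: 24 pores x 2000 ns for the interval arithmetic, and five
replicate fits of 24 x 599 rows for parameter recovery (95% intervals
cover planted truth in at least 90% of per-state checks, with Rhat and
ESS thresholds met in every fit). Passing these shows the pipeline
measures what it claims on data matching its assumptions; it does not
show that real trajectories satisfy those assumptions (Markovian
gating, residue independence, NB counts), nor can the published
trajectory-derived numbers be reproduced without the original
multi-microsecond trajectories, which are not deposited.

## Known limitations

* Trajectory formats: portable CSV and DCD are read natively; XTC/TRR
  readers are not available in this implementation - convert to one of
  the supported formats first.
* No autocorrelation correction across overlapping interval pairs.
* The hydrogen-bond criterion (0.35 nm donor-acceptor, 30 degrees off
  linearity) is the de facto standard, stated in the output metadata;
  the original study does not specify one.
* Pipeline stages form a chain; `fit` can restart from the dataset CSV,
  while earlier stages re-run from the seeded generators.
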