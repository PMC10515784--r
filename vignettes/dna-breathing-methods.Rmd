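---
title: "Simulating DNA breathing with the EPBD lattice model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating DNA breathing with the EPBD lattice model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epbdr)
```

## The model

At physiological temperature the two strands of the double helix transiently
and spontaneously separate — single bases flip out of the stack, and runs of
consecutive base pairs open simultaneously as denaturation bubbles. epbdr
models this with the Extended Peyrard-Bishop-Dauxois (EPBD) lattice: each
base pair *n* carries one transverse displacement $y_n$ (Å), the stretching
of its hydrogen bonds away from equilibrium (in per-strand coordinates,
$y_n = (u_n - v_n)/\sqrt{2}$). The potential energy of a configuration
$y = (y_1,\dots,y_N)$ is

$$
E(y) \;=\; \sum_{n=1}^{N} D_n\!\left(e^{-a_n y_n}-1\right)^2
\;+\; \sum_{n=2}^{N} \frac{k_{n-1,n}}{2}
\left(1+\rho\, e^{-b\,(y_n+y_{n-1})}\right)(y_n-y_{n-1})^2 .
$$

The Morse term models hydrogen bonding: $D_n, a_n$ depend on whether base
pair *n* is A·T (two H-bonds, shallower well) or G·C (three, deeper); the
potential plateaus at $D_n$, so a fully opened pair feels no restoring
force. The stacking term couples neighbours with a constant $k$ per
dinucleotide step; its exponential factor (amplitude $\rho$, range $b$)
stiffens the coupling while both pairs are closed and relaxes it once either
opens, which makes melting cooperative and bubble formation sharp.

Two modelling choices are fixed here and worth stating. First, the energy is
expressed in $y_n$ only: the common strand mode $u_n + v_n$ carries no
potential energy, so evolving it would be an energy-free random walk; a
proposal on one strand coordinate is statistically identical to a
$y$-proposal with width scaled by $1/\sqrt{2}$, and both forms are
available (`per_strand` in `mcmc_schedule()`). Second, the chain is open
($N-1$ stacking terms), which matches finite promoter fragments; there is no
periodic variant.

### The bounded displacement domain

Because the Morse potential plateaus, the partition function over an
unbounded domain diverges: equilibrium is only defined on a bounded one. The
sampler therefore works on a hard interval, by default $[-2, 20]$ Å, and
rejects proposals outside it. The quadrature references integrate over
exactly the same interval, so sampler-versus-quadrature comparisons are
exact by construction regardless of the chosen bounds. The bounds are part
of the parameter file and should be reported with any result: observables
such as the mean opening of an isolated base pair depend on them strongly
(most of the probability mass of an unstacked pair sits on the plateau).

### Parameters

The shipped parameter file (`inst/extdata/epbd_params_default.yaml`) uses
the classic homogeneous Morse constants for this model family —
$D_{AT} = 0.05$ eV, $a_{AT} = 4.2$ Å⁻¹, $D_{GC} = 0.075$ eV,
$a_{GC} = 6.9$ Å⁻¹, $\rho = 2$, $b = 0.35$ Å⁻¹ — and a dinucleotide
stacking table with values in the physical range around
$k = 0.025$ eV/Å², constructed to be reverse-complement symmetric. The
stacking table is illustrative: replace it with a melting-calibrated set
for production work. Every computation in the package treats parameters
strictly as input; nothing assumes these particular numbers beyond
$D_{AT} < D_{GC}$ ordering in the physically motivated tests. The table is
keyed by the ordered dinucleotide (base *n−1*, base *n*) on the reference
strand; a 10-entry table using one representative per reverse-complement
pair is accepted and expanded automatically.

## Sampling

`run_ensemble()` is plain Metropolis at fixed temperature. Each attempt
picks a site uniformly at random, draws a symmetric Gaussian candidate
around the current coordinate, rejects it outright if it leaves the bounded
domain, and otherwise accepts with probability
$\min\{1, e^{-\Delta E/k_BT}\}$, where $\Delta E$ is computed locally (one
Morse term, at most two stacking terms). A *sweep* is $N$ such attempts at
independently random sites; by default schedules are counted in sweeps so
step counts transfer across sequence lengths (`step_convention = "single"`
counts attempts instead). A run is `preheat_steps` of discarded burn-in
followed by `measure_steps` during which the displacement vector is
recorded every `record_interval` steps; an ensemble repeats this over
`n_runs` independently seeded runs (per-run seeds are a deterministic
function of `base_seed`, so results do not depend on how many runs execute
or in what order). All runs start from the closed helix ($y = 0$) by
default; `init = "uniform"` draws small random initial openings instead.

The default schedule (310 K, 50,000 preheating + 80,000 measurement steps,
100 runs) mirrors standard practice for this model family. Burn-in is
trusted, not tested: no convergence diagnostic is applied, and for slow
collective observables (see below) the preheat should be increased.

**Proposal width.** `proposal_sigma = "auto"` sets, per site, three times
the thermal width of the local harmonic approximation,
$3\sqrt{k_BT/(2 D_n a_n^2)}$. The bare harmonic width is the natural scale
of closed-state fluctuations, but moves on the Morse plateau are nearly
free, which pushes acceptance rates well above the standard random-walk
tuning band; the factor 3 brings the acceptance rate inside it (the test
suite checks 0.2–0.7 on A·T and G·C homopolymers at 310 K, and the
acceptance script reports the measured rate). The width is a pure
efficiency knob — any symmetric width samples the same distribution — so
it is safe to override.

**Reproducibility.** Both the compiled (Rcpp) engine and the pure-R
reference engine consume R's RNG stream in exactly the same order, and the
test suite checks they produce bit-identical trajectories. Everything
downstream of `(sequence, parameters, schedule, base_seed)` is
deterministic, including the text outputs byte for byte.

## Observables

All four characteristics are computed per run first and then averaged over
the $M$ runs, so the reported standard errors are honest run-to-run
variability (autocorrelation within a run never enters an error bar).

* **Average opening profile** `average_coordinates()`: $\langle y_n\rangle$
  over all recorded snapshots.
* **Flipping probability** `flipping_probability()`: fraction of snapshots
  with $y_n > thr$, strictly; ties at exactly the threshold count as
  closed (a measure-zero event, fixed for determinism). Default threshold
  1.5 Å.
* **Bubble tensor** `bubble_tensor()`: $P(n, l, thr)$, the probability that
  a bubble of length $l$ with amplitude above $thr$ exists starting at base
  pair $n$, on a grid of thresholds (default 0.5–2.5 Å) and lengths
  (default up to $\min(N, 20)$). Time is measured in recorded snapshots,
  since openings are only observed at recording times. The default
  *inclusive* convention counts a window as a bubble whenever all $l$
  positions are simultaneously open; it makes the tensor non-increasing in
  $l$ and in $thr$ and makes the $l=1$ slice exactly the flipping profile.
  The alternative `convention = "maximal"` counts only maximal open runs
  (closed neighbours or chain ends on both flanks), which decomposes
  openings by exact bubble extent but loses those monotonicities.

## Dynamic length

To compare two alleles (e.g. wild type versus an SNP mutant),
`compute_dynamic_length()` takes the per-run flipping fractions at each
position (an $M \times N$ matrix per allele), applies Welch's
unequal-variance t-test position by position, adjusts the p-values into a
q-factor profile, and thresholds at an FDR level `alpha` (default 0.05).
The *dynamic length* is the number of base pairs called significantly
changed; the positions themselves and the longest contiguous significant
block are reported alongside. Positions where both groups are constant get
$p = 1$ when the constants agree (no evidence of change) and $p = 0$ when
they differ.

Two q-value methods are offered because FDR estimation in this setting has
no single canonical form: Benjamini-Hochberg step-up adjustment (`"bh"`),
and a Storey-type estimate (`"storey"`, the default) that scales BH by the
estimated proportion of true nulls,
$\hat\pi_0 = (1 + \#\{p > 0.5\})/(m/2)$, capped at 1; with fewer than 20
positions it falls back to BH. The fixed-$\lambda$ form is used
deliberately: neighbouring positions are strongly positively dependent
(one widely-melted run shifts every position at once, bunching the
p-values), and under that dependence the spline-smoothed $\lambda$-grid
estimator can collapse $\hat\pi_0$ toward zero and declare everything
significant; the single-$\lambda$ add-one estimate stays conservative at
the tens-to-hundreds of tests a sequence profile yields. Only substitution alleles of
equal length are comparable; indels would need an alignment layer that is
out of scope.

## Quadrature references

For one and two base pairs the equilibrium averages have an independent
reference: `boltzmann_average_1bp()` and `boltzmann_average_2bp()` compute
$\langle f \rangle = \int f\, e^{-E/k_BT} / \int e^{-E/k_BT}$ by composite
Simpson quadrature over exactly the sampler's bounded domain (defaults
8001 points in 1-D, 1501 per dimension in 2-D; the result is stable to
well below $10^{-8}$ relative under grid doubling). The test suite requires
MCMC estimates to agree with these within three Monte-Carlo standard
errors; the same functions are exported so users can validate a custom
parameter file before a production run.

## What the synthetic sequences do and do not show

`generate_fixture()` provides homopolymers (cleanest temperature and
composition orderings), an AT-rich "promoter-like" random sequence with a
TATA-like core, and a wild/mutant pair differing by an adjacent AG→TC
dinucleotide substitution at the centre. These exercise every code path and
the physically expected orderings (flipping grows with temperature; A·T
tracts breathe more than G·C tracts). They do not capture several features
of real genomic DNA — long-range sequence correlations, salt and solvent
effects, methylation, or any kinetic information (the sampler yields
equilibrium statistics; bubble durations in physical time units are out of
scope). Passing tests therefore validate the sampler and the statistics,
not biological predictions for a particular locus.

## Numerical choices and problem sizes

Desk-scale test and validation sizes were chosen as follows, and are part
of the package's own test design:

* Sampler-versus-quadrature: 20 runs × 20,000 sweeps (after an equal
  preheat) for 1-bp and 2-bp systems.
* Orderings across temperature/composition: 30-mers, 20 runs × 2,000
  sweeps.
* Null dynamic-length control: 60-mer, 20 replicates of two independently
  seeded 20-run ensembles at 8,000 measurement sweeps. Test validity under
  the null does not depend on sampling depth, so these runs are short.
* Perturbation recovery: per-run flipping fractions are dominated by rare,
  long-lived bubble episodes — on the Morse plateau there is no restoring
  force, so an opened region closes only by diffusion and a single episode
  can span tens of thousands of sweeps. Runs must be long relative to that
  lifetime before run-to-run variance stabilises; the power study therefore
  uses 20 runs × 300,000 sweeps, under which a 30% Morse-depth reduction at
  three sites of a 60-mer is recovered consistently (typically with a few
  flanking positions, as expected for a cooperative model).

Other fixed conventions: strict `>` at thresholds; energies tracked
incrementally by local differences and verified against full recomputation
to $10^{-10}$ relative; q-values capped at 1; per-run seeds
`base_seed + 1000003·i (mod 2^31−1)`.

## Limitations

Single-sequence scope (no genome tiling); no helicoidal or torsional
degrees of freedom; no salt dependence; no Langevin or other kinetic
integrator; error bars are run-to-run only, with no autocorrelation
correction within runs; burn-in adequacy is the user's responsibility. The
shipped stacking table is a placeholder in the physical range, not a
calibrated set.

## A minimal session

```{r example, eval = FALSE}
seq <- generate_fixture("promoter_like", 60, seed = 1)
sch <- mcmc_schedule(preheat_steps = 1000, measure_steps = 8000,
                     record_interval = 10, n_runs = 20)
ens <- run_ensemble(seq, sch)
flipping_probability(ens, 1.5)
bubble_tensor(ens)

pair <- generate_fixture("snp_pair", 60, seed = 1)
epbd_compare(pair$wild, pair$mutant, schedule = sch)
```
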