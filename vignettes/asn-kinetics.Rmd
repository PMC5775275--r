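---
title: "Mass-action kinetics of wheat asparagine synthetase: model, simulation and parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-action kinetics of wheat asparagine synthetase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asnkin)
```

## The biochemical problem

Glutamine-dependent asparagine synthetase (EC 6.3.5.4) transfers the
amide nitrogen of glutamine to aspartate at the expense of ATP:

    Gln + Asp + ATP  ->  Glu + Asn + AMP + PPi

Free asparagine in cereal grain is the main precursor of acrylamide
formed during baking and frying, so the kinetics of the wheat isoforms
TaASN1 and TaASN2 are of direct applied interest. In vitro, both enzymes
show a striking asymmetry: glutamate accumulates much faster than
asparagine and keeps accumulating after asparagine production has
stopped, because the glutaminase half-reaction can run without the
synthetase half-reaction once aspartate is depleted.

`asnkin` represents this mechanism as a continuous Petri net — places
(species) holding continuous concentrations, transitions (reactions)
firing at mass-action rates — compiles it to an ODE system, simulates
it, and fits rate constants to time-course data. The canonical model
splits the catalytic cycle into four sequential elementary steps plus an
unproductive dissociation of the ammonia-loaded enzyme:

| step | reaction | rate constant |
|------|----------|----------------|
| r1 | ASNe + Gln → ASNe·Gln | k1 |
| r2 | ASNe·Gln → Glu + ASNe·NH3 | k2 |
| r3 | ASNe·NH3 + Asp + ATP + Mg²⁺ → βAsp-AMP·ASNe·NH3 (+ Mg²⁺) | k3 |
| r4 | βAsp-AMP·ASNe·NH3 → Asn + ASNe + AMP | k4 |
| D  | ASNe·NH3 → ASNe | kD |

Water and pyrophosphate are ubiquitous and omitted. The dissociation
step D is what lets the model reproduce the observed excess of glutamate
over asparagine: every firing of D consumes a glutamine-derived amide
nitrogen without making asparagine. ATP and Mg²⁺ are *clamped*
(boundary) places: they appear in the r3 flux product but their
derivatives are identically zero, standing in for the large buffered
pools (10 mM each) of the assay.

## From net to ODEs

With mass-action kinetics, reaction $j$ with rate constant $k_j$ and
substrate stoichiometries $s_{ij}$ fires at
$v_j = k_j \prod_i c_i^{s_{ij}}$, and the species dynamics are
$\dot c = N v(c)$ with $N$ the net stoichiometry matrix (clamped rows
zeroed). `compile_odes()` builds this derivative function; for the
canonical net it reproduces, term for term, the eleven equations of the
mechanism (the test suite checks this against an independently
hand-coded right-hand side at 1000 random states to a relative
tolerance of 1e-12).

The left null space of the dynamic stoichiometry matrix gives the
conserved moieties (`conserved_moieties()`), computed by a small exact
row-reduction and scaled to integer weights. The canonical net has four
independent laws, including the aspartate pool
(Asp + βcomplex + Asn), the glutamine pool (Gln + ASNe·Gln + Glu), total
enzyme, and the coupling AMP − Asn. These are used throughout the tests
as solver-independent oracles: any integration whose trajectories drift
off these hyperplanes is wrong, whatever it looks like.

## Units

Published descriptions of this system mix mg/mL, mM and nmol/mL across
assay buffer, enzyme loading and rate constants, and mass-action
constants of different reaction orders cannot in fact share one unit.
The package therefore works in one abstract concentration unit (c.u.)
and takes the reference rate constants at face value in that system:
the assay species load as Asp 1.6, Gln 10, ATP 10, Mg 10, and the
enzyme at 0.1 (TaASN1) or 0.09 (TaASN2) — the start values against
which the reference constants were fitted. The molar enzyme loadings
(2.03 and 2.10 nmol/mL) are carried as metadata only; they are
inconsistent with the mass start values by about 30% given the subunit
mass, and no reconciliation is attempted. All quantities the package
reports are either invariant to this choice or generated
self-consistently within it.

## Simulation

`simulate_network()` integrates with `deSolve::ode` (lsoda). The system
is stiff — kD = 700 against binding rates of order 0.01 spans five
orders of magnitude — so an implicit, stiffness-switching method is the
default, at `rtol = 1e-8`, `atol = 1e-10`. The default output grid is
2001 points over 2100 s (2000 steps of 1.05 s), mirroring the original
simulation protocol; the step figure is read as *output* step size,
with internal stepping left to the solver. Mass-action systems started
non-negative stay non-negative, so output values in `[-100 * atol, 0)`
are clipped to zero and anything more negative raises an integration
error rather than being silently accepted.

```{r sim}
traj <- simulate_network(asn_network(), asn_rate_params("TaASN1"),
                         asn_initial_state("TaASN1"))
plateau_metrics(traj)$glu_asn_ratio
```

`plateau_metrics()` summarizes the product plateau: final and maximum
concentrations, time to 95% of the final net change, the final
glutamate:asparagine ratio (reported as `Inf`, not an error, when no
asparagine is ever made), and a flag for "glutamate still rising while
asparagine is flat", defined over the last quartile of the grid as a
relative glutamate increase more than ten times that of asparagine.

## The synthetic assay generator

`generate_assay_dataset()` emulates the HPLC activity assay end to end,
and its defaults *are* the assay design: sampling at 1.5, 2.5, 3.5, 5,
15, 25 and 35 min (stored in seconds), two replicates, and a five-point
standard series at 0, 5, 10, 15, 20 nmol. The chain is: simulate the
mechanism from the assay initial state; sample Asn and Glu; map
concentrations to peak areas through a configured true instrument
response (default slope 1000 area units per c.u., intercept 25 —
arbitrary but realistic for o-phthalaldehyde fluorescence peaks, and
irrelevant to any downstream quantity because the chain is inverted
through a fitted curve); perturb each replicate area with multiplicative
Gaussian noise (default CV 5%, a typical HPLC fluorescence
repeatability; no error model is prescribed by the assay itself, so
this is a package choice and is configurable); run a fresh standards
series at the same noise level; fit the working calibration by ordinary
least squares; and invert areas back to concentrations, clipping
below-baseline values to zero with a flag. With `noise_cv = 0` the
chain is exactly the identity, which the tests assert.

What the generator deliberately does not emulate: chromatographic peak
shapes and retention, derivatization-efficiency kinetics, quench
imperfection (the acid stop is treated as instantaneous exact sampling),
pipetting volume errors, and any unit conversion between nmol per
injection and mM in the reaction — the dataset simply carries a unit
label. Passing recovery tests on these data therefore demonstrates that
the estimation machinery is correct and the design informative, not
that real chromatograms of this assay would constrain all five
constants equally well.

## Parameter estimation

`fit_timecourse()` minimizes an unweighted sum of squared concentration
residuals over asparagine and glutamate, all replicates and time points
(`sse_objective()`; a per-species weighting hook exists but is off by
default, since no weighting scheme is prescribed for these data). The
model is evaluated at the data's exact time points by passing them as
solver output times — equivalent to the usual dense-grid-plus-
interpolation scheme but without interpolation error.

The optimizer is a from-scratch Hooke–Jeeves pattern search
(`hooke_jeeves()`): exploratory per-coordinate ± steps in fixed order
with first-improvement acceptance, pattern (extrapolation) moves while
they keep paying, step contraction by 0.5 otherwise, candidates
projected onto the box. It is fully deterministic, never evaluates
outside the bounds, treats non-finite objective values as +Inf (but
rejects a non-finite start), and records a monotone best-so-far trace.
Search runs in log10 space because the bounds span twelve decades
(1e-6 to 1e+6); the defaults are an initial step of 0.2 decades,
stop step 1e-5 decades, and a budget of 20000 evaluations. A
Nelder–Mead simplex (via `stats::optim`, Brent in one dimension) is
available behind the same interface as an independent fallback.

For recovery studies the default free set is {k1, kD} with {k2, k3, k4}
fixed: the two isoforms share the three intermediate constants, the
fast steps are only weakly identifiable from sparse two-product data,
and k1/kD are exactly the constants that distinguish the isoforms
biologically. `recovery_experiment()` wires generator and fitter
together: by default it samples noiselessly at 100 evenly spaced times
over 0–2100 s, starts the search at twice the generating values, and
reports per-parameter relative errors. Noiseless recovery lands within
about 1e-5 of truth; at 5% measurement noise the k1 error grows but
stays well under 25% in the configurations the tests run.

```{r recover, eval = FALSE}
recovery_experiment("TaASN1", noise_cv = 0, n_replicates = 1, seed = 1)
```

## Numerical and design choices worth knowing

- **Clamping** is implemented by zeroing rows of the stoichiometry
  matrix, not by removing species: clamped places keep their position in
  the state vector and their (constant) value in trajectories.
- **Mg²⁺ in r3** is written on both sides of the reaction; its flux
  contribution survives while its net stoichiometry is zero (and it is
  clamped anyway).
- **Tie-breaks in the search**: the exploratory sweep tries +step before
  −step and accepts the *first* improvement; coordinate order is the
  declaration order of the free parameters. Equal objective values are
  not accepted as improvements, so a start at the global minimum returns
  unchanged ("zero-iteration convergence").
- **Degenerate inputs** fail loudly: empty datasets, observed species
  absent from the network, a calibration with non-positive slope, all
  standards at one concentration, start values outside bounds, and
  overlapping free/fixed sets are all errors, not silent repairs.
- **Reproducibility**: every stochastic routine takes an explicit seed
  and restores the caller's RNG state; the pipeline commands expand one
  global seed into per-stage seeds by fixed offsets so stages can be
  re-run independently; artifacts embed the seed and a config hash.
- **Problem sizes** used by the shipped tests and the acceptance script
  — full-length 2001-point trajectories, 100-time-point recovery
  datasets, 1000-state oracle sweeps, 20 random quadratics — were chosen
  as the smallest designs that exercise every claim; all of them run in
  seconds.

## Limitations

Only mass-action kinetics are supported (no Michaelis–Menten or Hill
laws), nets are flat (no compartments beyond one, no colored/
hierarchical structure), tokens are continuous (no stochastic
semantics), and the fitter provides point estimates only — no
confidence intervals, profile likelihood or model selection. The
ammonia-dependent activity of asparagine synthetases and the TaASN3/4
isoforms are out of scope for lack of kinetic characterization. SBML
export (`write_sbml()`) is one-way; there is no importer.
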