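---
title: "Methods: equivalent kinetic-model populations over nested network reductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equivalent kinetic-model populations over nested network reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, assumptions and numerical choices
behind `nestMCA`, in the spirit of a methods section: what each stage
computes, which parameters matter, and what the synthetic test system does
and does not show about real data.

## The problem

A reduced stoichiometric model is one point on a spectrum of complexity.
When a family of reductions is *nested* — each larger model contains the
smaller one's reactions and adds connections around shared metabolites —
it becomes possible to ask how conclusions from a kinetic model depend on
network size, provided the models are kept *equivalent* in every other
respect: same physiology, numerically similar steady states, and identical
kinetic parameters wherever the networks overlap.  `nestMCA` builds that
equivalence chain and then compares flux control coefficients (FCCs)
across the levels.

## Thermodynamics-based flux analysis

The feasible set couples net fluxes, flux directions and metabolite
log-concentrations.  Per reaction `i` with standard Gibbs energy `ΔG°_i`
(kJ/mol):

* `NF_i = VF_i − VR_i`, with `VF, VR ≥ 0` and direction binaries
  `b⁺_i, b⁻_i ∈ {0,1}`, `b⁺ + b⁻ ≤ 1`;
* `VF_i ≤ M_i b⁺_i`, `VR_i ≤ M_i b⁻_i` with `M_i = max(|lb_i|, |ub_i|, 1)`
  (the tightest safe big-M);
* `ΔG_i = ΔG°_i + RT Σ_j n_ij ln x_j` over metabolites with concentration
  variables (water and protons are held at fixed activity and excluded);
* equilibrium exclusion: `ΔG_i ≤ −RT·δ + M^G_i (1 − b⁺_i)` and
  `ΔG_i ≥ RT·δ − M^G_i (1 − b⁻_i)`, with a per-reaction energy big-M
  derived from `|ΔG°_i|` and the concentration windows;
* basal activity: `VF_i ≥ ε b⁺_i`, `VR_i ≥ ε b⁻_i` with
  `ε = 1e-6` mmol/gDW/h.

The displacement is `Γ_i = exp(ΔG_i/RT)`; `Γ = 1` at equilibrium and
`|ln Γ| ≥ δ` for any reaction with an assigned direction.  Two parameters
deserve comment:

* **δ (default 0.01, dimensionless).**  The equilibrium exclusion exists
  because downstream elasticities contain the factor `Γ/(1 − Γ)`, which
  diverges as `Γ → 1`.  δ = 0.01 bounds that factor near 100 while
  distorting variability ranges by at most 1% in `ln Γ` terms; it is
  configurable because no canonical value exists.
* **Basal activity ε (default 1e-6 mmol/gDW/h).**  A direction binary
  without a flux floor can be set on a reaction that mass balance pins at
  exactly zero — the direction is then decorative, and every kinetic
  instance built on such a state has a singular Jacobian (a metabolite
  whose every producing and consuming flux is zero has no dynamics).  The
  floor makes "directed" mean "active at least at basal level", matching
  the convention used for passive basal transporters.

Concentration windows default to 1 nM – 100 mM in ln(mol/L); experimental
bounds in log10(mM) are converted at the boundary
(`logConcToLn()`).  Strict inequalities are realised as closed ones with
the δ/ε offsets, since MILP solvers operate on closed sets.

All optimisation goes through one batched interface to the HiGHS solver
(deterministic; MIP gaps set to zero and feasibility tolerances to 1e-8/1e-9
so that the 1e-6-scale basal couplings are binding rather than absorbed by
solver slack).

## Steady-state selection and transfer

With binaries fixed (the package fixes them by maximising the number of
assigned directions, so every reaction that can carry flux does), the flux
and concentration polytopes are convex and decouple.  Each is sampled with
artificial-centering hit-and-run in null-space coordinates (warm-up 1000
steps, thinning 10 by default; both configurable).  Samples satisfy
`S v = 0` to machine precision because the walk lives in the null space
itself.  The representative state is chosen by PCA: variables are
standardised, constant columns dropped, components retained to 90%
cumulative variance (the retention count is pool-specific, so a coverage
fraction replaces any fixed component number), and the pool member closest
to the projected mean is returned — always an actual sample, never an
average; ties break to the lowest index.

Transfer into the next larger model imposes a band
`ref ± relaxation · max(|ref|, floor)` on every shared non-exchange
variable.  The default relaxation is 1%.  The floor (1e-6) exists because
1% of a zero reference is zero: without it every near-zero flux would be
banded to a point.  A binary `z` per band deactivates its two constraints,
and the MILP minimises `Σ z`; since all-`z = 1` recovers the unbanded
model, the program is feasible whenever the model is.  Non-violated bands
are then imposed permanently, violated ones dropped, and the flux/
concentration spaces are re-sampled for the larger model's representative
state.  Concentration bands act on `ln x` (the linear TFA variables).  The
percent deviations reported use the smaller model's value as denominator.
The full TFA constraint set stays active during the transfer MILP by
default (`keepThermo = FALSE` restricts it to mass balance, matching the
minimal published statement of the program; both are exposed because the
original formulation leaves this open).

## Kinetic ensembles at the elasticity level

Kinetic model instances are represented by the pair (steady state,
elasticity matrix) rather than explicit rate constants: local stability
and control coefficients — the outputs of interest — depend on nothing
else.  For reaction `i` oriented along its net flux (backward flux swaps
substrate/product roles and inverts Γ) and metabolite `j`:

```
E_ij = ε_binding − n'_ij · Γ_i / (1 − Γ_i)
```

with binding terms: convenience kinetics `|n|(1 − σ)` for substrates and
`−|n| σ` for products; reversible Hill multiplies both by the Hill
coefficient `h`; mass action contributes `|n|` for substrates and 0 for
products; inhibitors add `−σ` and activators `+(1 − σ)`.  σ is the
fractional occupancy of the binding site, sampled i.i.d. uniform on
`(1e-6, 1 − 1e-6)` — the open interval keeps the rate-law back-solve
`K = x(1−σ)/σ` well-posed.  Literature Michaelis constants enter as fixed
saturations `σ = x/(K + x)` at the reference concentration.  Reactions
without Gibbs-energy data are treated as irreversible (`Γ = 0`).  These
formulations are the package's own documented registry; they are verified
against finite differences of explicit rate laws built from the same
(σ, Γ) pairs, to 1e-6 relative.

Stability uses the reduced Jacobian `J = N_R diag(v) E diag(x)⁻¹ L`, where
`S = L N_R` is the conserved-moiety reduction (pivoted QR row selection;
link-matrix entries snapped to integers when within 1e-9, so rational
stoichiometries give exact conservation relations).  An instance is stable
when no eigenvalue has real part above 1e-9 — the slack admits exact zeros,
which conservation laws do not produce because they are removed by the
reduction.  Control coefficients follow from
`C^x = −diag(x)⁻¹ L J⁻¹ N_R diag(v)` and `C^v = I + E C^x`, with one
enzyme per reaction and rates proportional to enzyme level, so enzyme FCCs
are the matrix columns.  Instances with `rcond(J) < 1e-12` are discarded
and counted separately: their control coefficients are undefined, not
zero.  Because sampled fluxes satisfy `N_R v = 0` exactly, the summation
theorems (`Σ_k C^v = 1`, `Σ_k C^x = 0`) hold to floating-point precision —
the test suite asserts 1e-6 on every stable instance.

**Stratified resampling.**  To keep parameter equivalence across levels,
the σ values of enzyme–metabolite pairs shared with the smaller model are
copied bit-exactly; only expansion-specific pairs are redrawn, up to
`maxTries = 50` times until the instance is stable in the larger model.
Instances that never stabilise are flagged and excluded, and the retained
fraction is reported — the population-level accounting that makes
cross-model FCC comparisons fair.  Lumped reactions present in both models
are treated as shared (resampling them would break equivalence for no
benefit).

## Deviation index and comparison reports

With one enzyme per reaction, *every* reaction is a perturbable step, so
the summation theorem spans the full reaction set — transporters included.
The deviation index of a flux over the enzymes shared with a smaller model,
`DI = |Σ_{k∈shared} C̄^v_k − 1|`, therefore equals exactly the mean control
held by expansion-added reactions; computed over the full set it is zero to
numerical precision, which the tests use as an end-to-end invariant.  The
optional restriction of DI sums to enzymatic and lumped reactions (the
`model` argument of `deviationIndex()`) exists for comparisons phrased in
terms of enzymatic reactions only; it is not the default because the DI
null then no longer holds wherever transport steps carry control.  DI is
computed on population-mean FCCs by default — the published comparisons are
mean-based — with the per-instance DI distribution always returned
alongside, since the aggregation order is a genuinely open choice.
Percentile classes cut at the 25th and 75th empirical percentiles with
ties taking the lower class (determinism).  Rankings sort by |mean FCC|
with ties broken by enzyme id.

## The synthetic family

`generateNestedToys()` emulates the structural features the workflow
assumes from systematically reduced models: a branched central backbone
with an uptake/excretion boundary, an ATP/ADP conserved pair, one lumped
mass-balanced reaction feeding a biomass building block (flux capped at
~10% of core flux, mirroring biomass-dilution scales), and per level a set
of two-reaction parallel routes around hub metabolites — the branch-point
creation mechanism that drives control redistribution.  Gibbs energies are
assigned backwards from a nominal 1 mM state so that every reaction has a
negative driving force there (drawn from −20…−5 kJ/mol per reaction,
shared across levels); thermodynamic feasibility is by construction, not
by search.  Expansion routes carry a basal lower bound of 1e-3 mmol/gDW/h
so the added reactions participate in the kinetics rather than idling at
zero flux.

The generated physiology imitates fluxomics/metabolomics constraints:
bounds of ±20% around an *interior* point of the TFA space (a hit-and-run
representative, not an LP vertex — measured organisms do not operate at
polytope corners), an exactly fixed uptake, an absolute flux half-width
floor of 0.01 mmol/gDW/h (measurement precision), and a 0.05 mmol/gDW/h
detection limit below which fluxes are left unconstrained.

What passing tests on this family show: the algebra and bookkeeping of the
whole chain — TFA, transfer, stratification, MCA, DI — are correct, at
network sizes where independent oracles (vertex enumeration, exhaustive
binary enumeration, finite-difference ODE perturbation) are exact.  What
they do not show: behaviour under the degeneracies of genome-scale data —
thousands of reactions, flat thermodynamic gradients, many alternative
optima, measurement noise — nor any biological conclusion.  The deposited
reduced *E. coli* models can be dropped into
`inst/extdata/deposited/D{1,2,3}.tsv` (TSV dialect) to run the
corresponding published benchmarks in the acceptance suite.

## Problem sizes and runtime choices

The test suite and the acceptance script run the 3-level family with
500–1000 polytope samples per space and 200 kinetic instances at the base
level, stratified upward — sizes at which every stage completes in seconds
while the oracles remain exhaustive (the transfer oracle enumerates all
2^k violation assignments for k ≤ 12 bands).  All sampling is seeded;
identical seeds give bit-identical pools, ensembles and reports.

## Known limitations

* The elasticity registry covers convenience, reversible Hill and mass
  action with simple modifier terms; detailed multi-substrate mechanism
  formularies are out of scope, as is ODE integration for production use.
* Transfer assumes exact id matching between nested models (an alias
  table is accepted); it does not attempt structural matching.
* TVA on MILP problems is exact but serial per variable; genome-scale
  models will be solver-bound.
* The MAT-container format of the deposited models is not read directly;
  models must be exported to SBML or the TSV dialect first.
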