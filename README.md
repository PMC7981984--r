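# nestMCA

Kinetic models of metabolism are usually built around a reduced
stoichiometric network, and the choice of network size changes the
conclusions drawn from the model.  `nestMCA` implements a workflow for
quantifying that effect: it constructs *equivalent* populations of kinetic
models across a family of nested reduced models (a shared core plus
expansion reactions), computes metabolic control coefficients for each
population, and measures how flux-control conclusions shift with network
complexity.  It is aimed at modellers in systems biology and metabolic
engineering who work with systematically reduced genome-scale models and
ORACLE-style kinetic ensembles.

## What it does

For nested stoichiometric models M1 ⊂ M2 ⊂ … with thermodynamic data the
package provides:

* **TFA** — thermodynamics-based flux analysis as a MILP: mass balance
  `S v = 0`, direction binaries `b⁺, b⁻` coupled to the reaction Gibbs
  energy `ΔG_r = ΔG°_r + RT Σ_j n_ij ln x_j`, and an equilibrium-exclusion
  constraint `|ln Γ| ≥ δ` on the thermodynamic displacement
  `Γ = exp(ΔG_r/RT)`, plus thermodynamic variability analysis (TVA) and
  bidirectionality classification.
* **Steady-state selection** — artificial-centering hit-and-run sampling of
  the flux and log-concentration polytopes, with a PCA-based choice of the
  pool member closest to the projected mean.
* **Steady-state transfer** — a MILP that imposes ±1% bands around a
  smaller model's reference state onto the larger model, one violation
  binary `z` per shared variable, minimising `Σ z`:
  `NF_i + (F^ub_i − UB_i) z_i ≤ F^ub_i` and
  `NF_i + (F^lb_i − LB_i) z_i ≥ F^lb_i`.
* **Kinetic ensembles** — uniform Monte-Carlo sampling of enzyme saturation
  states σ, conversion to scaled elasticities
  `E_ij = ε^binding_ij − n_ij Γ_i/(1 − Γ_i)`, eigenvalue-based local
  stability filtering, and *stratified* resampling that copies shared σ
  values bit-exactly into the next larger model.
* **MCA** — conserved-moiety reduction (`S = L N_R`), flux and
  concentration control coefficients (`C^v = I + E C^x`,
  `C^x = −diag(x)⁻¹ L J⁻¹ N_R diag(v)`), with the summation theorems
  (`Σ_k C^v_k = 1`, `Σ_k C^x_k = 0`) holding to numerical precision.
* **Deviation index** — `DI = |Σ_{k∈shared} C^v_{p_k} − 1|` over the
  enzymes shared with a smaller model; by the summation theorem the DI
  equals the control held by expansion-added reactions.  Percentile
  classes, top-controller rankings and subsystem-wise absolute FCC
  deviations reproduce the standard comparison reports.
* **Synthetic families** — a generator for nested toy models (branched
  core, ATP/ADP moiety, lumped biomass reaction, hub expansions with
  feasible thermodynamics) so the entire workflow runs and is tested with
  no external data.

Optimisation runs on the HiGHS solver through a bundled scipy bridge
(`python` must be on the PATH, as in any standard scientific setup).

## Worked example

```r
library(nestMCA)

fam <- generateNestedToys(seed = 1)        # 3 nested models + physiology
fam$models[[1]]
#> MetabolicModel 'toy_D1': 12 metabolites x 14 reactions
#>   kinds: enzymatic=8, transport=2, lumped=1, exchange=3, biomass=0
#>   reactions with dG0: 11

prob1 <- buildTFAProblem(fam$models[[1]], physiology = fam$physiology)
prob1
#> TFAProblem on 'toy_D1': 81 variables (22 binary), 34 eq + 77 ineq constraints
#>   thermodynamically constrained reactions: 11 (delta = 0.01)

## representative steady state: sample fluxes, then concentrations
pool   <- sampleFluxSpace(prob1, n = 1000, seed = 2)
sel    <- selectRepresentative(pool)
poolC  <- sampleConcentrationSpace(prob1, sel$values, n = 1000, seed = 3)
state1 <- makeSteadyState(prob1, sel$values, selectRepresentative(poolC)$values)

## carry the state into the next nested level with 1% bands
prob2 <- buildTFAProblem(fam$models[[2]], physiology = fam$physiology)
tr <- transferSteadyState(prob2, fam$mappings[[1]], state1, n = 1000, seed = 4)
tr$fluxReport
#> TransferReport (flux phase): 0 band violation(s)

## kinetic ensembles: 200 instances, stratified into the larger model
ens1 <- kineticEnsemble(fam$models[[1]], state1, n = 200, seed = 5)
ens1
#> KineticEnsemble on 'toy_D1': 200 sampled, 200 stable (100.0%), 0 unstable, 0 singular

mech2 <- assignMechanisms(fam$models[[2]])
strat <- stratifiedResample(ens1@saturations, fam$mappings[[1]], mech2, seed = 6,
  stabilityCheck = makeStabilityCheck(fam$models[[2]], tr$state, mech2))
ens2 <- kineticEnsemble(fam$models[[2]], tr$state, mech2, saturations = strat)

## deviation index over the enzymes shared with the smaller model
di <- percentileClasses(deviationIndex(ens2, fam$mappings[[1]]@shared$id_large))
head(di@table[order(-di@table$di), ], 5)
#>  flux_id          di percentile_class
#>  XP2_1_1 0.995122704             high
#>  XP2_1_2 0.995122704             high
#>  XP2_2_1 0.981732263             high
#>  XP2_2_2 0.981732263             high
#>       R3 0.005766053              mid
```

The DI is largest for the expansion reactions themselves — the shared
enzymes hold almost none of their control — while the shared backbone
reaction `R3` keeps `DI ≈ 0.006`: its control pattern barely changed when
the network grew, so conclusions about it are robust to model size.
Controller rankings work the same way:

```r
rankControllers(ens1, "EX_BBB", topK = 3)
#> RankingReport for flux 'EX_BBB' (top 3):
#>     enzyme   mean_fcc  abs_mean        q25       q75
#>       EX_A  2.0259291 2.0259291  1.0088212  2.549547
#>  LMPD_BBB1  0.5675908 0.5675908  0.4745595  0.640399
#>       R5_1 -0.4629532 0.4629532 -0.5647116 -0.157957
```

A command-line interface exposing each stage (`fixtures`, `tfa`, `tva`,
`sample`, `transfer`, `kinetics`, `mca`, `deviation`, `run-all`) is
installed at `inst/scripts/nestmca`, and `runPipeline()` orchestrates the
whole workflow with per-stage outputs, seeds and a configuration hash.

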