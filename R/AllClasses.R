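## S4 class definitions.

setOldClass("lpProblem")

REACTION_KINDS <- c("enzymatic", "transport", "lumped", "exchange", "biomass")
LUMP_PREFIX <- "LMPD"

#' MetabolicModel: a stoichiometric model with bounds and thermodynamic data
#'
#' Container for a (reduced) stoichiometric metabolic model.  Holds a
#' metabolite table, a reaction table with flux bounds (mmol/gDW/h),
#' subsystem labels, reaction kinds and optional standard Gibbs energies
#' (kJ/mol), and the sparse stoichiometric matrix `S` (metabolites x
#' reactions).
#'
#' @slot name Model name.
#' @slot metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `formula`, `is_bbb` (biomass building block flag).
#' @slot reactions `data.frame` with columns `id`, `lb`, `ub`, `subsystem`,
#'   `kind` (one of enzymatic/transport/lumped/exchange/biomass), `dG0`,
#'   `dG0_err` (`NA` when no thermodynamic data).
#' @slot S Sparse stoichiometric matrix, rows named by metabolite id,
#'   columns by reaction id.
#' @export
setClass("MetabolicModel",
  representation(name = "character", metabolites = "data.frame",
                 reactions = "data.frame", S = "Matrix"))

setValidity("MetabolicModel", function(object) {
  met <- object@metabolites; rxn <- object@reactions; S <- object@S
  msgs <- character()
  need_m <- c("id", "name", "compartment", "formula", "is_bbb")
  need_r <- c("id", "lb", "ub", "subsystem", "kind", "dG0", "dG0_err")
  if (!all(need_m %in% names(met))) msgs <- c(msgs, "metabolite table missing columns")
  if (!all(need_r %in% names(rxn))) msgs <- c(msgs, "reaction table missing columns")
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicate reaction ids")
  if (any(!nzchar(met$compartment))) msgs <- c(msgs, "empty compartment")
  if (!all(rxn$kind %in% REACTION_KINDS))
    msgs <- c(msgs, sprintf("unknown reaction kind(s): %s",
                            paste(setdiff(rxn$kind, REACTION_KINDS), collapse = ", ")))
  if (any(rxn$lb > rxn$ub)) msgs <- c(msgs, "reaction with lb > ub")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, "S dimensions inconsistent with tables")
  else {
    if (!identical(rownames(S), met$id)) msgs <- c(msgs, "S rownames != metabolite ids")
    if (!identical(colnames(S), rxn$id)) msgs <- c(msgs, "S colnames != reaction ids")
    if (ncol(S) > 0 && any(Matrix::colSums(S != 0) == 0))
      msgs <- c(msgs, "reaction with empty stoichiometry")
  }
  if (length(msgs)) msgs else TRUE
})

#' NestedMapping: correspondence between a small and a large nested model
#'
#' @slot smallName,largeName Names of the mapped models.
#' @slot shared `data.frame` with columns `id_small`, `id_large` (reaction
#'   pairs with identical stoichiometry).
#' @slot addedReactions Reaction ids present only in the large model.
#' @slot sharedMetabolites `data.frame` with `id_small`, `id_large`.
#' @slot addedMetabolites Metabolite ids present only in the large model.
#' @slot mismatches Ids matched by name whose stoichiometries differ.
#' @export
setClass("NestedMapping",
  representation(smallName = "character", largeName = "character",
                 shared = "data.frame", addedReactions = "character",
                 sharedMetabolites = "data.frame",
                 addedMetabolites = "character", mismatches = "character"))

setValidity("NestedMapping", function(object) {
  if (anyDuplicated(object@shared$id_large)) return("mapping not injective")
  TRUE
})

#' LumpComparison: commonality statistics of lumped-reaction sets
#'
#' @slot commonCount Lumps common to all compared models.
#' @slot uniqueCounts Named integer: lumps unique to each model.
#' @slot partialCount Lumps shared by some but not all models.
#' @slot totalDistinct Distinct lumps across all models.
#' @slot constituentUnionCounts Named integer: distinct constituent
#'   reactions per model (subnetwork criterion only).
#' @slot constituentCommonCount Constituent reactions common to all models.
#' @slot criterion `"net_stoichiometry"` or `"subnetwork"`.
#' @export
setClass("LumpComparison",
  representation(commonCount = "integer", uniqueCounts = "integer",
                 partialCount = "integer", totalDistinct = "integer",
                 constituentUnionCounts = "integer",
                 constituentCommonCount = "integer", criterion = "character"))

setValidity("LumpComparison", function(object) {
  if (object@commonCount + sum(object@uniqueCounts) + object@partialCount !=
      object@totalDistinct)
    return("lump counts do not add up to the distinct total")
  if (object@commonCount < 0 || any(object@uniqueCounts < 0))
    return("negative count")
  TRUE
})

#' ThermoParams: thermodynamic constants and displacement exclusion
#'
#' @slot RT Gas constant times temperature, kJ/mol (default 2.4789, 310.15 K).
#' @slot delta Minimum |ln Gamma| for active reactions (equilibrium
#'   exclusion), dimensionless, > 0.
#' @slot concDefault Default log-concentration window `c(lb, ub)` in
#'   ln(mol/L) for metabolites without explicit bounds.
#' @slot bigMEnergy Big-M constant for energy couplings, kJ/mol.
#' @slot basalFlux Minimum |net flux| (mmol/gDW/h) a reaction must carry
#'   once a direction binary is set: reactions are either off or active at
#'   basal level, never at an exact zero with an assigned direction.
#' @slot fixedActivity Metabolite ids excluded from concentration terms
#'   (water, protons).
#' @export
setClass("ThermoParams",
  representation(RT = "numeric", delta = "numeric", concDefault = "numeric",
                 bigMEnergy = "numeric", basalFlux = "numeric",
                 fixedActivity = "character"))

setValidity("ThermoParams", function(object) {
  if (object@RT <= 0) return("RT must be > 0")
  if (object@delta <= 0) return("delta must be > 0")
  if (object@basalFlux <= 0) return("basalFlux must be > 0")
  if (object@concDefault[1] > object@concDefault[2]) return("concDefault lb > ub")
  TRUE
})

#' TFAProblem: MILP formulation of thermodynamics-based flux analysis
#'
#' Variables: per reaction, net flux `NF`, forward/backward parts `VF`/`VR`
#' and direction binaries `BF`/`BR`; per covered reaction a Gibbs energy
#' `DG`; per covered metabolite a log-concentration `LNX`.
#'
#' @slot model The underlying [MetabolicModel-class].
#' @slot params [ThermoParams-class] used to build the problem.
#' @slot vars `data.frame` (name, type, id, lb, ub, integer).
#' @slot lp The `lpProblem` constraint container.
#' @slot thermoRxns Ids of reactions carrying thermodynamic constraints.
#' @slot notes List of bookkeeping records (applied physiology bounds, ...).
#' @export
setClass("TFAProblem",
  representation(model = "MetabolicModel", params = "ThermoParams",
                 vars = "data.frame", lp = "lpProblem",
                 thermoRxns = "character", notes = "list"))

#' TVAResult: variability ranges from thermodynamic variability analysis
#'
#' @slot ranges `data.frame` (variable, type, id, min, max).
#' @slot tol Flux tolerance used for bidirectionality classification.
#' @export
setClass("TVAResult",
  representation(ranges = "data.frame", tol = "numeric"))

setValidity("TVAResult", function(object) {
  ok <- is.na(object@ranges$min) | is.na(object@ranges$max) |
    object@ranges$min <= object@ranges$max + 1e-7
  if (!all(ok)) return("range with min > max")
  TRUE
})

#' SamplePool: rows of feasible samples from a convex polytope
#'
#' @slot samples Numeric matrix, one sample per row, columns named by
#'   variable id.
#' @slot seed Integer seed the sampler was run with.
#' @slot sampler Sampler name.
#' @slot settings Sampler settings (warmup, thinning, ...).
#' @export
setClass("SamplePool",
  representation(samples = "matrix", seed = "integer", sampler = "character",
                 settings = "list"))

setValidity("SamplePool", function(object) {
  if (is.null(colnames(object@samples))) return("samples must have column names")
  TRUE
})

#' SteadyState: a paired flux / log-concentration reference state
#'
#' @slot fluxes Named net-flux vector (mmol/gDW/h) satisfying `S v = 0`.
#' @slot lnConc Named log-concentration vector, ln(mol/L).
#' @slot gamma Named per-reaction thermodynamic displacement
#'   Gamma = exp(dG/RT) (`NA` for reactions without thermodynamic data).
#' @slot model Name of the model the state belongs to.
#' @slot provenance List (seed, selection method, sample index, ...).
#' @export
setClass("SteadyState",
  representation(fluxes = "numeric", lnConc = "numeric", gamma = "numeric",
                 model = "character", provenance = "list"))

#' TransferProblem: band-violation MILP for steady-state transfer
#'
#' @slot lp The `lpProblem` with band constraints and violation binaries.
#' @slot vars Variable table of the underlying TFA problem, extended with
#'   the `Z` violation binaries.
#' @slot bands `data.frame` (id, ref, flb, fub, LB, UB) for banded variables.
#' @slot phase `"flux"` or `"concentration"`.
#' @slot relaxation Band half-width as a fraction of |reference|.
#' @export
setClass("TransferProblem",
  representation(lp = "lpProblem", vars = "data.frame", bands = "data.frame",
                 phase = "character", relaxation = "numeric"))

#' TransferReport: outcome of a minimum-violation transfer
#'
#' @slot objective Minimum number of violated bands.
#' @slot violated Ids whose bands could not be kept.
#' @slot table Per-id reference, achieved value and percent deviation.
#' @slot phase `"flux"` or `"concentration"`.
#' @export
setClass("TransferReport",
  representation(objective = "numeric", violated = "character",
                 table = "data.frame", phase = "character"))

setValidity("TransferReport", function(object) {
  if (length(object@violated) != object@objective)
    return("objective != number of violated ids")
  TRUE
})

#' MechanismSet: kinetic mechanism assignment for every reaction
#'
#' @slot mechanisms `data.frame` (reaction_id, mechanism) with mechanism in
#'   convenience / reversible_hill / mass_action.
#' @slot pairs `data.frame` of enzyme-metabolite pairs (reaction_id,
#'   metabolite_id, role in substrate/product/inhibitor/activator, n =
#'   |stoichiometric coefficient|, hill).  These pairs define which
#'   saturations are sampled.
#' @export
setClass("MechanismSet",
  representation(mechanisms = "data.frame", pairs = "data.frame"))

setValidity("MechanismSet", function(object) {
  p <- object@pairs
  if (!all(p$role %in% c("substrate", "product", "inhibitor", "activator")))
    return("unknown pair role")
  if (any(p$hill < 1)) return("Hill coefficients must be >= 1")
  TRUE
})

#' SaturationEnsemble: sampled enzyme saturation states
#'
#' @slot sigma Matrix (instances x pairs) of saturations in (0, 1); columns
#'   named `"reaction@metabolite"`.
#' @slot pairs The pair table of the generating [MechanismSet-class].
#' @slot seed Sampling seed.
#' @slot info List (retention flags, provenance).
#' @export
setClass("SaturationEnsemble",
  representation(sigma = "matrix", pairs = "data.frame", seed = "integer",
                 info = "list"))

setValidity("SaturationEnsemble", function(object) {
  s <- object@sigma
  if (length(s) && (any(s <= 0) || any(s >= 1)))
    return("saturations must lie strictly inside (0, 1)")
  TRUE
})

#' ReducedSystem: conserved-moiety reduction of a stoichiometric matrix
#'
#' @slot NR Reduced stoichiometric matrix (independent metabolites x
#'   reactions).
#' @slot L Link matrix (all metabolites x independent metabolites) with
#'   `S = L NR` after row reordering.
#' @slot independentIds,dependentIds Metabolite id partition.
#' @export
setClass("ReducedSystem",
  representation(NR = "Matrix", L = "Matrix", independentIds = "character",
                 dependentIds = "character"))

#' StabilityReport: eigenvalue-based local stability verdict
#'
#' @slot eigenvalues Complex eigenvalues of the reduced Jacobian.
#' @slot maxRealPart Largest real part.
#' @slot stable TRUE iff `maxRealPart <= tol`.
#' @slot tol Numerical slack (default 1e-9).
#' @export
setClass("StabilityReport",
  representation(eigenvalues = "complex", maxRealPart = "numeric",
                 stable = "logical", tol = "numeric"))

setValidity("StabilityReport", function(object) {
  if (!identical(object@stable, object@maxRealPart <= object@tol))
    return("stable flag inconsistent with maxRealPart and tol")
  TRUE
})

#' ControlMatrices: flux and concentration control coefficients
#'
#' @slot FCC Matrix (fluxes x enzymes) of scaled flux control coefficients;
#'   rows sum to 1 (summation theorem).
#' @slot CCC Matrix (independent metabolites x enzymes) of scaled
#'   concentration control coefficients; rows sum to 0.
#' @export
setClass("ControlMatrices",
  representation(FCC = "matrix", CCC = "matrix"))

#' KineticEnsemble: a population of kinetic model parameterisations
#'
#' One steady state, many saturation draws; each draw yields an elasticity
#' matrix, a stability verdict and (if stable) control coefficient matrices.
#'
#' @slot state The reference [SteadyState-class].
#' @slot saturations The [SaturationEnsemble-class] sampled.
#' @slot stability `data.frame` (instance, maxRealPart, stable, singular).
#' @slot FCC 3-d array (fluxes x enzymes x stable instances).
#' @slot CCC 3-d array (independent metabolites x enzymes x stable
#'   instances).
#' @slot counts List: sampled, stable, unstable, singular.
#' @export
setClass("KineticEnsemble",
  representation(state = "SteadyState", saturations = "SaturationEnsemble",
                 stability = "data.frame", FCC = "array", CCC = "array",
                 counts = "list"))

setValidity("KineticEnsemble", function(object) {
  cnt <- object@counts
  if (cnt$sampled != cnt$stable + cnt$unstable + cnt$singular)
    return("counts inconsistent: sampled != stable + unstable + singular")
  if (dim(object@FCC)[3] != cnt$stable)
    return("FCC array third dimension != stable count")
  TRUE
})

#' DIReport: deviation indices over a shared enzyme set
#'
#' @slot table `data.frame` (flux_id, di, percentile_class).
#' @slot sharedEnzymes Enzyme (reaction) ids summed over.
#' @slot aggregation `"population_mean_fcc"` or `"per_instance_mean"`.
#' @slot perInstance Optional matrix (fluxes x instances) of per-instance DI.
#' @export
setClass("DIReport",
  representation(table = "data.frame", sharedEnzymes = "character",
                 aggregation = "character", perInstance = "matrix"))

setValidity("DIReport", function(object) {
  if (any(object@table$di < -1e-12)) return("negative deviation index")
  TRUE
})

#' RankingReport: enzymes ranked by absolute mean control over a target flux
#'
#' @slot table `data.frame` (enzyme, mean_fcc, abs_mean, q25, q75) sorted by
#'   `abs_mean` descending.
#' @slot target Target flux id.
#' @slot topK Number of top controllers highlighted (default 9).
#' @export
setClass("RankingReport",
  representation(table = "data.frame", target = "character", topK = "integer"))

#' SubsystemDeviationReport: subsystem-wise absolute FCC deviations
#'
#' @slot deviations Matrix (reactions x subsystems): the sum over shared
#'   enzymes of a subsystem of |mean FCC difference| between two ensembles.
#' @slot referenceFlux Named reference fluxes of the row reactions.
#' @export
setClass("SubsystemDeviationReport",
  representation(deviations = "matrix", referenceFlux = "numeric"))
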