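## Synthetic nested toy model families.
##
## The generator emulates the structure the workflow assumes from
## systematically reduced models: a shared central-carbon-like core (linear
## backbone, one branch point, an ATP/ADP conserved pair, a lumped reaction
## feeding a biomass building block), expanded level by level with
## two-reaction parallel routes around hub metabolites, so larger models
## strictly contain smaller ones.  Standard Gibbs energies are assigned so
## that a forward-driven, away-from-equilibrium steady state exists at a
## nominal concentration of 1 mM for every species.

.toyHubPairs <- list(c("C_c", "P_c"), c("B_c", "D_c"), c("C_c", "E_c"),
                     c("B_c", "P_c"), c("D_c", "P_c"))

#' Generate a nested family of toy models
#'
#' @param coreSize Number of non-exchange core reactions (>= 11; the
#'   default 12 adds one extra backbone step).
#' @param nLevels Nesting depth (default 3).
#' @param expansionsPerLevel Parallel two-reaction routes added per level
#'   (default 2).
#' @param includeMoiety Include the ATP/ADP conserved pair (default TRUE).
#' @param seed Integer seed (Gibbs-energy draws).
#' @param dgSpread Range of the thermodynamic driving force (kJ/mol,
#'   negative) sampled per reaction.
#' @param forcedBranchLB Lower flux bound imposed on the first reaction of
#'   every expansion route.  The default 1e-3 keeps every reaction weakly
#'   active so that no Jacobian row degenerates at zero flux (the same
#'   basal-activity convention as [addBasalTransporters()]); larger values
#'   force substantial flux through the added branches and provoke
#'   transfer-band violations.
#' @return List with `models` (list of [MetabolicModel-class], smallest
#'   first), `mappings` (list of [NestedMapping-class], level k -> k+1),
#'   and `physiology` (bounds table for [buildTFAProblem()], built on the
#'   smallest model's core).
#' @export
generateNestedToys <- function(coreSize = 12, nLevels = 3,
                               expansionsPerLevel = 2,
                               includeMoiety = TRUE, seed = 1L,
                               dgSpread = c(-20, -5),
                               forcedBranchLB = 1e-3) {
  stopifnot(coreSize >= 11, nLevels >= 1, expansionsPerLevel >= 1,
            dgSpread[1] <= dgSpread[2], dgSpread[2] < 0)
  restore <- .restoreSeed(); on.exit(restore())
  set.seed(seed)

  row <- function(rxn, mets, coefs, lb, ub, subsystem, kind)
    data.frame(rxn_id = rxn, metabolite_id = mets, coeff = coefs,
               lb = lb, ub = ub, subsystem = subsystem, kind = kind,
               dG0 = NA_real_, dG0_err = NA_real_, stringsAsFactors = FALSE)

  core <- list(
    row("EX_A", "A_e", -1, -10, -1, "Exchange", "exchange"),
    row("At", c("A_e", "A_c"), c(-1, 1), 0, 10, "Transport", "transport"),
    if (includeMoiety)
      row("R1", c("A_c", "atp_c", "B_c", "adp_c"), c(-1, -1, 1, 1),
          0, 10, "Upper glycolysis", "enzymatic")
    else
      row("R1", c("A_c", "B_c"), c(-1, 1), 0, 10, "Upper glycolysis",
          "enzymatic"),
    row("R2", c("B_c", "C_c"), c(-1, 1), -10, 10, "Upper glycolysis",
        "enzymatic"),
    row("R3", c("C_c", "D_c"), c(-1, 1), 0, 10, "Lower glycolysis",
        "enzymatic"),
    row("R4", c("D_c", "E_c"), c(-1, 1), 0, 10, "Lower glycolysis",
        "enzymatic"),
    row("R6", c("C_c", "F_c"), c(-1, 1), 0, 10, "Branch", "enzymatic"),
    row("R7", c("F_c", "P_c"), c(-1, 1), 0, 10, "Branch", "enzymatic"),
    if (includeMoiety)
      row("RATP", c("adp_c", "atp_c"), c(-1, 1), 0, 10, "Energy",
          "enzymatic"),
    row("LMPD_BBB1", c("C_c", "D_c", "bbb_c"), c(-0.5, -0.5, 1), 0, 1,
        "Lump", "lumped"),
    row("Pt", c("P_c", "P_e"), c(-1, 1), 0, 10, "Transport", "transport"),
    row("EX_P", "P_e", -1, 0, 10, "Exchange", "exchange"),
    row("EX_BBB", "bbb_c", -1, 0, 1, "Exchange", "exchange"))
  core <- core[!vapply(core, is.null, logical(1))]

  ## extra backbone steps E -> K1 -> ... -> P (coreSize - 11 of them)
  nExtra <- coreSize - 11L + if (includeMoiety) 0L else 1L
  chainMets <- if (nExtra > 1) paste0("K", seq_len(nExtra - 1), "_c")
               else character()
  chain <- c("E_c", chainMets, "P_c")
  for (k in seq_len(length(chain) - 1L)) {
    core[[length(core) + 1L]] <- row(paste0("R5_", k),
                                     c(chain[k], chain[k + 1]), c(-1, 1),
                                     0, 10, "Lower glycolysis", "enzymatic")
  }

  levels <- list(do.call(rbind, core))
  for (l in seq_len(nLevels - 1L) + 1L) {
    prev <- levels[[l - 1L]]
    add <- list()
    for (e in seq_len(expansionsPerLevel)) {
      hub <- .toyHubPairs[[(((l - 2L) * expansionsPerLevel + e - 1L) %%
                              length(.toyHubPairs)) + 1L]]
      mid <- sprintf("x%d%d_c", l, e)
      add[[length(add) + 1L]] <- row(sprintf("XP%d_%d_1", l, e),
                                     c(hub[1], mid), c(-1, 1),
                                     forcedBranchLB, 5,
                                     sprintf("Expansion L%d", l), "enzymatic")
      add[[length(add) + 1L]] <- row(sprintf("XP%d_%d_2", l, e),
                                     c(mid, hub[2]), c(-1, 1), 0, 5,
                                     sprintf("Expansion L%d", l), "enzymatic")
    }
    levels[[l]] <- rbind(prev, do.call(rbind, add))
  }

  ## Gibbs energies: one driving force per reaction, shared across levels.
  ## At the nominal state (all ln x = ln 1e-3) every covered reaction has
  ## dG = drive < 0, so a forward-driven non-equilibrium state exists.
  lnx0 <- log(1e-3)
  RT <- 2.4789
  allRxn <- unique(unlist(lapply(levels, function(tb) tb$rxn_id)))
  drives <- stats::setNames(stats::runif(length(allRxn), dgSpread[1],
                                         dgSpread[2]), allRxn)
  drives["RATP"] <- -30   # energy regeneration strongly driven
  models <- lapply(seq_along(levels), function(l) {
    tb <- levels[[l]]
    first <- !duplicated(tb$rxn_id)
    for (r in unique(tb$rxn_id)) {
      kind <- tb$kind[tb$rxn_id == r][1]
      if (kind == "exchange") next
      sel <- tb$rxn_id == r
      nsum <- sum(tb$coeff[sel])   # sum of coefficients; all ln x = lnx0
      tb$dG0[sel & first] <- drives[[r]] - RT * nsum * lnx0
      tb$dG0_err[sel & first] <- 1
    }
    m <- makeModel(sprintf("toy_D%d", l), tb)
    m@metabolites$is_bbb[m@metabolites$id == "bbb_c"] <- TRUE
    m
  })

  mappings <- if (nLevels > 1)
    lapply(seq_len(nLevels - 1L),
           function(l) buildNestedMapping(models[[l]], models[[l + 1L]]))
  else list()

  physiology <- generateReferencePhysiology(models[[1L]], seed = seed)
  list(models = models, mappings = mappings, physiology = physiology)
}

#' Generate a reference physiology bounds table for a model
#'
#' Draws an interior point of the model's TFA solution space (a short
#' hit-and-run run for fluxes, then for log-concentrations given that flux
#' profile), fixes the uptake exchange at its value, and bounds a
#' deterministic subset of fluxes and log-concentrations within
#' +-`tighten` of the point, so the point itself always remains feasible.
#' An interior point (rather than an LP vertex) emulates an operating
#' physiology: no measured flux sits exactly at zero and no concentration
#' at a solubility extreme.
#'
#' @param model A [MetabolicModel-class].
#' @param seed Integer seed (selects which variables get bounded).
#' @param tighten Half-width as a fraction of the value (default 0.2;
#'   0 gives exact point constraints).
#' @param floorFlux Absolute floor (mmol/gDW/h) entering the flux
#'   half-width as `tighten * max(|v|, floorFlux)`, emulating the absolute
#'   uncertainty of fluxomics measurements; keeps near-zero measured
#'   fluxes from pinching off the basal activity of expansion reactions.
#' @param floorConc Analogous floor for log-concentration bands.
#' @param minMeasurable Detection limit (mmol/gDW/h): fluxes whose solved
#'   value is below it are left unconstrained, as fluxomics cannot resolve
#'   them; pinning them near zero would also degenerate the kinetic
#'   models' Jacobians.
#' @param params [ThermoParams-class] used for the feasibility solve.
#' @return `data.frame(type, id, lb, ub, units)` for [buildTFAProblem()].
#' @export
generateReferencePhysiology <- function(model, seed = 1L, tighten = 0.2,
                                        floorFlux = 0.01, floorConc = 0.1,
                                        minMeasurable = 0.05,
                                        params = thermoParams()) {
  stopifnot(tighten >= 0)
  problem <- buildTFAProblem(model, params)
  pattern <- fixDirectionalities(problem)
  poolF <- sampleFluxSpace(problem, n = 50, seed = seed, pattern = pattern,
                           warmup = 300, thin = 2)
  vpt <- selectRepresentative(poolF)$values
  poolC <- sampleConcentrationSpace(problem, vpt, n = 50, seed = seed + 1L,
                                    warmup = 300, thin = 2)
  lnpt <- selectRepresentative(poolC)$values
  restore <- .restoreSeed(); on.exit(restore())
  set.seed(seed)

  rows <- list()
  ## fix the uptake exchange at its interior value
  ex <- model@reactions$id[model@reactions$kind == "exchange" &
                             model@reactions$lb < 0]
  if (length(ex)) {
    v <- vpt[[ex[1]]]
    rows[[1]] <- data.frame(type = "flux", id = ex[1], lb = v, ub = v,
                            units = NA_character_)
  }
  band <- function(v, half) c(v - half, v + half)
  enz <- model@reactions$id[model@reactions$kind %in%
                              c("enzymatic", "transport")]
  pick <- sort(sample(enz, ceiling(length(enz) / 2)))
  for (id in pick) {
    v <- vpt[[id]]
    if (abs(v) < minMeasurable) next    # below the detection limit
    b <- band(v, tighten * max(abs(v), floorFlux))
    rows[[length(rows) + 1L]] <- data.frame(type = "flux", id = id,
                                            lb = b[1], ub = b[2],
                                            units = NA_character_)
  }
  pickM <- sort(sample(names(lnpt), ceiling(length(lnpt) / 2)))
  for (id in pickM) {
    v <- lnpt[[id]]
    b <- band(v, tighten * max(abs(v), floorConc))
    rows[[length(rows) + 1L]] <- data.frame(type = "lnconc", id = id,
                                            lb = b[1], ub = b[2],
                                            units = "ln_M")
  }
  do.call(rbind, rows)
}

#' Write the standard synthetic test family to a directory
#'
#' Materialises the default nested family as TSV models plus the
#' physiology table — the `fixtures` CLI subcommand.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed to [generateNestedToys()].
#' @return The directory path, invisibly.
#' @export
writeToyFixtures <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- generateNestedToys(seed = seed, ...)
  for (m in fam$models)
    writeModelTSV(m, file.path(dir, paste0(modelName(m), ".tsv")))
  utils::write.table(fam$physiology, file.path(dir, "physiology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
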