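## Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

## The standard 3-level synthetic family used across the suite.
toyFamily <- function() fixture("family", generateNestedToys(seed = 42))

toyProblem <- function(level = 1) {
  fixture(paste0("problem", level), {
    fam <- toyFamily()
    buildTFAProblem(fam$models[[level]], physiology = fam$physiology)
  })
}

## Representative steady states: level 1 sampled, levels 2-3 transferred.
toyStates <- function() {
  fixture("states", {
    fam <- toyFamily()
    p1 <- toyProblem(1)
    pool <- sampleFluxSpace(p1, n = 150, seed = 421, warmup = 150, thin = 2)
    sel <- selectRepresentative(pool)
    poolC <- sampleConcentrationSpace(p1, sel$values, n = 150, seed = 422,
                                      warmup = 150, thin = 2)
    st <- list(makeSteadyState(p1, sel$values,
                               selectRepresentative(poolC)$values,
                               provenance = list(seed = 421)))
    transfers <- list()
    for (l in 2:3) {
      pl <- toyProblem(l)
      tr <- transferSteadyState(pl, fam$mappings[[l - 1]], st[[l - 1]],
                                n = 150, seed = 420 + 10 * l,
                                warmup = 150, thin = 2)
      st[[l]] <- tr$state
      transfers[[l - 1]] <- tr
    }
    list(states = st, transfers = transfers)
  })
}

## Kinetic ensembles: 200 instances at level 1, stratified into levels 2-3.
toyEnsembles <- function() {
  fixture("ensembles", {
    fam <- toyFamily()
    st <- toyStates()$states
    ens <- list(kineticEnsemble(fam$models[[1]], st[[1]], n = 200,
                                seed = 4242))
    for (l in 2:3) {
      mech <- assignMechanisms(fam$models[[l]])
      check <- makeStabilityCheck(fam$models[[l]], st[[l]], mech)
      strat <- stratifiedResample(ens[[l - 1]]@saturations,
                                  fam$mappings[[l - 1]], mech,
                                  seed = 4242 + l,
                                  stabilityCheck = check)
      ens[[l]] <- kineticEnsemble(fam$models[[l]], st[[l]], mech,
                                  saturations = strat)
    }
    ens
  })
}

## A minimal hand-written model: A_c -> B_c with exchanges on both sides.
miniModel <- function(dG0_R = NA, lbR = -10, ubR = 10) {
  makeModel("mini", data.frame(
    rxn_id = c("EX_A", "R", "R", "EX_B"),
    metabolite_id = c("A_c", "A_c", "B_c", "B_c"),
    coeff = c(1, -1, 1, -1),
    lb = c(-10, lbR, lbR, -10), ub = c(10, ubR, ubR, 10),
    subsystem = "s", kind = c("exchange", "enzymatic", "enzymatic",
                              "exchange"),
    dG0 = c(NA, dG0_R, dG0_R, NA), dG0_err = NA))
}
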