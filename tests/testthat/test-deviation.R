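## Hand-built two-instance ensemble with a known FCC array.
fakeEnsemble <- function(fcc1, fcc2 = fcc1) {
  rxns <- rownames(fcc1)
  st <- methods::new("SteadyState",
                     fluxes = stats::setNames(rep(1, length(rxns)), rxns),
                     lnConc = c(X_c = log(1e-3)), gamma = stats::setNames(
                       rep(NA_real_, length(rxns)), rxns),
                     model = "fake", provenance = list())
  sat <- methods::new("SaturationEnsemble",
                      sigma = matrix(0.5, 2, 1,
                                     dimnames = list(NULL, "r1@X_c")),
                      pairs = data.frame(reaction_id = "r1",
                                         metabolite_id = "X_c",
                                         role = "substrate", n = 1,
                                         hill = 1),
                      seed = 1L, info = list(retained = c(TRUE, TRUE)))
  methods::new("KineticEnsemble", state = st, saturations = sat,
               stability = data.frame(instance = 1:2,
                                      maxRealPart = -1, stable = TRUE,
                                      singular = FALSE),
               FCC = array(c(fcc1, fcc2),
                           dim = c(dim(fcc1), 2),
                           dimnames = c(dimnames(fcc1), list(NULL))),
               CCC = array(0, dim = c(1, length(rxns), 2),
                           dimnames = list("X_c", rxns, NULL)),
               counts = list(sampled = 2, stable = 2, unstable = 0,
                             singular = 0))
}

test_that("the deviation index follows the summation theorem exactly", {
  rxns <- c("a", "b", "c", "d")
  fcc <- matrix(c(0.5, 0.3, 0.1, 0.1,
                  0.2, 0.6, 0.1, 0.1,
                  0.4, 0.2, 0.2, 0.2,
                  0.1, 0.1, 0.4, 0.4), 4, byrow = TRUE,
                dimnames = list(rxns, rxns))
  ens <- fakeEnsemble(fcc)
  ## full enzyme set: DI = 0 for every flux
  full <- deviationIndex(ens, rxns)
  expect_true(all(full@table$di < 1e-12))
  ## excluded enzymes holding 0.2 mean control -> DI exactly 0.2
  di <- deviationIndex(ens, c("a", "b"))
  expect_equal(di@table$di, unname(abs(rowSums(fcc[, c("c", "d")]))),
               tolerance = 1e-12)
  expect_equal(di@table$di[3], 0.4, tolerance = 1e-12)
  ## DI equals |total mean FCC of the excluded set| for every flux
  expect_equal(di@table$di,
               unname(abs(rowSums(meanFCC(ens)[, c("c", "d")]))))
  expect_error(deviationIndex(ens, character()), "empty")
  expect_error(deviationIndex(ens, "nope"), "not in ensemble")
})

test_that("identical ensembles give zero DI through the real pipeline", {
  ens <- toyEnsembles()[[2]]
  full <- deviationIndex(ens, colnames(ens@FCC))
  expect_lt(max(full@table$di), 1e-6)
  ## per-instance aggregation obeys the same null
  fullPI <- deviationIndex(ens, colnames(ens@FCC),
                           aggregation = "per_instance_mean")
  expect_lt(max(fullPI@table$di), 1e-6)
})

test_that("percentile classes split at the 25th and 75th percentiles", {
  mk <- function(di) methods::new("DIReport",
    table = data.frame(flux_id = paste0("r", seq_along(di)), di = di,
                       percentile_class = NA_character_),
    sharedEnzymes = "x", aggregation = "population_mean_fcc",
    perInstance = matrix(di))
  r <- percentileClasses(mk(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(r@table$percentile_class, c("low", "mid", "mid", "high"))
  ## ties share the lower class
  expect_equal(percentileClasses(mk(rep(0.3, 5)))@table$percentile_class,
               rep("low", 5))
  expect_error(percentileClasses(mk(c(1, 2, 3))), "at least 4")
})

test_that("controller rankings are deterministic and quartile-bracketed", {
  rxns <- c("a", "b", "c", "d")
  f1 <- matrix(0.25, 4, 4, dimnames = list(rxns, rxns))
  f1["a", ] <- c(0.6, -0.5, 0.5, 0.4)
  f2 <- f1; f2["a", ] <- c(0.4, -0.7, 0.5, 0.75)
  ens <- fakeEnsemble(f1, f2)
  rk <- rankControllers(ens, "a", topK = 2)
  ## |means| 0.5, 0.6, 0.5, 0.575 -> b, d, then the a/c tie alphabetically
  expect_equal(rk@table$enzyme, c("b", "d", "a", "c"))
  expect_equal(rk@table$mean_fcc[1], -0.6)
  expect_true(all(rk@table$q25 <= rk@table$q75))
  expect_equal(rk@topK, 2L)
  expect_equal(rankControllers(ens, "a")@topK, 9L)   # default top-9

  ## single-instance ensembles rank by |FCC| of that instance
  e1 <- fakeEnsemble(f1)
  e1@FCC <- array(f1, dim = c(4, 4, 1), dimnames = list(rxns, rxns, NULL))
  e1@counts$sampled <- e1@counts$stable <- 1
  e1@stability <- e1@stability[1, ]
  rk1 <- rankControllers(e1, "a")
  expect_equal(rk1@table$abs_mean,
               unname(sort(abs(f1["a", ]), decreasing = TRUE)))

  ## pairwise union report covers both models' top sets
  un <- topControllerUnion(ens, e1, "a", sharedEnzymes = rxns, topK = 2)
  expect_true(all(c("enzyme", "mean_fcc_A", "mean_fcc_B") %in% names(un)))
  expect_gte(nrow(un), 2)
})

test_that("subsystem deviations are zero on identity and symmetric in A/B", {
  fam <- toyFamily()
  ens2 <- toyEnsembles()[[2]]
  mapId <- buildNestedMapping(fam$models[[2]], fam$models[[2]])
  devAA <- subsystemAbsDeviation(ens2, ens2, mapId, fam$models[[2]],
                                 fam$models[[2]])
  expect_true(all(devAA@deviations == 0))

  ens1 <- toyEnsembles()[[1]]
  map <- fam$mappings[[1]]
  devAB <- subsystemAbsDeviation(ens1, ens2, map, fam$models[[1]],
                                 fam$models[[2]])
  expect_true(all(devAB@deviations >= 0))
  expect_equal(devAB@referenceFlux,
               fluxes(ens1@state)[rownames(devAB@deviations)])
  ## symmetry: |meanA - meanB| does not depend on the comparison order
  mapBack <- methods::new("NestedMapping",
    smallName = map@largeName, largeName = map@smallName,
    shared = data.frame(id_small = map@shared$id_large,
                        id_large = map@shared$id_small),
    addedReactions = character(),
    sharedMetabolites = data.frame(
      id_small = map@sharedMetabolites$id_large,
      id_large = map@sharedMetabolites$id_small),
    addedMetabolites = character(), mismatches = character())
  devBA <- subsystemAbsDeviation(ens2, ens1, mapBack, fam$models[[2]],
                                 fam$models[[1]])
  rows <- rownames(devAB@deviations)   # shared ids, identical across levels
  expect_equal(unname(devBA@deviations[rows, ]),
               unname(devAB@deviations[rows, ]))

  ## one differing enzyme alone in its subsystem -> exactly its difference
  rxns <- c("a", "b", "c", "d")
  f <- matrix(0.25, 4, 4, dimnames = list(rxns, rxns))
  g <- f; g[, "a"] <- f[, "a"] + 0.1; g[, "b"] <- g[, "b"] - 0.1
  eA <- fakeEnsemble(f); eB <- fakeEnsemble(g)
  mA <- makeModel("mA", data.frame(
    rxn_id = rep(rxns, each = 2),
    metabolite_id = rep(c("X_c", "Y_c"), 4),
    coeff = rep(c(-1, 1), 4), lb = 0, ub = 10,
    subsystem = rep(c("s1", "s2", "s3", "s4"), each = 2),
    kind = "enzymatic", dG0 = NA, dG0_err = NA))
  idM <- buildNestedMapping(mA, mA)
  dev <- subsystemAbsDeviation(eA, eB, idM, mA, mA)
  expect_equal(unname(dev@deviations[, "s1"]), rep(0.1, 4))
  expect_true(all(dev@deviations[, "s3"] == 0))
})
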