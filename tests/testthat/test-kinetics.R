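test_that("mechanism assignment applies defaults and overrides", {
  m <- toyFamily()$models[[1]]
  mech <- assignMechanisms(m)
  mm <- mech@mechanisms
  expect_equal(mm$mechanism[mm$reaction_id == "R1"], "convenience")
  expect_equal(mm$mechanism[mm$reaction_id == "At"], "mass_action")
  expect_equal(mm$mechanism[mm$reaction_id == "EX_A"], "mass_action")

  over <- data.frame(reaction_id = "R2", mechanism = "reversible_hill",
                     hill = 2)
  mech2 <- assignMechanisms(m, overrides = over)
  expect_equal(mech2@mechanisms$mechanism[
    mech2@mechanisms$reaction_id == "R2"], "reversible_hill")
  expect_true(all(mech2@pairs$hill[mech2@pairs$reaction_id == "R2"] == 2))
  expect_error(assignMechanisms(m, overrides = data.frame(
    reaction_id = "nope", mechanism = "convenience")), "unknown reaction")

  ## the declared pair set matches the stoichiometry sparsity pattern
  S <- stoichMatrix(m)
  for (k in seq_len(nrow(mech@pairs)))
    expect_true(S[mech@pairs$metabolite_id[k],
                  mech@pairs$reaction_id[k]] != 0)
})

test_that("saturation sampling is uniform, bounded, and reproducible", {
  mech <- assignMechanisms(toyFamily()$models[[1]])
  ens <- sampleSaturations(mech, 10000, seed = 77)
  sig <- ens@sigma
  expect_true(all(sig > 0 & sig < 1))
  ## empirical means within 3 standard errors of 1/2 (uniform moments)
  se <- sqrt(1 / 12) / sqrt(nrow(sig))
  expect_true(all(abs(colMeans(sig) - 0.5) < 3 * se))
  expect_identical(sampleSaturations(mech, 10000, seed = 77)@sigma, sig)

  ## literature-derived saturations stay fixed across instances
  key <- colnames(sig)[1]
  f <- sampleSaturations(mech, 50, seed = 1,
                         fixed = stats::setNames(0.25, key))
  expect_true(all(f@sigma[, key] == 0.25))
  expect_equal(saturationFromKm(1e-3, 3e-3), 0.25)
})

test_that("elasticities reproduce the hand-computed displacement algebra", {
  ## one reaction S_c -> P_c at a controlled displacement
  mk <- function(gamma, vsign = 1) {
    RT <- 2.4789
    tb <- data.frame(
      rxn_id = c("EX_S", "R", "R", "EX_P"),
      metabolite_id = c("S_c", "S_c", "P_c", "P_c"),
      coeff = c(1, -1, 1, -1), lb = -10, ub = 10, subsystem = "s",
      kind = c("exchange", "enzymatic", "enzymatic", "exchange"),
      dG0 = c(NA, RT * log(gamma), RT * log(gamma), NA), dG0_err = NA)
    model <- makeModel("one", tb)
    prob <- buildTFAProblem(model)
    lnc <- stats::setNames(rep(0, 2), c("S_c", "P_c"))  # x = 1 M
    v <- vsign * c(EX_S = 1, R = 1, EX_P = 1)
    state <- makeSteadyState(prob, v, lnc)
    list(model = model, state = state, mech = assignMechanisms(model))
  }
  ## irreversible limit Gamma -> 0 with sigma = 0: mass-action value 1
  t0 <- mk(1e-12)
  sig <- c("R@S_c" = 1e-9, "R@P_c" = 0.3,
           "EX_S@S_c" = 0.5, "EX_P@P_c" = 0.5)
  E <- elasticitiesFromSaturations(sig, t0$mech, t0$state)
  expect_equal(E["R", "S_c"], 1, tolerance = 1e-6)

  ## Gamma = 0.5: substrate (1 - 0.4) + 0.5/0.5 = 1.6,
  ##              product  -0.3 - 0.5/0.5 = -1.3
  t5 <- mk(0.5)
  sig5 <- c("R@S_c" = 0.4, "R@P_c" = 0.3,
            "EX_S@S_c" = 0.5, "EX_P@P_c" = 0.5)
  E5 <- elasticitiesFromSaturations(sig5, t5$mech, t5$state)
  expect_equal(E5["R", "S_c"], 1.6, tolerance = 1e-12)
  expect_equal(E5["R", "P_c"], -1.3, tolerance = 1e-12)

  ## backward operation swaps roles and inverts the displacement
  tb <- mk(2, vsign = -1)   # Gamma(written) = 2 -> oriented 0.5
  Eb <- elasticitiesFromSaturations(sig5, tb$mech, tb$state)
  expect_equal(Eb["R", "P_c"], (1 - 0.3) + 1, tolerance = 1e-12)
  expect_equal(Eb["R", "S_c"], -0.4 - 1, tolerance = 1e-12)

  ## near equilibrium the elasticities are refused by name
  teq <- mk(1 + 1e-9)
  expect_error(elasticitiesFromSaturations(sig5, teq$mech, teq$state),
               "R.*equilibrium")
  ## substrate elasticity grows monotonically along a Gamma ramp
  ramp <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(g) {
    t <- mk(g)
    elasticitiesFromSaturations(sig5, t$mech, t$state)["R", "S_c"]
  }, numeric(1))
  expect_true(all(diff(ramp) > 0))
})

test_that("every mechanism's elasticities match the rate-law oracle", {
  for (topo in c("chain", "branch", "moiety")) {
    toy <- oracleToy(topo, seed = 3)
    E <- elasticitiesFromSaturations(toy$sigma, toy$mech, toy$state)
    rf <- oracleRateFactory(toy$model, toy$mech, toy$sigma, toy$state)
    Efd <- oracleElasticities(toy$model, rf$rates, rf$xref)
    expect_equal(E[rownames(Efd), colnames(Efd)], Efd, tolerance = 1e-6)
    ## sparsity: non-participating metabolites have exactly zero entries
    S <- as.matrix(stoichMatrix(toy$model))
    zero <- t(S[colnames(E), rownames(E)]) == 0
    expect_true(all(E[zero] == 0))
  }

  ## reversible Hill and modifiers, against the same oracle
  toy <- oracleToy("chain", seed = 11)
  over <- data.frame(reaction_id = "S1", mechanism = "reversible_hill",
                     hill = 2)
  mods <- data.frame(reaction_id = "S2", metabolite_id = "X_c",
                     type = "inhibitor")
  mech <- assignMechanisms(toy$model, overrides = over, modifiers = mods)
  sigma <- sampleSaturations(mech, 1, seed = 12)@sigma[1, ]
  E <- elasticitiesFromSaturations(sigma, mech, toy$state)
  rf <- oracleRateFactory(toy$model, mech, sigma, toy$state)
  Efd <- oracleElasticities(toy$model, rf$rates, rf$xref)
  expect_equal(E[rownames(Efd), colnames(Efd)], Efd, tolerance = 1e-6)
})

test_that("stratified resampling copies shared saturations bit-exactly", {
  fam <- toyFamily()
  m1 <- fam$models[[1]]
  mech1 <- assignMechanisms(m1)
  ens <- sampleSaturations(mech1, 20, seed = 5)

  ## identical models: output equals input bit for bit, retention 100%
  idMap <- buildNestedMapping(m1, m1)
  out <- stratifiedResample(ens, idMap, mech1, seed = 6)
  expect_identical(out@sigma[, colnames(ens@sigma)], ens@sigma)
  expect_equal(out@info$retainedFraction, 1)

  ## into the larger model: shared pairs equal the source exactly
  mech2 <- assignMechanisms(fam$models[[2]])
  out2 <- stratifiedResample(ens, fam$mappings[[1]], mech2, seed = 6)
  sharedKeys <- intersect(colnames(ens@sigma), colnames(out2@sigma))
  expect_gt(length(sharedKeys), 0)
  expect_identical(out2@sigma[, sharedKeys], ens@sigma[, sharedKeys])
  ## new pairs were actually resampled
  newKeys <- setdiff(colnames(out2@sigma), sharedKeys)
  expect_gt(length(newKeys), 0)
  expect_true(all(out2@sigma[, newKeys] > 0 & out2@sigma[, newKeys] < 1))

  ## determinism of the retained set and values
  out3 <- stratifiedResample(ens, fam$mappings[[1]], mech2, seed = 6)
  expect_identical(out3@sigma, out2@sigma)

  ## a rejecting stability check reports the retained fraction
  flaky <- local({
    i <- 0
    function(sig) { i <<- i + 1; i %% 3 == 0 }
  })
  out4 <- stratifiedResample(ens, fam$mappings[[1]], mech2, seed = 7,
                             stabilityCheck = flaky, maxTries = 2)
  expect_true(out4@info$retainedFraction < 1)
  expect_equal(out4@info$retainedFraction, mean(out4@info$retained))
})
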