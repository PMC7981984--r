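## A reference steady state for the mini model, built from a TFA solve.
miniReference <- function(prob) {
  res <- solveTFA(prob, objective = c("NF:R" = 1), sense = "max")
  vars <- prob@vars
  nf <- res$x[nestMCA:::.varIdx(vars, "NF")]
  names(nf) <- vars$id[nestMCA:::.varIdx(vars, "NF")]
  ln <- res$x[nestMCA:::.varIdx(vars, "LNX")]
  names(ln) <- vars$id[nestMCA:::.varIdx(vars, "LNX")]
  makeSteadyState(prob, nf, ln)
}

test_that("band construction follows the relaxation and floor rules", {
  prob <- buildTFAProblem(miniModel(dG0_R = -10))
  ref <- miniReference(prob)
  tp <- buildTransferMILP(prob, buildNestedMapping(prob@model, prob@model),
                          ref, relaxation = 0.01)
  b <- tp@bands[tp@bands$id == "R", ]
  ## ref = 10 (maximised), 1% relaxation -> band [9.9, 10.1]
  expect_equal(unname(c(b$flb, b$fub)), c(0.99, 1.01) * b$ref)

  ## a zero reference flux gets the absolute floor: [-1e-8, +1e-8]
  ref0 <- ref
  ref0@fluxes["R"] <- 0
  ref0@fluxes["EX_A"] <- 0
  ref0@fluxes["EX_B"] <- 0
  tp0 <- buildTransferMILP(prob, buildNestedMapping(prob@model, prob@model),
                           ref0, relaxation = 0.01, floor = 1e-6)
  b0 <- tp0@bands[tp0@bands$id == "R", ]
  expect_equal(unname(c(b0$flb, b0$fub)), c(-1e-8, 1e-8))
})

test_that("z = 0 enforces the band and z = 1 recovers the model bounds", {
  ## algebraic substitution of the band constraints, checked by solving
  prob <- buildTFAProblem(miniModel(dG0_R = -10))
  ref <- miniReference(prob)
  tp <- buildTransferMILP(prob, buildNestedMapping(prob@model, prob@model),
                          ref, relaxation = 0.01)
  lp <- tp@lp
  zi <- grep("^Z:NF:R$", lp$names)
  xi <- match("NF:R", lp$names)
  cc <- numeric(length(lp$lb))
  cc[xi] <- 1
  for (zfix in c(0, 1)) {
    ov <- stats::setNames(zfix, zi)
    rng <- vapply(c("min", "max"), function(s)
      solveLP(lp, list(list(c = cc, sense = s, lbOverride = ov,
                            ubOverride = ov)))[[1]]$objective, numeric(1))
    if (zfix == 0) {
      b <- tp@bands[tp@bands$id == "R", ]
      expect_gte(rng[["min"]], b$flb - 1e-7)
      expect_lte(rng[["max"]], b$fub + 1e-7)
    } else {
      ## with the band inactive the full model range returns
      expect_lt(rng[["min"]], 1e-7)
      expect_equal(rng[["max"]], 10, tolerance = 1e-6)
    }
  }
})

test_that("identity transfer yields zero violations and banded fluxes", {
  fam <- toyFamily()
  prob <- toyProblem(1)
  st <- toyStates()$states[[1]]
  map <- buildNestedMapping(fam$models[[1]], fam$models[[1]])
  tp <- buildTransferMILP(prob, map, st, relaxation = 0.01)
  rep <- minimizeViolations(tp)
  expect_equal(rep@objective, 0)
  expect_length(rep@violated, 0)
  ## achieved fluxes sit inside their bands
  expect_true(all(rep@table$achieved >= tp@bands$flb - 1e-7 &
                  rep@table$achieved <= tp@bands$fub + 1e-7))
})

test_that("a forced expansion branch provokes exactly the expected violation", {
  ## Small: fixed uptake 1 routed through R1.  Large adds branch RB with a
  ## forced lower bound 0.1, so R1 <= 0.9 and its 1% band [0.99, 1.01]
  ## cannot hold; no other band is affected.  Exhaustive reasoning over
  ## the binaries: with z_R1 = 0 infeasible, z_R1 = 1 feasible -> optimum 1.
  small <- makeModel("tsmall", data.frame(
    rxn_id = c("EX_in", "R1", "R1", "EX_out"),
    metabolite_id = c("X_c", "X_c", "Y_c", "Y_c"),
    coeff = c(1, -1, 1, -1),
    lb = c(1, 0, 0, 0), ub = c(1, 10, 10, 10),
    subsystem = "s", kind = c("exchange", "enzymatic", "enzymatic",
                              "exchange"),
    dG0 = NA, dG0_err = NA))
  largeTab <- data.frame(
    rxn_id = c("EX_in", "R1", "R1", "RB", "RB", "EX_out"),
    metabolite_id = c("X_c", "X_c", "Y_c", "X_c", "Y_c", "Y_c"),
    coeff = c(1, -1, 1, -1, 1, -1),
    lb = c(1, 0, 0, 0.1, 0.1, 0), ub = c(1, 10, 10, 10, 10, 10),
    subsystem = "s", kind = c("exchange", "enzymatic", "enzymatic",
                              "enzymatic", "enzymatic", "exchange"),
    dG0 = NA, dG0_err = NA)
  large <- makeModel("tlarge", largeTab)
  mapping <- buildNestedMapping(small, large)
  probS <- buildTFAProblem(small)
  ref <- makeSteadyState(probS, c(EX_in = 1, R1 = 1, EX_out = 1),
                         stats::setNames(rep(log(1e-3), 2),
                                         c("X_c", "Y_c")))
  probL <- buildTFAProblem(large)
  tp <- buildTransferMILP(probL, mapping, ref, relaxation = 0.01)
  rep <- minimizeViolations(tp)
  expect_equal(rep@objective, 1)
  expect_equal(rep@violated, "R1")
  ## enumeration of all minimum-cardinality sets agrees
  sets <- enumerateViolationSets(tp, 1)
  expect_true(list("R1") %in% sets)
})

test_that("decreasing the relaxation never decreases the optimum", {
  fam <- toyFamily()
  st <- toyStates()$states[[1]]
  prob2 <- toyProblem(2)
  objs <- vapply(c(0.05, 0.01, 0.001), function(rx) {
    tp <- buildTransferMILP(prob2, fam$mappings[[1]], st, relaxation = rx)
    minimizeViolations(tp)@objective
  }, numeric(1))
  expect_true(all(diff(objs) >= 0))
})

test_that("two-phase transfer returns a state within the kept bands", {
  fam <- toyFamily()
  st <- toyStates()
  tr <- st$transfers[[1]]
  state2 <- tr$state
  expect_s4_class(state2, "SteadyState")
  ## every non-violated shared flux within its 1% band
  prob2 <- toyProblem(2)
  tp <- buildTransferMILP(prob2, fam$mappings[[1]], st$states[[1]],
                          relaxation = 0.01)
  kept <- !(tp@bands$id %in% tr$fluxReport@violated)
  v2 <- fluxes(state2)[tp@bands$id[kept]]
  expect_true(all(v2 >= tp@bands$flb[kept] - 1e-7 &
                  v2 <= tp@bands$fub[kept] + 1e-7))
  ## violated reactions carry their percent deviation in the report
  if (length(tr$fluxReport@violated)) {
    tab <- tr$fluxReport@table
    expect_true(all(tab$percent_deviation[tab$violated] > 0))
  }
})
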