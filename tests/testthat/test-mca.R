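test_that("system reduction finds conserved moieties and satisfies S = L N_R", {
  fam <- toyFamily()
  m <- fam$models[[1]]
  red <- reduceSystem(m)
  ## the ATP/ADP pair leaves exactly one dependent metabolite, linked with
  ## coefficient -1 (hand elimination of the conservation atp + adp = T)
  expect_length(red@dependentIds, 1)
  expect_true(red@dependentIds %in% c("atp_c", "adp_c"))
  other <- setdiff(c("atp_c", "adp_c"), red@dependentIds)
  L <- as.matrix(red@L)
  expect_equal(unname(L[red@dependentIds, other]), -1)
  ## defining identity, exact
  expect_equal(as.matrix(red@L %*% red@NR)[metaboliteIds(m), ],
               as.matrix(stoichMatrix(m)))

  ## full-row-rank S: L is the identity
  loop <- oracleToy("chain")$model
  redc <- reduceSystem(loop)
  expect_length(redc@dependentIds, 0)
  expect_equal(as.matrix(redc@L), diag(nrow(stoichMatrix(loop))),
               ignore_attr = TRUE)
})

test_that("the reduced Jacobian matches hand algebra on small systems", {
  ## 1-metabolite chain: v1 constant, v2 with elasticity 1, v = x = 1
  tb <- data.frame(rxn_id = c("v1", "v2"), metabolite_id = "X_c",
                   coeff = c(1, -1), lb = 0, ub = 10, subsystem = "s",
                   kind = "exchange", dG0 = NA, dG0_err = NA)
  m <- makeModel("j1", tb)
  prob <- buildTFAProblem(m)
  st <- makeSteadyState(prob, c(v1 = 1, v2 = 1), c(X_c = 0))
  E <- matrix(c(0, 1), 2, 1, dimnames = list(c("v1", "v2"), "X_c"))
  red <- reduceSystem(m)
  J <- jacobianReduced(red, st, E)
  expect_equal(unname(J), matrix(-1))

  ## diagonal similarity: eigenvalues agree between linear- and log-space
  ## formulations J and D^-1 J D with D = diag(x)
  fam <- toyFamily()
  st1 <- toyStates()$states[[1]]
  mech <- assignMechanisms(fam$models[[1]])
  sig <- sampleSaturations(mech, 1, seed = 31)@sigma[1, ]
  Ef <- elasticitiesFromSaturations(sig, mech, st1)
  redf <- reduceSystem(fam$models[[1]])
  Jf <- jacobianReduced(redf, st1, Ef)
  x <- exp(lnConc(st1)[redf@independentIds])
  Jlog <- diag(1 / x) %*% Jf %*% diag(x)
  ev1 <- sort(Re(eigen(Jf, only.values = TRUE)$values))
  ev2 <- sort(Re(eigen(Jlog, only.values = TRUE)$values))
  expect_equal(ev1, ev2, tolerance = 1e-9)
})

test_that("stability verdicts follow the eigenvalues and an ODE oracle", {
  expect_true(checkStability(matrix(-1))@stable)
  expect_false(checkStability(matrix(0.5))@stable)
  expect_true(checkStability(matrix(c(-1, 0, 0, -1e-12), 2))@stable)
  expect_error(checkStability(matrix(NaN)), "non-finite")

  ## two-step pathway: the verdict agrees with relaxation of a perturbed
  ## ODE trajectory back to the steady state
  toy <- oracleToy("chain", seed = 9)
  E <- elasticitiesFromSaturations(toy$sigma, toy$mech, toy$state)
  red <- reduceSystem(toy$model)
  J <- jacobianReduced(red, toy$state, E)
  verdict <- checkStability(J)
  rf <- oracleRateFactory(toy$model, toy$mech, toy$sigma, toy$state)
  NR <- as.matrix(red@NR)
  e0 <- stats::setNames(rep(1, length(reactionIds(toy$model))),
                        reactionIds(toy$model))
  ## integrate in log space to respect positivity of concentrations
  deriv <- function(t, y, parms) {
    xx <- stats::setNames(exp(y), red@independentIds)
    list(as.numeric(NR %*% rf$rates(xx, e0)) / xx)
  }
  y0 <- log(rf$xref[red@independentIds] * 1.01)   # 1% perturbation
  tr <- deSolve::lsoda(y0, c(0, 0.5, 1), deriv)
  back <- abs(exp(tr[nrow(tr), -1]) - rf$xref[red@independentIds]) /
    rf$xref[red@independentIds]
  expect_true(verdict@stable)
  expect_true(all(back < 1e-4))
})

test_that("control coefficients recover the closed-form two-step chain", {
  ## elasticities (-1, 0.5) -> FCCs (1/3, 2/3) for the pathway flux
  tb <- data.frame(rxn_id = c("v1", "v2"), metabolite_id = "X_c",
                   coeff = c(1, -1), lb = 0, ub = 10, subsystem = "s",
                   kind = "enzymatic", dG0 = NA, dG0_err = NA)
  m <- makeModel("chain2", tb)
  prob <- buildTFAProblem(m)
  st <- makeSteadyState(prob, c(v1 = 1, v2 = 1), c(X_c = 0))
  E <- matrix(c(-1, 0.5), 2, 1, dimnames = list(c("v1", "v2"), "X_c"))
  cm <- controlCoefficients(reduceSystem(m), st, E)
  expect_equal(unname(cm@FCC["v1", ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(cm@FCC["v2", ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(rowSums(cm@CCC)), 0, tolerance = 1e-12)
})

test_that("matrix-formula FCCs match finite-difference ODE perturbation", {
  ## three topologies: linear chain, branch point, conserved-moiety cycle
  for (topo in c("chain", "branch", "moiety")) {
    toy <- oracleToy(topo, seed = 21)
    E <- elasticitiesFromSaturations(toy$sigma, toy$mech, toy$state)
    red <- reduceSystem(toy$model)
    cm <- controlCoefficients(red, toy$state, E)
    rf <- oracleRateFactory(toy$model, toy$mech, toy$sigma, toy$state)
    fd <- oracleFCC(toy$model, rf$rates, rf$xref, rel = 0.01)
    expect_equal(cm@FCC, fd, tolerance = 1e-4)
    ## flux connectivity: FCC E L = 0
    Efull <- matrix(0, nrow(cm@FCC), nrow(red@L),
                    dimnames = list(rownames(cm@FCC), rownames(red@L)))
    Efull[rownames(E), colnames(E)] <- E
    expect_lt(max(abs(cm@FCC %*% Efull %*% as.matrix(red@L))), 1e-6)
  }
})

test_that("kinetic ensembles filter instances and keep exact summation", {
  fam <- toyFamily()
  ens <- toyEnsembles()[[1]]
  cnt <- ensembleCounts(ens)
  expect_equal(cnt$sampled, cnt$stable + cnt$unstable + cnt$singular)
  expect_equal(dim(ens@FCC)[3], cnt$stable)
  expect_gt(cnt$stable, 0)
  fccSums <- apply(ens@FCC, 3, function(M) max(abs(rowSums(M) - 1)))
  cccSums <- apply(ens@CCC, 3, function(M) max(abs(rowSums(M))))
  expect_lt(max(fccSums), 1e-6)
  expect_lt(max(cccSums), 1e-6)
  expect_equal(dim(meanFCC(ens)), dim(ens@FCC)[1:2])
})
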