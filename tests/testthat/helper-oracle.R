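## Independent oracle: explicit rate laws parameterised to match a
## (saturation, displacement) pair, a Newton steady-state solver, and
## central-difference control coefficients / elasticities.  Everything here
## is built from the rate-law definitions directly, not from the package's
## matrix formulas.

## Rate function factory.  For each reaction the rate is
##   v = e * k * prod_subs (x/K)^(h|n|) / prod_part (1 + (x/K)^h)^|n|
##         * (1 - Gamma(x))          [convenience / reversible Hill]
##   v = e * k * prod_subs x^|n| * (1 - Gamma(x))        [mass action]
## times inhibitor factors 1/(1+x/KI) and activator factors
## (x/KA)/(1+x/KA); Gamma(x) = exp((dG0 + RT sum n ln x)/RT), omitted for
## reactions without dG0.  K values are back-solved from the saturations at
## the reference state, and k is calibrated so v(x_ref, e = 1) = v_ref.
## Only nets whose reference fluxes are all positive are supported.
oracleRateFactory <- function(model, mech, sigma, state, RT = 2.4789,
                              excluded = character()) {
  rxn <- reactions(model)
  S <- as.matrix(stoichMatrix(model))
  xref <- rep(1, nrow(S)); names(xref) <- rownames(S)
  ln <- lnConc(state)
  xref[intersect(names(ln), rownames(S))] <-
    exp(ln[intersect(names(ln), rownames(S))])
  vref <- fluxes(state)
  stopifnot(all(vref > 0))
  pairs <- mech@pairs
  mm <- mech@mechanisms

  perRxn <- lapply(rxn$id, function(r) {
    coef <- S[, r]
    mec <- mm$mechanism[mm$reaction_id == r]
    pr <- pairs[pairs$reaction_id == r, , drop = FALSE]
    info <- list(mec = mec, dG0 = rxn$dG0[rxn$id == r], coef = coef)
    ks <- list()
    for (k in seq_len(nrow(pr))) {
      m <- pr$metabolite_id[k]
      s <- sigma[[paste0(r, "@", m)]]
      h <- pr$hill[k]
      K <- switch(pr$role[k],
        substrate = , product = xref[m] * (s / (1 - s))^(-1 / h),
        inhibitor = , activator = xref[m] * (1 - s) / s)
      ks[[k]] <- list(met = m, role = pr$role[k], n = pr$n[k], h = h, K = K)
    }
    info$terms <- ks
    info
  })
  names(perRxn) <- rxn$id

  rawRate <- function(r, x) {
    info <- perRxn[[r]]
    val <- 1
    for (t in info$terms) {
      xm <- x[[t$met]]
      val <- val * switch(t$role,
        substrate = if (info$mec == "mass_action") xm^t$n
                    else (xm / t$K)^(t$h * t$n) /
                         (1 + (xm / t$K)^t$h)^t$n,
        product = if (info$mec == "mass_action") 1
                  else 1 / (1 + (xm / t$K)^t$h)^t$n,
        inhibitor = 1 / (1 + xm / t$K),
        activator = (xm / t$K) / (1 + xm / t$K))
    }
    if (!is.na(info$dG0)) {
      mets <- names(info$coef)[info$coef != 0 & !(names(info$coef) %in%
                                                    excluded)]
      dg <- info$dG0 + RT * sum(info$coef[mets] * log(x[mets]))
      val <- val * (1 - exp(dg / RT))
    }
    val
  }
  kcal <- vapply(rxn$id, function(r) vref[[r]] / rawRate(r, xref),
                 numeric(1))
  list(
    rates = function(x, e) {
      v <- vapply(rxn$id, function(r) e[[r]] * kcal[[r]] * rawRate(r, x),
                  numeric(1))
      names(v) <- rxn$id
      v
    },
    xref = xref, vref = vref)
}

## Newton solve of N_R v(x) = 0 over the independent metabolites (log
## coordinates); dependent metabolites follow the conservation relations
## through the link matrix.
oracleSteadyState <- function(model, rateFun, e, x0, maxIter = 200,
                              tol = 1e-12) {
  red <- reduceSystem(model)
  NR <- as.matrix(red@NR)
  L <- as.matrix(red@L)
  ind <- red@independentIds
  dep <- red@dependentIds
  x0 <- x0[rownames(L)]
  fullX <- function(xi) {
    x <- x0
    x[ind] <- xi
    if (length(dep))
      x[dep] <- x0[dep] + as.numeric(L[dep, , drop = FALSE] %*%
                                       (xi - x0[ind]))
    x
  }
  resid <- function(xi) as.numeric(NR %*% rateFun(fullX(xi), e))
  xi <- x0[ind]
  for (it in seq_len(maxIter)) {
    f <- resid(xi)
    if (max(abs(f)) < tol * max(1, max(abs(rateFun(fullX(xi), e)))))
      break
    Jn <- matrix(0, length(f), length(xi))
    for (j in seq_along(xi)) {
      hstep <- 1e-7 * max(abs(xi[j]), 1e-9)
      xp <- xi; xp[j] <- xp[j] + hstep
      xm <- xi; xm[j] <- xm[j] - hstep
      Jn[, j] <- (resid(xp) - resid(xm)) / (2 * hstep)
    }
    step <- tryCatch(solve(Jn, f), error = function(e) qr.solve(Jn, f))
    lam <- 1
    repeat {
      xin <- xi - lam * step
      if (all(fullX(xin) > 0) &&
          (max(abs(resid(xin))) < max(abs(f)) || lam < 1e-4)) break
      lam <- lam / 2
    }
    xi <- xi - lam * step
  }
  fullX(xi)
}

## Central-difference flux control coefficients via the oracle rates.
oracleFCC <- function(model, rateFun, x0, rel = 0.01) {
  rxns <- reactionIds(model)
  e0 <- rep(1, length(rxns)); names(e0) <- rxns
  out <- matrix(NA_real_, length(rxns), length(rxns),
                dimnames = list(rxns, rxns))
  for (k in rxns) {
    ep <- e0; ep[k] <- 1 + rel
    em <- e0; em[k] <- 1 - rel
    xp <- oracleSteadyState(model, rateFun, ep, x0)
    xm <- oracleSteadyState(model, rateFun, em, x0)
    vp <- rateFun(xp, ep); vm <- rateFun(xm, em)
    out[, k] <- (log(vp) - log(vm)) / (log(1 + rel) - log(1 - rel))
  }
  out
}

## Central-difference scaled elasticities of the oracle rates at reference.
oracleElasticities <- function(model, rateFun, x0, rel = 1e-6) {
  rxns <- reactionIds(model)
  mets <- names(x0)
  e0 <- rep(1, length(rxns)); names(e0) <- rxns
  out <- matrix(0, length(rxns), length(mets),
                dimnames = list(rxns, mets))
  for (m in mets) {
    xp <- x0; xp[m] <- xp[m] * (1 + rel)
    xm <- x0; xm[m] <- xm[m] * (1 - rel)
    vp <- rateFun(xp, e0); vm <- rateFun(xm, e0)
    out[, m] <- (log(vp) - log(vm)) / (log(1 + rel) - log(1 - rel))
  }
  out
}

## A hand-sized model whose reference state is a simple all-forward flux,
## used by the MCA oracle tests: linear chain, branch point, moiety cycle.
oracleToy <- function(topology = c("chain", "branch", "moiety"),
                      seed = 1) {
  topology <- match.arg(topology)
  RT <- 2.4789
  lnx0 <- log(1e-3)
  tb <- switch(topology,
    chain = data.frame(
      rxn_id = c("IN", "S1", "S1", "S2", "S2", "OUT"),
      metabolite_id = c("X_c", "X_c", "Y_c", "Y_c", "Z_c", "Z_c"),
      coeff = c(1, -1, 1, -1, 1, -1),
      lb = 0, ub = 10, subsystem = "s",
      kind = c("exchange", rep("enzymatic", 4), "exchange"),
      dG0 = c(NA, -8, -8, -6, -6, NA), dG0_err = NA),
    branch = data.frame(
      rxn_id = c("IN", "B1", "B1", "B2", "B2", "OUTY", "OUTZ"),
      metabolite_id = c("X_c", "X_c", "Y_c", "X_c", "Z_c", "Y_c", "Z_c"),
      coeff = c(1, -1, 1, -1, 1, -1, -1),
      lb = 0, ub = 10, subsystem = "s",
      kind = c("exchange", rep("enzymatic", 4), "exchange", "exchange"),
      dG0 = c(NA, -8, -8, -10, -10, NA, NA), dG0_err = NA),
    moiety = data.frame(
      rxn_id = c("IN", "U1", "U1", "U1", "U1", "RG", "RG", "OUT"),
      metabolite_id = c("X_c", "X_c", "atp_c", "Y_c", "adp_c",
                        "adp_c", "atp_c", "Y_c"),
      coeff = c(1, -1, -1, 1, 1, -1, 1, -1),
      lb = 0, ub = 10, subsystem = "s",
      kind = c("exchange", rep("enzymatic", 6), "exchange"),
      dG0 = c(NA, -9, -9, -9, -9, -12, -12, NA), dG0_err = NA))
  ## dG0 here is the driving force at the nominal 1 mM state; shift to a
  ## standard-state value so that dG(x = 1 mM) equals that drive
  for (r in unique(tb$rxn_id)) {
    sel <- tb$rxn_id == r
    if (all(is.na(tb$dG0[sel]))) next
    tb$dG0[sel] <- tb$dG0[sel][1] - RT * sum(tb$coeff[sel]) * lnx0
  }
  model <- makeModel(paste0("oracle_", topology), tb)
  mets <- metaboliteIds(model)
  lnC <- rep(lnx0, length(mets)); names(lnC) <- mets
  ## reference flux: unit chain flux (branch splits 0.6 / 0.4)
  v <- switch(topology,
    chain = c(IN = 1, S1 = 1, S2 = 1, OUT = 1),
    branch = c(IN = 1, B1 = 0.6, B2 = 0.4, OUTY = 0.6, OUTZ = 0.4),
    moiety = c(IN = 1, U1 = 1, RG = 1, OUT = 1))
  problem <- buildTFAProblem(model)
  state <- makeSteadyState(problem, v, lnC,
                           provenance = list(oracle = topology))
  mech <- assignMechanisms(model)
  sigma <- sampleSaturations(mech, 1, seed = seed)@sigma[1, ]
  list(model = model, state = state, mech = mech, sigma = sigma)
}
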