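## Metabolic control analysis on elasticity-parameterised instances.
##
## With one enzyme per reaction and rates proportional to enzyme level,
## the scaled control coefficients follow from the reduced Jacobian
##   J = N_R diag(v) E diag(x)^-1 L
## as C^x = -diag(x)^-1 L J^-1 N_R diag(v) (concentrations, all
## metabolites) and C^v = I + E C^x (fluxes).  Steady state (N_R v = 0)
## makes FCC rows sum to 1 and CCC rows to 0 (summation theorems).

#' Split metabolites into independent and dependent sets (conserved moieties)
#'
#' Selects a maximal independent row set of `S` by pivoted QR and builds
#' the link matrix `L` with `S = L N_R` (rows reordered to the model's
#' metabolite order).  Near-integer entries of `L` are snapped, so rational
#' stoichiometries give exact link coefficients.
#'
#' @param model A [MetabolicModel-class].
#' @return A [ReducedSystem-class].
#' @export
reduceSystem <- function(model) {
  S <- as.matrix(model@S)
  mets <- rownames(S)
  qrS <- qr(t(S))            # columns of t(S) = metabolite rows of S
  rank <- qrS$rank
  indep <- sort(qrS$pivot[seq_len(rank)])
  dep <- setdiff(seq_len(nrow(S)), indep)
  NR <- S[indep, , drop = FALSE]
  L <- matrix(0, nrow(S), rank, dimnames = list(mets, mets[indep]))
  L[cbind(indep, seq_len(rank))] <- 1
  if (length(dep)) {
    ## dependent rows are linear combinations of the independent ones
    coefs <- t(qr.coef(qr(t(NR)), t(S[dep, , drop = FALSE])))
    coefs[is.na(coefs)] <- 0
    near <- abs(coefs - round(coefs)) < 1e-9
    coefs[near] <- round(coefs[near])
    coefs[abs(coefs) < 1e-12] <- 0
    L[dep, ] <- coefs
  }
  methods::new("ReducedSystem",
               NR = Matrix::Matrix(NR, sparse = TRUE),
               L = Matrix::Matrix(L, sparse = TRUE),
               independentIds = mets[indep], dependentIds = mets[dep])
}

## Concentrations (mol/L) in model metabolite order; species without a
## log-concentration variable (fixed activity) get 1 so they cancel.
.concVector <- function(reduced, state) {
  mets <- rownames(reduced@L)
  x <- rep(1, length(mets)); names(x) <- mets
  ln <- lnConc(state)
  hit <- intersect(mets, names(ln))
  x[hit] <- exp(ln[hit])
  if (any(x <= 0)) stop("non-positive concentration in steady state")
  x
}

#' Reduced Jacobian of the independent metabolite dynamics
#'
#' `J = N_R diag(v) E diag(x)^-1 L`, the Jacobian of
#' `dx_ind/dt = N_R v(x)` at the reference state.
#'
#' @param reduced A [ReducedSystem-class].
#' @param state A [SteadyState-class].
#' @param E Elasticity matrix (reactions x metabolites) from
#'   [elasticitiesFromSaturations()].
#' @return Dense square matrix (independent metabolites).
#' @export
jacobianReduced <- function(reduced, state, E) {
  mets <- rownames(reduced@L)
  rxns <- colnames(reduced@NR)
  x <- .concVector(reduced, state)
  v <- fluxes(state)[rxns]
  Efull <- matrix(0, length(rxns), length(mets),
                  dimnames = list(rxns, mets))
  hit <- intersect(colnames(E), mets)
  Efull[rownames(E), hit] <- E[, hit]
  as.matrix(reduced@NR %*% (v * Efull) %*% ((1 / x) * as.matrix(reduced@L)))
}

#' Local stability from Jacobian eigenvalues
#'
#' An instance is stable when no eigenvalue has positive real part
#' (boundary values within `tol` of zero count as stable).
#'
#' @param J Square numeric matrix.
#' @param tol Numerical slack on the real part (default 1e-9).
#' @return A [StabilityReport-class].
#' @export
checkStability <- function(J, tol = 1e-9) {
  if (!all(is.finite(J))) stop("Jacobian contains non-finite entries")
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  mr <- max(Re(ev))
  methods::new("StabilityReport", eigenvalues = ev, maxRealPart = mr,
               stable = mr <= tol, tol = tol)
}

#' Flux and concentration control coefficients
#'
#' @param reduced A [ReducedSystem-class].
#' @param state A [SteadyState-class] (must satisfy `S v = 0`).
#' @param E Elasticity matrix of the instance.
#' @param rcondTol Reciprocal-condition threshold below which the Jacobian
#'   is treated as singular (control coefficients undefined).
#' @return A [ControlMatrices-class]: `FCC` (fluxes x enzymes, rows sum to
#'   1) and `CCC` (independent metabolites x enzymes, rows sum to 0).
#' @export
controlCoefficients <- function(reduced, state, E, rcondTol = 1e-12) {
  mets <- rownames(reduced@L)
  rxns <- colnames(reduced@NR)
  x <- .concVector(reduced, state)
  v <- fluxes(state)[rxns]
  Efull <- matrix(0, length(rxns), length(mets),
                  dimnames = list(rxns, mets))
  hit <- intersect(colnames(E), mets)
  Efull[rownames(E), hit] <- E[, hit]
  J <- as.matrix(reduced@NR %*% (v * Efull) %*%
                   ((1 / x) * as.matrix(reduced@L)))
  if (nrow(J) > 0 && rcond(J) < rcondTol)
    stop("singular Jacobian: control coefficients undefined")
  NV <- as.matrix(reduced@NR) %*% diag(v, length(v))
  Jinv_NV <- if (nrow(J)) solve(J, NV) else
    matrix(0, 0, length(v))
  CxFull <- -(1 / x) * (as.matrix(reduced@L) %*% Jinv_NV)
  colnames(CxFull) <- rxns
  FCC <- diag(length(rxns)) + Efull %*% CxFull
  dimnames(FCC) <- list(rxns, rxns)
  CCC <- CxFull[reduced@independentIds, , drop = FALSE]
  methods::new("ControlMatrices", FCC = FCC, CCC = CCC)
}

#' Build a kinetic ensemble around a steady state
#'
#' Samples `n` saturation instances, converts each to elasticities, tests
#' local stability, and computes control coefficients for the stable,
#' non-singular instances.
#'
#' @param model A [MetabolicModel-class].
#' @param state A [SteadyState-class] for that model.
#' @param mech A [MechanismSet-class]; default [assignMechanisms()].
#' @param n Number of instances.
#' @param seed Integer seed.
#' @param saturations Optional pre-built [SaturationEnsemble-class]
#'   (e.g. from [stratifiedResample()]); only its retained rows are used
#'   and `n`/`seed` are ignored.
#' @param stabilityTol Eigenvalue slack for [checkStability()].
#' @return A [KineticEnsemble-class].
#' @export
kineticEnsemble <- function(model, state, mech = NULL, n = 1000, seed = 1L,
                            saturations = NULL, stabilityTol = 1e-9) {
  if (is.null(mech)) mech <- assignMechanisms(model)
  reduced <- reduceSystem(model)
  if (is.null(saturations))
    saturations <- sampleSaturations(mech, n, seed)
  keep <- which(saturations@info$retained)
  rxns <- model@reactions$id
  nI <- length(keep)
  stab <- data.frame(instance = keep, maxRealPart = NA_real_,
                     stable = FALSE, singular = FALSE)
  FCCs <- list(); CCCs <- list()
  for (ii in seq_len(nI)) {
    sig <- saturations@sigma[keep[ii], ]
    E <- elasticitiesFromSaturations(sig, mech, state)
    J <- jacobianReduced(reduced, state, E)
    rep <- checkStability(J, tol = stabilityTol)
    stab$maxRealPart[ii] <- rep@maxRealPart
    if (!rep@stable) next
    cm <- tryCatch(controlCoefficients(reduced, state, E),
                   error = function(e) NULL)
    if (is.null(cm)) { stab$singular[ii] <- TRUE; next }
    stab$stable[ii] <- TRUE
    FCCs[[length(FCCs) + 1L]] <- cm@FCC
    CCCs[[length(CCCs) + 1L]] <- cm@CCC
  }
  nS <- length(FCCs)
  dimF <- c(length(rxns), length(rxns), nS)
  FCC <- array(if (nS) unlist(FCCs) else numeric(0), dim = dimF,
               dimnames = list(rxns, rxns, NULL))
  CCC <- array(if (nS) unlist(CCCs) else numeric(0),
               dim = c(length(reduced@independentIds), length(rxns), nS),
               dimnames = list(reduced@independentIds, rxns, NULL))
  methods::new("KineticEnsemble", state = state, saturations = saturations,
               stability = stab, FCC = FCC, CCC = CCC,
               counts = list(sampled = nI, stable = nS,
                             unstable = sum(!stab$stable & !stab$singular),
                             singular = sum(stab$singular)))
}

#' Stability predicate for stratified resampling
#'
#' Builds the `stabilityCheck` callable used by [stratifiedResample()]:
#' a saturation row is accepted when its elasticities give a locally
#' stable Jacobian at the large model's steady state.
#'
#' @param model Large [MetabolicModel-class].
#' @param state Large-model [SteadyState-class].
#' @param mech Large-model [MechanismSet-class].
#' @param tol Eigenvalue slack.
#' @return `function(sigmaRow) -> logical`.
#' @export
makeStabilityCheck <- function(model, state, mech, tol = 1e-9) {
  reduced <- reduceSystem(model)
  function(sigma) {
    E <- elasticitiesFromSaturations(sigma, mech, state)
    J <- jacobianReduced(reduced, state, E)
    checkStability(J, tol = tol)@stable
  }
}
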