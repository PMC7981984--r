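## Kinetic parameterisation via enzyme saturation states.
##
## Instead of explicit rate constants, each kinetic model instance is the
## pair (steady state, elasticity matrix).  Scaled elasticities decompose
## into a mechanism-specific binding term plus a thermodynamic term driven
## by the displacement Gamma (from the factorisation v = v+ (1 - Gamma)):
##     E_ij = eps_binding_ij - n'_ij * Gamma_i / (1 - Gamma_i)
## with n' the stoichiometric coefficient in the net-forward orientation.
## The binding term per mechanism (sigma = binding-site occupancy):
##   convenience:      substrate |n| (1 - sigma), product -|n| sigma
##   reversible_hill:  substrate h |n| (1 - sigma), product -h |n| sigma
##   mass_action:      substrate |n|, product 0
##   modifiers:        inhibitor -sigma, activator +(1 - sigma)

MECHANISMS <- c("convenience", "reversible_hill", "mass_action")

#' Assign kinetic mechanisms to every reaction
#'
#' Defaults: convenience kinetics for reactions with unknown mechanism;
#' mass action for transport and exchange reactions.  Overrides win.
#'
#' @param model A [MetabolicModel-class].
#' @param overrides Optional `data.frame(reaction_id, mechanism, hill)`;
#'   `hill` (default 1) applies to the reaction's substrate/product pairs.
#' @param modifiers Optional `data.frame(reaction_id, metabolite_id, type)`
#'   with `type` in `"inhibitor"` / `"activator"`.
#' @param excluded Metabolite ids excluded from kinetics (fixed-activity
#'   species such as water and protons).
#' @return A [MechanismSet-class].
#' @export
assignMechanisms <- function(model, overrides = NULL, modifiers = NULL,
                             excluded = c("h2o_c", "h2o_e", "h_c", "h_e",
                                          "h2o_p", "h_p")) {
  rxn <- model@reactions
  mech <- ifelse(rxn$kind %in% c("transport", "exchange"),
                 "mass_action", "convenience")
  hill <- rep(1, nrow(rxn))
  if (!is.null(overrides)) {
    bad <- setdiff(overrides$reaction_id, rxn$id)
    if (length(bad)) stop("mechanism override for unknown reaction(s): ",
                          paste(bad, collapse = ", "))
    if (!all(overrides$mechanism %in% MECHANISMS))
      stop("unknown mechanism(s): ",
           paste(setdiff(overrides$mechanism, MECHANISMS), collapse = ", "))
    i <- match(overrides$reaction_id, rxn$id)
    mech[i] <- overrides$mechanism
    if (!is.null(overrides$hill)) {
      h <- overrides$hill; h[is.na(h)] <- 1
      hill[i] <- h
    }
  }
  S <- model@S
  rows <- list()
  for (j in seq_len(nrow(rxn))) {
    coef <- S[, j]
    idx <- which(coef != 0 & !(rownames(S) %in% excluded))
    if (!length(idx)) next
    rows[[length(rows) + 1L]] <- data.frame(
      reaction_id = rxn$id[j], metabolite_id = rownames(S)[idx],
      role = ifelse(coef[idx] < 0, "substrate", "product"),
      n = abs(coef[idx]), hill = hill[j], stringsAsFactors = FALSE)
  }
  if (!is.null(modifiers)) {
    bad <- setdiff(modifiers$reaction_id, rxn$id)
    if (length(bad)) stop("modifier for unknown reaction(s): ",
                          paste(bad, collapse = ", "))
    rows[[length(rows) + 1L]] <- data.frame(
      reaction_id = modifiers$reaction_id,
      metabolite_id = modifiers$metabolite_id,
      role = modifiers$type, n = 0,
      hill = 1, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  ## mass-action products contribute no binding saturation but keep the
  ## pair (their elasticity is purely thermodynamic)
  methods::new("MechanismSet",
               mechanisms = data.frame(reaction_id = rxn$id,
                                       mechanism = mech,
                                       stringsAsFactors = FALSE),
               pairs = pairs)
}

.pairKey <- function(rxn, met) paste0(rxn, "@", met)

#' Sample enzyme saturation states uniformly
#'
#' Each saturation is drawn independently and uniformly on
#' `(eps, 1 - eps)`; draws are reproducible per seed.  Known saturations
#' (e.g. from literature Km values via [saturationFromKm()]) can be fixed.
#'
#' @param mech A [MechanismSet-class].
#' @param n Number of instances.
#' @param seed Integer seed.
#' @param eps Open-interval margin (default 1e-6).
#' @param fixed Optional named numeric of fixed saturations, names as
#'   `"reaction@metabolite"`.
#' @return A [SaturationEnsemble-class] (instances x pairs).
#' @export
sampleSaturations <- function(mech, n, seed = 1L, eps = 1e-6, fixed = NULL) {
  stopifnot(n >= 1)
  pairs <- mech@pairs
  keys <- .pairKey(pairs$reaction_id, pairs$metabolite_id)
  restore <- .restoreSeed(); on.exit(restore())
  set.seed(seed)
  sig <- matrix(stats::runif(n * length(keys), eps, 1 - eps), nrow = n,
                dimnames = list(NULL, keys))
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), keys)
    if (length(bad)) stop("fixed saturation for unknown pair(s): ",
                          paste(bad, collapse = ", "))
    sig[, names(fixed)] <- rep(fixed, each = n)
  }
  methods::new("SaturationEnsemble", sigma = sig, pairs = pairs,
               seed = as.integer(seed),
               info = list(retained = rep(TRUE, n)))
}

#' Saturation implied by a Michaelis constant at a reference concentration
#'
#' @param x Concentration (mol/L).
#' @param K Michaelis constant (mol/L).
#' @return sigma = x / (K + x).
#' @export
saturationFromKm <- function(x, K) x / (K + x)

#' Scaled elasticity matrix from a saturation sample
#'
#' Orients every reaction along its net flux (for backward flux the
#' substrate/product roles swap and the displacement inverts), then applies
#' the mechanism binding terms and the thermodynamic term
#' `-n' Gamma/(1 - Gamma)`.  Reactions without thermodynamic data are
#' treated as irreversible (`Gamma = 0`, binding term only).
#'
#' @param sigma Named saturation vector (one ensemble row), names
#'   `"reaction@metabolite"`.
#' @param mech A [MechanismSet-class].
#' @param state A [SteadyState-class] providing flux signs and
#'   displacements.
#' @param tol Near-equilibrium guard: an active reaction with
#'   `|1 - Gamma|` below `tol` is an error.
#' @return Dense matrix (reactions x metabolites) of scaled elasticities
#'   `d ln v / d ln x`; exactly zero for non-participating metabolites.
#' @export
elasticitiesFromSaturations <- function(sigma, mech, state, tol = 1e-6) {
  mm <- mech@mechanisms
  pairs <- mech@pairs
  v <- fluxes(state)
  gam <- displacement(state)
  rxns <- mm$reaction_id
  mets <- unique(pairs$metabolite_id)
  E <- matrix(0, length(rxns), length(mets),
              dimnames = list(rxns, mets))
  keys <- .pairKey(pairs$reaction_id, pairs$metabolite_id)
  sig <- sigma[keys]
  for (k in seq_len(nrow(pairs))) {
    r <- pairs$reaction_id[k]; m <- pairs$metabolite_id[k]
    vr <- v[r]
    backward <- !is.na(vr) && vr < 0
    role <- pairs$role[k]
    if (backward && role %in% c("substrate", "product"))
      role <- if (role == "substrate") "product" else "substrate"
    g <- gam[r]
    gOr <- if (is.na(g)) 0 else if (backward) 1 / g else g
    if (gOr != 0 && abs(1 - gOr) < tol)
      stop("reaction ", r, " is too close to thermodynamic equilibrium ",
           "(Gamma = ", signif(gOr, 6), "); elasticities diverge")
    mec <- mm$mechanism[match(r, mm$reaction_id)]
    s <- sig[k]; nn <- pairs$n[k]; h <- pairs$hill[k]
    bind <- switch(role,
      substrate = switch(mec,
        convenience = nn * (1 - s),
        reversible_hill = h * nn * (1 - s),
        mass_action = nn),
      product = switch(mec,
        convenience = -nn * s,
        reversible_hill = -h * nn * s,
        mass_action = 0),
      inhibitor = -s,
      activator = (1 - s))
    thermo <- 0
    if (gOr != 0 && role %in% c("substrate", "product")) {
      nOr <- if (role == "substrate") -nn else nn
      thermo <- -nOr * gOr / (1 - gOr)
    }
    E[r, m] <- E[r, m] + bind + thermo
  }
  E
}

#' Stratified resampling of saturations into a larger nested model
#'
#' For every retained instance of the small-model ensemble, the saturation
#' values of shared enzyme-metabolite pairs are copied bit-exactly into the
#' large model; the expansion-specific pairs are resampled uniformly until
#' `stabilityCheck` accepts the instance or `maxTries` is exhausted.
#' Instances that never stabilise are flagged and excluded, preserving the
#' retained-fraction accounting.
#'
#' @param smallEnsemble A [SaturationEnsemble-class] of the small model.
#' @param mapping [NestedMapping-class] small -> large.
#' @param mechLarge [MechanismSet-class] of the large model.
#' @param seed Integer seed for the resampled coordinates.
#' @param stabilityCheck `function(sigmaRow) -> logical`; `NULL` accepts
#'   everything on the first try.
#' @param maxTries Resampling attempts per instance (default 50).
#' @param eps Open-interval margin for resampled saturations.
#' @return A [SaturationEnsemble-class] for the large model; `info$retained`
#'   flags instances stable in the large model, `info$tries` the attempts
#'   used, `info$sourceInstance` the originating small-model row.
#' @export
stratifiedResample <- function(smallEnsemble, mapping, mechLarge, seed = 1L,
                               stabilityCheck = NULL, maxTries = 50L,
                               eps = 1e-6) {
  pairsL <- mechLarge@pairs
  keysL <- .pairKey(pairsL$reaction_id, pairsL$metabolite_id)
  ## translate large-model pair keys into small-model keys where shared
  toSmallRxn <- stats::setNames(mapping@shared$id_small, mapping@shared$id_large)
  metShared <- stats::setNames(mapping@sharedMetabolites$id_small,
                               mapping@sharedMetabolites$id_large)
  keysSmallEquiv <- ifelse(
    pairsL$reaction_id %in% names(toSmallRxn) &
      pairsL$metabolite_id %in% names(metShared),
    .pairKey(toSmallRxn[pairsL$reaction_id], metShared[pairsL$metabolite_id]),
    NA_character_)
  sharedCol <- !is.na(keysSmallEquiv) &
    keysSmallEquiv %in% colnames(smallEnsemble@sigma)

  src <- which(smallEnsemble@info$retained)
  nInst <- length(src)
  sig <- matrix(NA_real_, nInst, length(keysL),
                dimnames = list(NULL, keysL))
  retained <- logical(nInst)
  tries <- integer(nInst)
  restore <- .restoreSeed(); on.exit(restore())
  set.seed(seed)
  freeCols <- which(!sharedCol)
  for (i in seq_len(nInst)) {
    row <- numeric(length(keysL))
    row[sharedCol] <- smallEnsemble@sigma[src[i], keysSmallEquiv[sharedCol]]
    ok <- FALSE
    t <- 0L
    repeat {
      t <- t + 1L
      if (length(freeCols))
        row[freeCols] <- stats::runif(length(freeCols), eps, 1 - eps)
      names(row) <- keysL
      ok <- if (is.null(stabilityCheck)) TRUE else isTRUE(stabilityCheck(row))
      if (ok || t >= maxTries || !length(freeCols)) break
    }
    sig[i, ] <- row
    retained[i] <- ok
    tries[i] <- t
  }
  methods::new("SaturationEnsemble", sigma = sig, pairs = pairsL,
               seed = as.integer(seed),
               info = list(retained = retained, tries = tries,
                           sourceInstance = src,
                           retainedFraction = mean(retained)))
}
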