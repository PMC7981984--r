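## Thermodynamics-based flux analysis (TFA).
##
## The MILP couples net fluxes to reaction Gibbs energies: a reaction may
## only carry forward flux if dG_r <= -RT*delta and backward flux if
## dG_r >= +RT*delta, where dG_r = dG0_r + RT * sum_j n_ij ln x_j.  The
## delta offset excludes thermodynamic equilibrium (|ln Gamma| >= delta), a
## requirement for the downstream kinetic ensembles whose elasticities
## diverge at Gamma = 1.

#' Thermodynamic parameter set
#'
#' @param RT Gas constant times temperature in kJ/mol; the default 2.4789
#'   corresponds to 310.15 K.
#' @param delta Minimum |ln Gamma| away from equilibrium (default 0.01).
#' @param concDefault Default log-concentration window in ln(mol/L);
#'   the default spans 1 nM to 100 mM.
#' @param bigMEnergy Fallback big-M for energy couplings, kJ/mol.
#' @param basalFlux Minimum |net flux| once a direction binary is set
#'   (default 1e-6 mmol/gDW/h, the basal-activity convention); rules out
#'   reactions that are nominally directed yet carry an exact zero flux.
#' @param fixedActivity Metabolite ids treated at fixed activity and
#'   excluded from concentration terms (water and protons by default).
#' @return A [ThermoParams-class].
#' @export
thermoParams <- function(RT = 2.4789, delta = 0.01,
                         concDefault = c(log(1e-9), log(0.1)),
                         bigMEnergy = 1000, basalFlux = 1e-6,
                         fixedActivity = c("h2o_c", "h2o_e", "h_c", "h_e",
                                           "h2o_p", "h_p")) {
  methods::new("ThermoParams", RT = RT, delta = delta,
               concDefault = concDefault, bigMEnergy = bigMEnergy,
               basalFlux = basalFlux, fixedActivity = fixedActivity)
}

#' Thermodynamic displacement
#'
#' Gamma = exp(dG_r / RT); Gamma = 1 at equilibrium and Gamma < 1 for a
#' thermodynamically favourable forward reaction.
#'
#' @param delta_g_r Reaction Gibbs energy, kJ/mol (vectorised).
#' @param RT kJ/mol, > 0.
#' @return Dimensionless displacement(s).
#' @export
computeGamma <- function(delta_g_r, RT = 2.4789) {
  stopifnot(RT > 0)
  exp(delta_g_r / RT)
}

#' Convert concentration bounds between log conventions
#'
#' Experimental tables often report metabolite levels as log10(mM); the TFA
#' variables are natural logs of mol/L.
#'
#' @param x Numeric values.
#' @param from `"log_mM"` (log10 of mM) or `"ln_M"`.
#' @return Values in ln(mol/L).
#' @export
logConcToLn <- function(x, from = c("log_mM", "ln_M")) {
  from <- match.arg(from)
  if (from == "ln_M") x else x * log(10) + log(1e-3)
}

## index of a variable in a TFAProblem variable table
.varIdx <- function(vars, type, id = NULL) {
  sel <- vars$type == type
  if (!is.null(id)) sel <- sel & vars$id %in% id
  which(sel)
}

#' Build the TFA MILP for a model
#'
#' Variables: `NF` (net flux, all reactions), `VF`/`VR` and binaries
#' `BF`/`BR` plus `DG` for every reaction with a standard Gibbs energy, and
#' `LNX` for every metabolite outside the fixed-activity set.  Constraints:
#' mass balance `S v = 0`; `NF = VF - VR`; `VF <= M BF`, `VR <= M BR`,
#' `BF + BR <= 1`; `DG = dG0 + RT sum n_ij LNX_j`; and the equilibrium
#' exclusion `DG <= -RT delta + M (1 - BF)`, `DG >= RT delta - M (1 - BR)`.
#'
#' @param model A [MetabolicModel-class].
#' @param params A [ThermoParams-class].
#' @param physiology Optional bounds table, `data.frame(type, id, lb, ub)`
#'   with `type` in `"flux"` / `"lnconc"`; log-concentration rows may carry
#'   a `units` column (`"ln_M"` default, `"log_mM"` accepted).
#' @param thermo Optional reaction ids to constrain thermodynamically;
#'   default: every reaction with a non-missing `dG0`.  Listing a reaction
#'   without `dG0` is a configuration error.
#' @return A [TFAProblem-class].
#' @export
buildTFAProblem <- function(model, params = thermoParams(),
                            physiology = NULL, thermo = NULL) {
  rxn <- model@reactions; met <- model@metabolites; S <- model@S
  if (is.null(thermo)) {
    thermo <- rxn$id[!is.na(rxn$dG0)]
  } else {
    noDG <- thermo[is.na(rxn$dG0[match(thermo, rxn$id)])]
    if (length(noDG))
      stop("reaction(s) flagged for thermodynamic treatment without dG0: ",
           paste(noDG, collapse = ", "))
  }
  concMet <- setdiff(met$id, params@fixedActivity)

  nfLB <- rxn$lb; nfUB <- rxn$ub
  lnLB <- rep(params@concDefault[1], length(concMet))
  lnUB <- rep(params@concDefault[2], length(concMet))
  names(lnLB) <- names(lnUB) <- concMet
  applied <- list()
  if (!is.null(physiology) && nrow(physiology)) {
    units <- if (!is.null(physiology$units)) physiology$units else "ln_M"
    units <- rep_len(units, nrow(physiology))
    for (k in seq_len(nrow(physiology))) {
      row <- physiology[k, ]
      if (row$type == "flux") {
        i <- match(row$id, rxn$id)
        if (is.na(i)) stop("physiology flux bound for unknown reaction ", row$id)
        nfLB[i] <- max(nfLB[i], row$lb); nfUB[i] <- min(nfUB[i], row$ub)
      } else if (row$type == "lnconc") {
        if (!row$id %in% concMet)
          stop("physiology concentration bound for unknown metabolite ", row$id)
        lb <- logConcToLn(row$lb, if (units[k] == "log_mM") "log_mM" else "ln_M")
        ub <- logConcToLn(row$ub, if (units[k] == "log_mM") "log_mM" else "ln_M")
        lnLB[row$id] <- max(lnLB[row$id], lb)
        lnUB[row$id] <- min(lnUB[row$id], ub)
      } else stop("unknown physiology bound type: ", row$type)
      applied[[length(applied) + 1L]] <- row
    }
    if (any(nfLB > nfUB) || any(lnLB > lnUB))
      stop("physiology bounds leave an empty box (lb > ub) for: ",
           paste(c(rxn$id[nfLB > nfUB], concMet[lnLB > lnUB]), collapse = ", "))
  }

  ti <- match(thermo, rxn$id)
  Mflux <- pmax(abs(nfLB), abs(nfUB), 1)[ti]
  lnAbsMax <- pmax(abs(lnLB), abs(lnUB))
  Menergy <- vapply(seq_along(thermo), function(k) {
    j <- ti[k]
    coef <- S[, j]; idx <- which(coef != 0 & rownames(S) %in% concMet)
    abs(rxn$dG0[j]) + params@RT * (sum(abs(coef[idx]) *
      lnAbsMax[match(rownames(S)[idx], concMet)]) + params@delta) + 1
  }, numeric(1))
  Menergy <- pmax(Menergy, params@RT * params@delta * 2)

  nR <- nrow(rxn); nT <- length(thermo); nC <- length(concMet)
  vblock <- function(type, id, lb, ub, integer) {
    data.frame(name = if (length(id)) paste0(type, ":", id) else character(0),
               type = rep(type, length(id)),
               id = id, lb = rep_len(lb, length(id)),
               ub = rep_len(ub, length(id)),
               integer = rep(integer, length(id)))
  }
  vars <- rbind(
    vblock("NF", rxn$id, nfLB, nfUB, FALSE),
    vblock("VF", thermo, 0, Mflux, FALSE),
    vblock("VR", thermo, 0, Mflux, FALSE),
    vblock("BF", thermo, 0, 1, TRUE),
    vblock("BR", thermo, 0, 1, TRUE),
    vblock("DG", thermo, -Menergy, Menergy, FALSE),
    vblock("LNX", concMet, lnLB, lnUB, FALSE))
  rownames(vars) <- NULL
  nV <- nrow(vars)
  iNF <- seq_len(nR)
  iVF <- nR + seq_len(nT); iVR <- nR + nT + seq_len(nT)
  iBF <- nR + 2L * nT + seq_len(nT); iBR <- nR + 3L * nT + seq_len(nT)
  iDG <- nR + 4L * nT + seq_len(nT); iLNX <- nR + 5L * nT + seq_len(nC)

  trip <- function(i, j, x) data.frame(i = i, j = j, x = x)
  ## equalities
  eq <- list(); beq <- numeric(); row0 <- 0L
  ST <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  eq[[1]] <- trip(ST@i + 1L, iNF[ST@j + 1L], ST@x)
  beq <- c(beq, numeric(nrow(S))); row0 <- nrow(S)
  if (nT) {
    eq[[2]] <- trip(rep(row0 + seq_len(nT), 3L),
                    c(iNF[ti], iVF, iVR), rep(c(1, -1, 1), each = nT))
    beq <- c(beq, numeric(nT)); row0 <- row0 + nT
    dgTrip <- list(trip(seq_len(nT) + row0, iDG, rep(1, nT)))
    for (k in seq_len(nT)) {
      j <- ti[k]; coef <- S[, j]
      idx <- which(coef != 0 & rownames(S) %in% concMet)
      if (length(idx))
        dgTrip[[k + 1L]] <- trip(rep(row0 + k, length(idx)),
                                 iLNX[match(rownames(S)[idx], concMet)],
                                 -params@RT * coef[idx])
    }
    eq[[3]] <- do.call(rbind, dgTrip)
    beq <- c(beq, rxn$dG0[ti]); row0 <- row0 + nT
  }
  eqT <- do.call(rbind, eq)
  A_eq <- Matrix::sparseMatrix(i = eqT$i, j = eqT$j, x = eqT$x,
                               dims = c(row0, nV))

  ## inequalities
  if (nT) {
    ub <- list(); bub <- numeric(); r <- 0L
    ub[[1]] <- trip(rep(r + seq_len(nT), 2L), c(iVF, iBF),
                    c(rep(1, nT), -Mflux))
    bub <- c(bub, numeric(nT)); r <- r + nT
    ub[[2]] <- trip(rep(r + seq_len(nT), 2L), c(iVR, iBR),
                    c(rep(1, nT), -Mflux))
    bub <- c(bub, numeric(nT)); r <- r + nT
    ub[[3]] <- trip(rep(r + seq_len(nT), 2L), c(iBF, iBR), rep(1, 2L * nT))
    bub <- c(bub, rep(1, nT)); r <- r + nT
    ub[[4]] <- trip(rep(r + seq_len(nT), 2L), c(iDG, iBF),
                    c(rep(1, nT), Menergy))
    bub <- c(bub, Menergy - params@RT * params@delta); r <- r + nT
    ub[[5]] <- trip(rep(r + seq_len(nT), 2L), c(iDG, iBR),
                    c(rep(-1, nT), Menergy))
    bub <- c(bub, Menergy - params@RT * params@delta); r <- r + nT
    ## assigned direction implies at least basal flux: VF >= basal * BF
    ub[[6]] <- trip(rep(r + seq_len(nT), 2L), c(iVF, iBF),
                    c(rep(-1, nT), rep(params@basalFlux, nT)))
    bub <- c(bub, numeric(nT)); r <- r + nT
    ub[[7]] <- trip(rep(r + seq_len(nT), 2L), c(iVR, iBR),
                    c(rep(-1, nT), rep(params@basalFlux, nT)))
    bub <- c(bub, numeric(nT)); r <- r + nT
    ubT <- do.call(rbind, ub)
    A_ub <- Matrix::sparseMatrix(i = ubT$i, j = ubT$j, x = ubT$x,
                                 dims = c(r, nV))
  } else {
    A_ub <- NULL; bub <- NULL
  }

  lp <- lpProblem(lb = vars$lb, ub = vars$ub,
                  A_eq = A_eq, b_eq = beq, A_ub = A_ub, b_ub = bub,
                  integrality = as.integer(vars$integer),
                  names = vars$name)
  methods::new("TFAProblem", model = model, params = params, vars = vars,
               lp = lp, thermoRxns = thermo,
               notes = list(physiology = applied))
}

#' Solve the TFA problem for one feasible point
#'
#' @param problem A [TFAProblem-class].
#' @param objective Optional named numeric over variable names (default:
#'   feasibility, zero objective).
#' @param sense `"min"` or `"max"`.
#' @return List with `status`, `x` (named), `objective`.  An infeasible
#'   problem raises an error listing the active bound set.
#' @export
solveTFA <- function(problem, objective = NULL, sense = "min") {
  c <- numeric(nrow(problem@vars))
  if (!is.null(objective)) {
    idx <- match(names(objective), problem@vars$name)
    if (anyNA(idx)) stop("unknown variable(s) in objective")
    c[idx] <- objective
  }
  res <- solveLP1(problem@lp, c, sense = sense)
  if (!isTRUE(res$success)) {
    if (res$status == 2)
      stop("TFA problem infeasible under the applied bounds; ",
           "applied physiology records: ",
           length(problem@notes$physiology))
    stop("TFA solver failure, status ", res$status)
  }
  res
}

#' Thermodynamic variability analysis
#'
#' Minimises and maximises each selected variable under the full TFA
#' constraint set (a pair of MILPs per variable, batched into one solver
#' call).
#'
#' @param problem A [TFAProblem-class].
#' @param variables Variable selection: `NULL` for all net fluxes, or a
#'   character vector of variable names (`"NF:<rxn>"`, `"LNX:<met>"`, ...).
#' @param tol Flux tolerance for bidirectionality classification.
#' @param options Solver options (e.g. `list(time_limit = 60)`); a
#'   per-variable timeout yields `NA` for that extremum, not a global
#'   failure.
#' @return A [TVAResult-class].
#' @export
runTVA <- function(problem, variables = NULL, tol = 1e-9, options = list()) {
  vars <- problem@vars
  if (is.null(variables)) {
    sel <- which(vars$type == "NF")
  } else {
    sel <- match(variables, vars$name)
    if (anyNA(sel)) stop("unknown variable(s): ",
                         paste(variables[is.na(sel)], collapse = ", "))
  }
  n <- nrow(vars)
  objs <- list()
  for (k in seq_along(sel)) {
    c <- numeric(n); c[sel[k]] <- 1
    objs[[2 * k - 1]] <- list(c = c, sense = "min")
    objs[[2 * k]] <- list(c = c, sense = "max")
  }
  res <- solveLP(problem@lp, objs, options = options)
  getv <- function(r) if (isTRUE(r$success)) r$objective else NA_real_
  mins <- vapply(res[seq_along(sel) * 2 - 1], getv, numeric(1))
  maxs <- vapply(res[seq_along(sel) * 2], getv, numeric(1))
  stMin <- vapply(res[seq_along(sel) * 2 - 1], function(r) r$status, numeric(1))
  if (any(stMin == 2))
    stop("TVA: problem infeasible")
  ranges <- data.frame(variable = vars$name[sel], type = vars$type[sel],
                       id = vars$id[sel], min = mins, max = maxs,
                       stringsAsFactors = FALSE)
  ## snap tiny solver residue onto an attained bound of zero
  ranges$min[abs(ranges$min) < 1e-11] <- 0
  ranges$max[abs(ranges$max) < 1e-11] <- 0
  methods::new("TVAResult", ranges = ranges, tol = tol)
}

#' Classify bidirectional reactions from TVA ranges
#'
#' A reaction is bidirectional when its feasible net-flux range extends
#' strictly both below `-tol` and above `+tol`.
#'
#' @param result A [TVAResult-class].
#' @param tol Flux tolerance (default `1e-9` mmol/gDW/h).
#' @return Character vector of bidirectional reaction ids.
#' @export
classifyBidirectional <- function(result, tol = 1e-9) {
  nf <- result@ranges[result@ranges$type == "NF", ]
  nf$id[!is.na(nf$min) & !is.na(nf$max) & nf$min < -tol & nf$max > tol]
}
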