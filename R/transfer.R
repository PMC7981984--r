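## Steady-state transfer between nested models.
##
## A reference steady state of the small model is imposed on the large
## model as +-relaxation bands around every shared variable.  A binary z
## per band deactivates its two constraints when set to 1:
##     x_i + (F_ub_i - UB_i) z_i <= F_ub_i
##     x_i + (F_lb_i - LB_i) z_i >= F_lb_i
## (z = 0 reduces to F_lb <= x <= F_ub, z = 1 to LB <= x <= UB), and the
## MILP minimises the number of active z.  Because all-z-equal-1 recovers
## the unbanded problem, the MILP is feasible whenever the large model is.

## Extend an lpProblem with band constraints + violation binaries.
.bandMILP <- function(lp, idx, ref, relaxation, floor) {
  n <- length(lp$lb)
  nz <- length(idx)
  UB <- lp$ub[idx]; LB <- lp$lb[idx]
  if (any(!is.finite(UB)) || any(!is.finite(LB)))
    stop("banded variable(s) with unbounded limits: ",
         paste(lp$names[idx[!is.finite(UB) | !is.finite(LB)]],
               collapse = ", "))
  half <- relaxation * pmax(abs(ref), floor)
  fub <- ref + half; flb <- ref - half
  zcol <- n + seq_len(nz)

  pad <- function(A) {
    if (is.null(A)) return(NULL)
    cbind(Matrix::Matrix(A, sparse = TRUE),
          Matrix::Matrix(0, nrow(A), nz, sparse = TRUE))
  }
  rows <- data.frame(
    i = rep(seq_len(2L * nz), each = 2L),
    j = c(rbind(idx, zcol, idx, zcol)),
    x = c(rbind(1, fub - UB, -1, -(flb - LB))))
  Aband <- Matrix::sparseMatrix(i = rows$i, j = rows$j, x = rows$x,
                                dims = c(2L * nz, n + nz))
  bband <- as.numeric(rbind(fub, -flb))

  A_ub <- rbind(pad(lp$A_ub), Aband)
  b_ub <- c(lp$b_ub, bband)
  lpz <- lpProblem(lb = c(lp$lb, rep(0, nz)), ub = c(lp$ub, rep(1, nz)),
                   A_eq = pad(lp$A_eq), b_eq = lp$b_eq,
                   A_ub = A_ub, b_ub = b_ub,
                   integrality = c(lp$integrality, rep(1L, nz)),
                   names = c(lp$names, paste0("Z:", lp$names[idx])))
  list(lp = lpz, zIdx = zcol, bands = data.frame(
    name = lp$names[idx], idx = idx, ref = ref, flb = flb, fub = fub,
    LB = LB, UB = UB, stringsAsFactors = FALSE))
}

#' Build the minimum-violation transfer MILP (flux phase)
#'
#' @param large [TFAProblem-class] of the large model.
#' @param mapping [NestedMapping-class] from the reference's model into the
#'   large model.
#' @param reference [SteadyState-class] of the small model.
#' @param relaxation Band half-width as a fraction of the reference value
#'   (default 0.01, i.e. a 1 percent relaxation).
#' @param floor Absolute floor (mmol/gDW/h) inside the half-width so that
#'   zero reference fluxes get a non-degenerate band (default 1e-6).
#' @param keepThermo Keep the full TFA constraint set during the MILP
#'   (default); `FALSE` retains only mass balance and flux bounds.
#' @return A [TransferProblem-class].
#' @export
buildTransferMILP <- function(large, mapping, reference, relaxation = 0.01,
                              floor = 1e-6, keepThermo = TRUE) {
  rxn <- large@model@reactions
  sh <- mapping@shared
  kindL <- rxn$kind[match(sh$id_large, rxn$id)]
  sh <- sh[kindL != "exchange", , drop = FALSE]   # intracellular only
  ref <- fluxes(reference)[sh$id_small]
  if (anyNA(ref)) stop("reference state misses shared reaction flux(es)")
  baseLp <- if (keepThermo) large@lp else {
    iNF <- .varIdx(large@vars, "NF")
    lpProblem(lb = large@vars$lb[iNF], ub = large@vars$ub[iNF],
              A_eq = large@model@S, b_eq = numeric(nrow(large@model@S)),
              names = large@vars$name[iNF])
  }
  idx <- match(paste0("NF:", sh$id_large), baseLp$names)
  bm <- .bandMILP(baseLp, idx, unname(ref), relaxation, floor)
  bands <- bm$bands
  bands$id <- sh$id_large
  bands$id_small <- sh$id_small
  methods::new("TransferProblem", lp = bm$lp,
               vars = data.frame(name = bm$lp$names,
                                 stringsAsFactors = FALSE),
               bands = bands, phase = "flux", relaxation = relaxation)
}

#' Minimise the number of violated bands
#'
#' @param problem A [TransferProblem-class].
#' @param floor Denominator floor for percent deviations.
#' @return A [TransferReport-class]: minimum violation count, violated
#'   ids, and per-band achieved values with percent deviation from the
#'   (small-model) reference.
#' @export
minimizeViolations <- function(problem, floor = 1e-6) {
  lp <- problem@lp
  n <- length(lp$lb)
  zIdx <- grep("^Z:", lp$names)
  cc <- numeric(n); cc[zIdx] <- 1
  res <- solveLP1(lp, cc)
  if (!isTRUE(res$success))
    stop("transfer MILP failed with solver status ", res$status)
  z <- round(res$x[zIdx])
  bands <- problem@bands
  achieved <- res$x[bands$idx]
  tab <- data.frame(id = bands$id, reference = bands$ref,
                    achieved = achieved,
                    percent_deviation = 100 * abs(achieved - bands$ref) /
                      pmax(abs(bands$ref), floor),
                    violated = z == 1,
                    stringsAsFactors = FALSE)
  methods::new("TransferReport", objective = sum(z),
               violated = bands$id[z == 1], table = tab,
               phase = problem@phase)
}

#' Enumerate all minimum-cardinality violation sets
#'
#' Exhaustively tests every subset of bands of the optimal size for
#' feasibility (intended for small models).
#'
#' @param problem A [TransferProblem-class].
#' @param objective Optimal violation count from [minimizeViolations()].
#' @param maxSubsets Safety cap on the number of subsets tested.
#' @return List of character vectors (ids of violated bands).
#' @export
enumerateViolationSets <- function(problem, objective, maxSubsets = 5000) {
  bands <- problem@bands
  nb <- nrow(bands)
  if (choose(nb, objective) > maxSubsets)
    stop("too many subsets to enumerate (", choose(nb, objective), ")")
  combos <- if (objective == 0) list(integer(0))
    else asplit(utils::combn(nb, objective), 2)
  lp <- problem@lp
  zIdx <- grep("^Z:", lp$names)
  objs <- lapply(combos, function(sel) {
    zfix <- rep(0, nb); zfix[sel] <- 1
    ov <- stats::setNames(zfix, zIdx)
    list(c = numeric(length(lp$lb)), sense = "min",
         lbOverride = ov, ubOverride = ov)
  })
  res <- solveLP(lp, objs)
  feas <- vapply(res, function(r) isTRUE(r$success), logical(1))
  lapply(which(feas), function(k) bands$id[combos[[k]]])
}

## Tighten NF (or LNX) bounds of a TFA problem to the kept bands.
.imposeBands <- function(problem, bands, keep) {
  vars <- problem@vars; lp <- problem@lp
  for (k in which(keep)) {
    i <- match(bands$name[k], vars$name)
    vars$lb[i] <- max(vars$lb[i], bands$flb[k])
    vars$ub[i] <- min(vars$ub[i], bands$fub[k])
    lp$lb[i] <- vars$lb[i]; lp$ub[i] <- vars$ub[i]
  }
  problem@vars <- vars; problem@lp <- lp
  problem
}

#' Transfer a reference steady state into a larger nested model
#'
#' Orchestrates the two-phase transfer: (flux phase) minimise band
#' violations, permanently impose the non-violated flux bands, sample the
#' resulting flux polytope and select a PCA representative; then
#' (concentration phase) repeat the band MILP on the log-concentrations of
#' shared metabolites given the selected flux profile, impose, sample, and
#' select.  Returns the large model's representative steady state plus the
#' two violation reports.
#'
#' @inheritParams buildTransferMILP
#' @param n Samples per phase (default 10000).
#' @param seed Integer seed.
#' @param varianceCoverage PCA retention fraction for representative
#'   selection.
#' @param warmup,thin Hit-and-run settings.
#' @return List with elements `state` ([SteadyState-class]),
#'   `fluxReport` and `concReport` ([TransferReport-class]).
#' @export
transferSteadyState <- function(large, mapping, reference, n = 10000,
                                seed = 1L, relaxation = 0.01, floor = 1e-6,
                                keepThermo = TRUE, varianceCoverage = 0.9,
                                warmup = 1000L, thin = 10L) {
  ## ---- flux phase
  tpF <- buildTransferMILP(large, mapping, reference, relaxation,
                           floor = floor, keepThermo = keepThermo)
  repF <- minimizeViolations(tpF, floor = floor)
  keep <- !tpF@bands$id %in% repF@violated
  probF <- .imposeBands(large, tpF@bands, keep)
  pattern <- fixDirectionalities(probF)
  poolF <- sampleFluxSpace(probF, n = n, seed = seed, pattern = pattern,
                           warmup = warmup, thin = thin)
  selF <- selectRepresentative(poolF, varianceCoverage)
  vLarge <- selF$values

  ## ---- concentration phase
  signs <- ifelse(vLarge[probF@thermoRxns] > 1e-9, 1L,
                  ifelse(vLarge[probF@thermoRxns] < -1e-9, -1L, 0L))
  poly <- .concPolytope(probF, signs)
  lpC <- lpProblem(lb = poly$lb, ub = poly$ub, A_ub = poly$A_ub,
                   b_ub = poly$b_ub, names = paste0("LNX:", poly$ids))
  shMet <- mapping@sharedMetabolites
  shMet <- shMet[shMet$id_large %in% poly$ids &
                 shMet$id_small %in% names(lnConc(reference)), , drop = FALSE]
  refC <- lnConc(reference)[shMet$id_small]
  idxC <- match(paste0("LNX:", shMet$id_large), lpC$names)
  bmC <- .bandMILP(lpC, idxC, unname(refC), relaxation, floor)
  bandsC <- bmC$bands; bandsC$id <- shMet$id_large
  tpC <- methods::new("TransferProblem", lp = bmC$lp,
                      vars = data.frame(name = bmC$lp$names,
                                        stringsAsFactors = FALSE),
                      bands = bandsC, phase = "concentration",
                      relaxation = relaxation)
  repC <- minimizeViolations(tpC, floor = floor)
  keepC <- !tpC@bands$id %in% repC@violated
  probC <- .imposeBands(probF, tpC@bands, keepC)
  poolC <- sampleConcentrationSpace(probC, vLarge, n = n, seed = seed + 1L,
                                    warmup = warmup, thin = thin)
  selC <- selectRepresentative(poolC, varianceCoverage)

  state <- makeSteadyState(probF, vLarge, selC$values,
                           provenance = list(seed = seed,
                                             method = "transfer+pca",
                                             fluxIndex = selF$index,
                                             concIndex = selC$index,
                                             from = reference@model))
  list(state = state, fluxReport = repF, concReport = repC)
}

#' Write a transfer report as TSV
#'
#' @param report A [TransferReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTransferReport <- function(report, path) {
  utils::write.table(report@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
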