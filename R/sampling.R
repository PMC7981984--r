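## Uniform sampling of the feasible flux and log-concentration polytopes.
##
## TFA feasible sets are convex only once the direction binaries are fixed,
## so a feasibility solve pins the directionality pattern first; the flux
## and concentration polytopes then decouple (they interact only through
## the binaries) and each is sampled with an artificial-centering
## hit-and-run walk in null-space coordinates.

.restoreSeed <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    function() assign(".Random.seed", old, envir = .GlobalEnv)
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  }
}

#' Fix the TFA directionality pattern from a feasibility solve
#'
#' Solves the TFA MILP maximising the number of assigned direction
#' binaries, so that every reaction that *can* carry flux gets a
#' direction: downstream kinetic models require nonzero net fluxes, and an
#' arbitrary feasibility solve may needlessly switch reactions off.
#'
#' @param problem A [TFAProblem-class].
#' @return Named integer vector over thermodynamically constrained
#'   reactions: `+1` forward, `-1` backward, `0` off.
#' @export
fixDirectionalities <- function(problem) {
  obj <- numeric(nrow(problem@vars))
  obj[.varIdx(problem@vars, "BF")] <- 1
  obj[.varIdx(problem@vars, "BR")] <- 1
  res <- solveLP1(problem@lp, obj, sense = "max")
  if (!isTRUE(res$success))
    stop("TFA problem infeasible under the applied bounds")
  vars <- problem@vars
  bf <- res$x[.varIdx(vars, "BF")]
  br <- res$x[.varIdx(vars, "BR")]
  pat <- ifelse(round(bf) == 1, 1L, ifelse(round(br) == 1, -1L, 0L))
  stats::setNames(as.integer(pat), problem@thermoRxns)
}

## Flux polytope after fixing binaries: box on NF + S NF = 0.
.fluxPolytope <- function(problem, pattern) {
  vars <- problem@vars
  rxn <- problem@model@reactions
  lb <- rxn$lb; ub <- rxn$ub
  ti <- match(problem@thermoRxns, rxn$id)
  iNF <- .varIdx(vars, "NF")
  lb <- vars$lb[iNF]; ub <- vars$ub[iNF]
  basal <- problem@params@basalFlux
  for (k in seq_along(ti)) {
    i <- ti[k]
    if (pattern[k] > 0) lb[i] <- max(lb[i], basal)
    else if (pattern[k] < 0) ub[i] <- min(ub[i], -basal)
    else { lb[i] <- 0; ub[i] <- 0 }
  }
  list(A_eq = problem@model@S, b_eq = numeric(nrow(problem@model@S)),
       A_ub = NULL, b_ub = NULL, lb = lb, ub = ub,
       ids = rxn$id)
}

## Concentration polytope for a fixed flux sign pattern: box on LNX plus,
## for every active thermo reaction, sum_j n_ij lnx_j on the favourable
## side of (-dG0/RT -+ delta).
.concPolytope <- function(problem, signs) {
  vars <- problem@vars
  S <- problem@model@S
  rxn <- problem@model@reactions
  iLNX <- .varIdx(vars, "LNX")
  concMet <- vars$id[iLNX]
  rows <- list(); rhs <- numeric(); r <- 0L
  for (k in seq_along(problem@thermoRxns)) {
    s <- signs[k]
    if (s == 0) next
    j <- match(problem@thermoRxns[k], rxn$id)
    coef <- S[, j]
    idx <- which(coef != 0 & rownames(S) %in% concMet)
    r <- r + 1L
    rows[[r]] <- data.frame(i = r, j = match(rownames(S)[idx], concMet),
                            x = s * coef[idx])
    rhs <- c(rhs, -s * rxn$dG0[j] / problem@params@RT - problem@params@delta)
  }
  A_ub <- if (r) {
    T <- do.call(rbind, rows)
    Matrix::sparseMatrix(i = T$i, j = T$j, x = T$x,
                         dims = c(r, length(concMet)))
  } else NULL
  list(A_eq = NULL, b_eq = NULL, A_ub = A_ub, b_ub = rhs,
       lb = vars$lb[iLNX], ub = vars$ub[iLNX], ids = concMet)
}

## Artificial-centering hit-and-run over
## {x : A_eq x = b_eq, A_ub x <= b_ub, lb <= x <= ub}.
.achr <- function(poly, n, seed, warmup = 1000L, thin = 10L) {
  nv <- length(poly$lb)
  ## variables pinned by a zero-width box become equalities, so that the
  ## walk directions live entirely in the free subspace
  pinned <- which(poly$ub - poly$lb < 1e-12)
  if (length(pinned)) {
    Epin <- matrix(0, length(pinned), nv)
    Epin[cbind(seq_along(pinned), pinned)] <- 1
    poly$A_eq <- rbind(if (!is.null(poly$A_eq)) as.matrix(poly$A_eq), Epin)
    poly$b_eq <- c(poly$b_eq, poly$lb[pinned])
  }
  free <- setdiff(seq_len(nv), pinned)
  ## inequality system G x <= h including the (free) box
  G <- rbind(if (!is.null(poly$A_ub)) as.matrix(poly$A_ub),
             diag(nv)[free, , drop = FALSE],
             -diag(nv)[free, , drop = FALSE])
  h <- c(poly$b_ub, poly$ub[free], -poly$lb[free])
  if (any(!is.finite(h)))
    stop("unbounded direction detected: close all variable bounds ",
         "before sampling")

  ## feasible point via LP, then exact projection onto the equalities
  lpp <- lpProblem(lb = poly$lb, ub = poly$ub, A_eq = poly$A_eq,
                   b_eq = poly$b_eq, A_ub = poly$A_ub, b_ub = poly$b_ub)
  res <- solveLP1(lpp, numeric(nv))
  if (!isTRUE(res$success))
    stop("polytope is empty: no feasible point under the fixed pattern")
  x0 <- res$x

  if (!is.null(poly$A_eq)) {
    Aeq <- as.matrix(poly$A_eq)
    sv <- svd(Aeq, nu = nrow(Aeq), nv = nv)
    tolr <- max(dim(Aeq)) * max(sv$d, 0) * .Machine$double.eps
    rank <- sum(sv$d > tolr)
    N <- sv$v[, setdiff(seq_len(nv), seq_len(rank)), drop = FALSE]
    ## exact projection of x0 onto the affine set
    resid <- as.numeric(Aeq %*% x0 - poly$b_eq)
    if (rank > 0) {
      corr <- sv$v[, seq_len(rank), drop = FALSE] %*%
        ((t(sv$u[, seq_len(rank), drop = FALSE]) %*% resid) /
           sv$d[seq_len(rank)])
      x0 <- x0 - as.numeric(corr)
    }
  } else {
    N <- diag(nv)
  }
  d <- ncol(N)
  if (d == 0L) {
    out <- matrix(rep(x0, each = n), nrow = n)
    colnames(out) <- poly$ids
    return(out)
  }

  Gy <- G %*% N               # inequalities in null-space coordinates
  hy <- h - as.numeric(G %*% x0)

  ## interior (Chebyshev-like) starting point in y-space; rows orthogonal
  ## to the null space must already hold at x0
  rn <- sqrt(rowSums(Gy^2))
  act <- rn > 1e-12
  if (any(hy[!act] < -1e-6))
    stop("feasible point violates inequalities after projection")
  lpc <- lpProblem(lb = c(rep(-Inf, d), 0), ub = c(rep(Inf, d), Inf),
                   A_ub = cbind(Gy[act, , drop = FALSE], rn[act]),
                   b_ub = hy[act])
  cc <- c(numeric(d), -1)
  resc <- solveLP1(lpc, cc)
  y <- if (isTRUE(resc$success)) resc$x[seq_len(d)] else numeric(d)

  restore <- .restoreSeed(); on.exit(restore())
  set.seed(seed)
  keepEvery <- max(1L, as.integer(thin))
  total <- warmup + n * keepEvery
  Gt <- Gy[act, , drop = FALSE]; ht <- hy[act]
  slack <- pmax(ht - as.numeric(Gt %*% y), 0)
  out <- matrix(NA_real_, n, nv)
  centre <- y
  stored <- matrix(NA_real_, 0, d)
  kept <- 0L
  for (it in seq_len(total)) {
    if (nrow(stored) >= 10L) {
      ref <- stored[sample.int(nrow(stored), 1L), ]
      dir <- ref - centre
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-12) { dir <- stats::rnorm(d); nd <- sqrt(sum(dir^2)) }
    } else {
      dir <- stats::rnorm(d); nd <- sqrt(sum(dir^2))
    }
    dir <- dir / nd
    gd <- as.numeric(Gt %*% dir)
    tmax <- suppressWarnings(min((slack / gd)[gd > 1e-12]))
    tmin <- suppressWarnings(max((slack / gd)[gd < -1e-12]))
    if (!is.finite(tmax) || !is.finite(tmin))
      stop("unbounded direction detected during hit-and-run")
    if (tmax < tmin) next
    step <- stats::runif(1, tmin, tmax)
    y <- y + step * dir
    slack <- slack - step * gd
    centre <- centre + (y - centre) / (it + 1)
    if (it %% 23L == 0L || nrow(stored) < 10L)
      stored <- rbind(stored, y)[seq_len(min(nrow(stored) + 1L, 200L)), ,
                                 drop = FALSE]
    if (it > warmup && (it - warmup) %% keepEvery == 0L) {
      kept <- kept + 1L
      out[kept, ] <- x0 + as.numeric(N %*% y)
      if (kept == n) break
    }
  }
  colnames(out) <- poly$ids
  out[seq_len(kept), , drop = FALSE]
}

#' Sample the feasible net-flux polytope
#'
#' @param problem A [TFAProblem-class].
#' @param n Number of samples (default 10000).
#' @param seed Integer seed; identical inputs give a bit-identical pool.
#' @param pattern Directionality pattern from [fixDirectionalities()];
#'   computed from a feasibility solve when `NULL`.
#' @param warmup,thin Hit-and-run warm-up steps and thinning.
#' @return A [SamplePool-class] over net fluxes (columns = reaction ids).
#' @export
sampleFluxSpace <- function(problem, n = 10000, seed = 1L, pattern = NULL,
                            warmup = 1000L, thin = 10L) {
  stopifnot(n >= 1)
  if (is.null(pattern)) pattern <- fixDirectionalities(problem)
  poly <- .fluxPolytope(problem, pattern)
  sm <- .achr(poly, n, seed, warmup = warmup, thin = thin)
  methods::new("SamplePool", samples = sm, seed = as.integer(seed),
               sampler = "achr", settings = list(warmup = warmup,
                                                 thin = thin,
                                                 pattern = pattern,
                                                 space = "flux"))
}

#' Sample the log-concentration polytope for a fixed flux profile
#'
#' The flux profile's signs determine on which side of equilibrium every
#' active reaction's Gibbs energy must lie; the resulting polytope over
#' ln-concentrations is sampled uniformly.
#'
#' @param problem A [TFAProblem-class].
#' @param fixedFlux Named net-flux vector (or a [SteadyState-class]).
#' @param n,seed,warmup,thin As in [sampleFluxSpace()].
#' @param tol Fluxes with `|NF| <= tol` are treated as inactive.
#' @return A [SamplePool-class] over ln(mol/L) concentrations.
#' @export
sampleConcentrationSpace <- function(problem, fixedFlux, n = 10000,
                                     seed = 1L, warmup = 1000L, thin = 10L,
                                     tol = 1e-9) {
  if (methods::is(fixedFlux, "SteadyState")) fixedFlux <- fluxes(fixedFlux)
  v <- fixedFlux[problem@thermoRxns]
  if (anyNA(v)) stop("fixed flux profile misses thermodynamic reaction(s)")
  signs <- ifelse(v > tol, 1L, ifelse(v < -tol, -1L, 0L))
  poly <- .concPolytope(problem, signs)
  sm <- tryCatch(.achr(poly, n, seed, warmup = warmup, thin = thin),
                 error = function(e) {
                   if (grepl("empty", conditionMessage(e)))
                     stop("fixed flux profile is thermodynamically ",
                          "infeasible: no concentration vector supports ",
                          "its directionalities", call. = FALSE)
                   stop(e)
                 })
  methods::new("SamplePool", samples = sm, seed = as.integer(seed),
               sampler = "achr", settings = list(warmup = warmup,
                                                 thin = thin,
                                                 signs = signs,
                                                 space = "concentration"))
}

#' Select a representative sample by PCA
#'
#' Columns are standardised (constant columns dropped), principal
#' components are retained until the cumulative explained variance reaches
#' `varianceCoverage`, and the pool member closest (Euclidean, in the
#' retained component space) to the projected pool mean is returned.  Ties
#' break to the lowest sample index.  The output is always an actual pool
#' member, never a synthetic average.
#'
#' @param pool A [SamplePool-class] with at least two samples.
#' @param varianceCoverage Fraction of variance to cover (default 0.9).
#' @return List with `index`, `values` (the selected sample),
#'   `nComponents`, and `coverage` actually reached.
#' @export
selectRepresentative <- function(pool, varianceCoverage = 0.9) {
  X <- pool@samples
  if (nrow(X) < 2) stop("need at least 2 samples to select a representative")
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 1e-12)
  if (!length(keep)) {
    return(list(index = 1L, values = X[1L, ], nComponents = 0L,
                coverage = 1))
  }
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= varianceCoverage)[1]
  if (is.na(k)) k <- length(cum)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ## the projected pool mean is the origin of the score space
  d2 <- rowSums(scores^2)
  idx <- which.min(d2)   # which.min returns the first (lowest index) tie
  list(index = idx, values = X[idx, ], nComponents = k, coverage = cum[k])
}

#' Assemble a SteadyState from flux and concentration vectors
#'
#' Computes the per-reaction displacement Gamma from the model's standard
#' Gibbs energies and the concentration vector, and validates mass balance.
#'
#' @param problem A [TFAProblem-class].
#' @param fluxes Named net-flux vector covering all reactions.
#' @param lnConc Named ln(mol/L) vector covering the concentration
#'   variables.
#' @param provenance List recorded in the state.
#' @return A [SteadyState-class].
#' @export
makeSteadyState <- function(problem, fluxes, lnConc, provenance = list()) {
  model <- problem@model
  fluxes <- fluxes[model@reactions$id]
  resid <- max(abs(as.numeric(model@S %*% fluxes)))
  if (resid > 1e-9 * max(1, max(abs(fluxes))))
    stop("flux vector violates mass balance: ||S v||_inf = ", resid)
  gamma <- rep(NA_real_, nrow(model@reactions))
  names(gamma) <- model@reactions$id
  for (id in problem@thermoRxns) {
    j <- match(id, model@reactions$id)
    coef <- model@S[, j]
    idx <- which(coef != 0 & rownames(model@S) %in% names(lnConc))
    dg <- model@reactions$dG0[j] +
      problem@params@RT * sum(coef[idx] * lnConc[rownames(model@S)[idx]])
    gamma[id] <- computeGamma(dg, problem@params@RT)
  }
  methods::new("SteadyState", fluxes = fluxes, lnConc = lnConc,
               gamma = gamma, model = model@name, provenance = provenance)
}
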