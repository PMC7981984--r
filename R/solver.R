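## Linear and mixed-integer programming layer.
##
## All optimisation in the package (TFA feasibility, TVA, transfer MILPs) goes
## through a single batched interface: a problem is a fixed constraint set
## over which any number of objectives are optimised in one solver call.
## Problems are handed to the HiGHS solver (through scipy.optimize.milp) in a
## short-lived subprocess; HiGHS is deterministic, so identical problems give
## identical solutions.

#' Construct an LP/MILP problem container
#'
#' A lightweight description of the feasible set
#' \eqn{\{x : A_{eq} x = b_{eq},\ A_{ub} x \le b_{ub},\ lb \le x \le ub\}},
#' with an optional 0/1 integrality marker per variable.
#'
#' @param lb,ub Numeric vectors of variable bounds (equal length).
#' @param A_eq,b_eq Equality constraints (matrix may be dense or `Matrix`
#'   sparse; `NULL` for none).
#' @param A_ub,b_ub Inequality constraints `A_ub x <= b_ub` (`NULL` for none).
#' @param integrality Integer vector (0 continuous, 1 integer), recycled.
#' @param names Optional variable names.
#' @return A list of class `lpProblem`.
#' @export
lpProblem <- function(lb, ub, A_eq = NULL, b_eq = NULL,
                      A_ub = NULL, b_ub = NULL, integrality = 0L,
                      names = NULL) {
  stopifnot(length(lb) == length(ub))
  n <- length(lb)
  integrality <- rep_len(as.integer(integrality), n)
  if (!is.null(A_eq)) stopifnot(ncol(A_eq) == n, nrow(A_eq) == length(b_eq))
  if (!is.null(A_ub)) stopifnot(ncol(A_ub) == n, nrow(A_ub) == length(b_ub))
  structure(list(lb = as.numeric(lb), ub = as.numeric(ub),
                 A_eq = A_eq, b_eq = as.numeric(b_eq),
                 A_ub = A_ub, b_ub = as.numeric(b_ub),
                 integrality = integrality, names = names),
            class = "lpProblem")
}

.tripletJSON <- function(A) {
  if (is.null(A)) return(NULL)
  T <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   "TsparseMatrix")
  list(i = T@i + 1L, j = T@j + 1L, x = T@x, nrow = nrow(A))
}

.denseToSparseObj <- function(c, sense) {
  idx <- which(c != 0)
  list(i = as.list(idx), x = as.list(unname(c[idx])), sense = sense)
}

#' Solve a batch of LPs/MILPs over a shared constraint set
#'
#' @param problem An [lpProblem()].
#' @param objectives A list; each element is `list(c = <numeric vector>,
#'   sense = "min"|"max")`, optionally with named numeric vectors
#'   `lbOverride` / `ubOverride` (index -> value) replacing individual
#'   variable bounds for that solve only.  A zero vector asks for a
#'   feasibility point.
#' @param options Named list passed to the solver (e.g. `time_limit`).
#' @return A list of results, one per objective, each with `status`
#'   (0 = optimal, 2 = infeasible, 3 = unbounded), `success`, `objective`,
#'   and the primal point `x` (named if the problem has names).
#' @export
solveLP <- function(problem, objectives, options = list()) {
  stopifnot(inherits(problem, "lpProblem"), length(objectives) >= 1)
  n <- length(problem$lb)
  payload <- list(
    ncol = n,
    lb = problem$lb, ub = problem$ub,
    integrality = problem$integrality,
    A_eq = .tripletJSON(problem$A_eq), b_eq = problem$b_eq,
    A_ub = .tripletJSON(problem$A_ub), b_ub = problem$b_ub,
    options = options,
    objectives = lapply(objectives, function(o) {
      stopifnot(length(o$c) == n)
      obj <- .denseToSparseObj(o$c, if (is.null(o$sense)) "min" else o$sense)
      if (!is.null(o$lbOverride)) {
        obj$lb_i <- as.list(as.integer(names(o$lbOverride)))
        obj$lb_x <- as.list(unname(o$lbOverride))
      }
      if (!is.null(o$ubOverride)) {
        obj$ub_i <- as.list(as.integer(names(o$ubOverride)))
        obj$ub_x <- as.list(unname(o$ubOverride))
      }
      obj
    })
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp_solve.py", package = "nestMCA",
                        mustWork = TRUE)
  py <- getOption("nestMCA.python", "python")
  status <- system2(py, c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("LP solver subprocess failed:\n", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(res$results, function(r) {
    if (!is.null(r$x) && !is.null(problem$names)) names(r$x) <- problem$names
    r
  })
}

## Single-objective convenience wrapper.
solveLP1 <- function(problem, c, sense = "min", options = list()) {
  solveLP(problem, list(list(c = c, sense = sense)), options = options)[[1L]]
}
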