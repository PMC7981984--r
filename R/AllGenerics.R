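## Generics, accessors and show methods.

#' Accessors for MetabolicModel and derived objects
#'
#' `reactions()` and `metabolites()` return the annotation tables,
#' `stoichMatrix()` the sparse stoichiometric matrix, `modelName()` the model
#' name, `reactionIds()`/`metaboliteIds()` the id vectors.
#'
#' @param object A [MetabolicModel-class] (or an object wrapping one).
#' @return The corresponding slot content.
#' @name model-accessors
#' @aliases reactions metabolites stoichMatrix modelName reactionIds
#'   metaboliteIds
NULL

#' @rdname model-accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname model-accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname model-accessors
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))
#' @rdname model-accessors
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))
#' @rdname model-accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname model-accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

setMethod("reactions", "MetabolicModel", function(object) object@reactions)
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)
setMethod("stoichMatrix", "MetabolicModel", function(object) object@S)
setMethod("modelName", "MetabolicModel", function(object) object@name)
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)

setMethod("reactions", "TFAProblem", function(object) object@model@reactions)
setMethod("modelName", "TFAProblem", function(object) object@model@name)

#' Flux / log-concentration accessors for steady states
#'
#' @param object A [SteadyState-class].
#' @return Named numeric vector.
#' @name steadystate-accessors
#' @aliases fluxes lnConc displacement
NULL

#' @rdname steadystate-accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname steadystate-accessors
#' @export
setGeneric("lnConc", function(object) standardGeneric("lnConc"))
#' @rdname steadystate-accessors
#' @export
setGeneric("displacement", function(object) standardGeneric("displacement"))

setMethod("fluxes", "SteadyState", function(object) object@fluxes)
setMethod("lnConc", "SteadyState", function(object) object@lnConc)
setMethod("displacement", "SteadyState", function(object) object@gamma)

#' Sample matrix of a pool
#' @param object A [SamplePool-class].
#' @return Numeric matrix, one sample per row.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
setMethod("samples", "SamplePool", function(object) object@samples)

#' Population-mean flux control coefficients of an ensemble
#' @param object A [KineticEnsemble-class].
#' @return Matrix (fluxes x enzymes) of FCC means over stable instances.
#' @export
setGeneric("meanFCC", function(object) standardGeneric("meanFCC"))
setMethod("meanFCC", "KineticEnsemble", function(object) {
  if (dim(object@FCC)[3] == 0L) stop("ensemble has no stable instances")
  apply(object@FCC, c(1, 2), mean)
})

#' Stable-instance count accessors
#' @param object A [KineticEnsemble-class].
#' @return Named list with sampled/stable/unstable/singular counts.
#' @export
setGeneric("ensembleCounts", function(object) standardGeneric("ensembleCounts"))
setMethod("ensembleCounts", "KineticEnsemble", function(object) object@counts)

## ---- show methods -------------------------------------------------------

setMethod("show", "MetabolicModel", function(object) {
  r <- object@reactions
  cat(sprintf("MetabolicModel '%s': %d metabolites x %d reactions\n",
              object@name, nrow(object@metabolites), nrow(r)))
  tab <- table(factor(r$kind, levels = REACTION_KINDS))
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  reactions with dG0: %d\n", sum(!is.na(r$dG0))))
})

setMethod("show", "NestedMapping", function(object) {
  cat(sprintf("NestedMapping %s -> %s: %d shared, %d added reactions; %d added metabolites\n",
              object@smallName, object@largeName, nrow(object@shared),
              length(object@addedReactions), length(object@addedMetabolites)))
  if (length(object@mismatches))
    cat("  stoichiometry mismatches:", paste(object@mismatches, collapse = ", "), "\n")
})

setMethod("show", "TFAProblem", function(object) {
  cat(sprintf("TFAProblem on '%s': %d variables (%d binary), %d eq + %d ineq constraints\n",
              object@model@name, nrow(object@vars), sum(object@vars$integer),
              length(object@lp$b_eq), length(object@lp$b_ub)))
  cat(sprintf("  thermodynamically constrained reactions: %d (delta = %g)\n",
              length(object@thermoRxns), object@params@delta))
})

setMethod("show", "TVAResult", function(object) {
  cat(sprintf("TVAResult: %d variables\n", nrow(object@ranges)))
  nf <- object@ranges[object@ranges$type == "NF", ]
  if (nrow(nf)) {
    bid <- sum(nf$min < -object@tol & nf$max > object@tol, na.rm = TRUE)
    cat(sprintf("  bidirectional reactions (tol %g): %d\n", object@tol, bid))
  }
})

setMethod("show", "SamplePool", function(object) {
  cat(sprintf("SamplePool: %d samples x %d variables (%s, seed %d)\n",
              nrow(object@samples), ncol(object@samples), object@sampler,
              object@seed))
})

setMethod("show", "SteadyState", function(object) {
  cat(sprintf("SteadyState of '%s': %d fluxes, %d log-concentrations\n",
              object@model, length(object@fluxes), length(object@lnConc)))
})

setMethod("show", "TransferReport", function(object) {
  cat(sprintf("TransferReport (%s phase): %d band violation(s)\n",
              object@phase, object@objective))
  if (length(object@violated))
    cat("  violated:", paste(object@violated, collapse = ", "), "\n")
})

setMethod("show", "KineticEnsemble", function(object) {
  cnt <- object@counts
  cat(sprintf("KineticEnsemble on '%s': %d sampled, %d stable (%.1f%%), %d unstable, %d singular\n",
              object@state@model, cnt$sampled, cnt$stable,
              100 * cnt$stable / max(1, cnt$sampled), cnt$unstable,
              cnt$singular))
})

setMethod("show", "DIReport", function(object) {
  cat(sprintf("DIReport (%s) over %d shared enzymes: %d fluxes\n",
              object@aggregation, length(object@sharedEnzymes),
              nrow(object@table)))
  if (nrow(object@table)) {
    cat(sprintf("  DI range: [%.3g, %.3g]\n", min(object@table$di),
                max(object@table$di)))
  }
})

setMethod("show", "RankingReport", function(object) {
  cat(sprintf("RankingReport for flux '%s' (top %d):\n", object@target,
              object@topK))
  print(utils::head(object@table, object@topK), row.names = FALSE)
})
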