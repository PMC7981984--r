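## Deviation index and cross-model comparison reports.
##
## By the summation theorem an FCC row summed over all enzymes is 1; summed
## only over the enzymes shared with a smaller model it falls short by
## exactly the control held by the expansion-added enzymes.  The deviation
## index DI = |sum_{k in shared} C^v_k - 1| therefore measures how much
## flux control a network expansion moved onto its new reactions.

.enzymeIds <- function(model) {
  model@reactions$id[model@reactions$kind %in% c("enzymatic", "lumped")]
}

#' Deviation index over a shared enzyme set
#'
#' @param ensemble A [KineticEnsemble-class] of the larger model.
#' @param sharedEnzymes Enzyme (reaction) ids shared with the smaller
#'   model.  With one enzyme per reaction, every reaction is a perturbable
#'   step, so the full set is all reaction ids (for which DI = 0 by the
#'   summation theorem).
#' @param model Optional large [MetabolicModel-class]; when given,
#'   `sharedEnzymes` is restricted to enzymatic and lumped reactions,
#'   mirroring comparisons over common *enzymatic* reactions only.
#' @param aggregation `"population_mean_fcc"` (DI of the mean FCCs,
#'   default) or `"per_instance_mean"` (mean over per-instance DIs).  The
#'   per-instance DI matrix is returned in either case.
#' @param fluxIds Fluxes to report (default: all).
#' @return A [DIReport-class] with percentile classes unset (see
#'   [percentileClasses()]).
#' @export
deviationIndex <- function(ensemble, sharedEnzymes, model = NULL,
                           aggregation = c("population_mean_fcc",
                                           "per_instance_mean"),
                           fluxIds = NULL) {
  aggregation <- match.arg(aggregation)
  if (!length(sharedEnzymes)) stop("empty shared enzyme set")
  if (!is.null(model))
    sharedEnzymes <- intersect(sharedEnzymes, .enzymeIds(model))
  fcc <- ensemble@FCC
  if (dim(fcc)[3] == 0) stop("ensemble has no stable instances")
  bad <- setdiff(sharedEnzymes, colnames(fcc))
  if (length(bad)) stop("shared enzyme(s) not in ensemble: ",
                        paste(bad, collapse = ", "))
  if (is.null(fluxIds)) fluxIds <- rownames(fcc)
  sub <- fcc[fluxIds, sharedEnzymes, , drop = FALSE]
  perInstance <- abs(apply(sub, c(1, 3), sum) - 1)   # fluxes x instances
  di <- if (aggregation == "population_mean_fcc") {
    abs(rowSums(meanFCC(ensemble)[fluxIds, sharedEnzymes, drop = FALSE]) - 1)
  } else {
    rowMeans(perInstance)
  }
  methods::new("DIReport",
    table = data.frame(flux_id = fluxIds, di = unname(di),
                       percentile_class = NA_character_,
                       stringsAsFactors = FALSE),
    sharedEnzymes = sharedEnzymes, aggregation = aggregation,
    perInstance = perInstance)
}

#' Assign DI percentile classes
#'
#' Classes by empirical percentile of the DI values: low (0-25), mid
#' (25-75), high (75-100); ties share the lower class.
#'
#' @param report A [DIReport-class] with at least 4 reactions.
#' @return The report with `percentile_class` filled in.
#' @export
percentileClasses <- function(report) {
  di <- report@table$di
  if (length(di) < 4) stop("need at least 4 reactions for percentile classes")
  ## empirical percentile of each value: fraction of values strictly below,
  ## so ties land in the lower class
  pct <- 100 * (rank(di, ties.method = "min") - 1) / length(di)
  cls <- ifelse(pct < 25, "low", ifelse(pct < 75, "mid", "high"))
  report@table$percentile_class <- cls
  report
}

#' Rank enzymes by absolute mean control over a target flux
#'
#' @param ensemble A [KineticEnsemble-class].
#' @param targetFlux Flux (reaction) id, e.g. the growth reaction.
#' @param topK Number of top controllers (default 9).
#' @param enzymes Optional enzyme subset (default: all ensemble enzymes).
#' @return A [RankingReport-class]; the table carries the population mean,
#'   |mean| and the FCC quartiles, sorted by |mean| descending with ties
#'   broken by enzyme id.
#' @export
rankControllers <- function(ensemble, targetFlux, topK = 9L,
                            enzymes = NULL) {
  fcc <- ensemble@FCC
  if (dim(fcc)[3] == 0) stop("ensemble has no stable instances")
  if (!targetFlux %in% rownames(fcc))
    stop("target flux not in ensemble: ", targetFlux)
  if (is.null(enzymes)) enzymes <- colnames(fcc)
  pop <- fcc[targetFlux, enzymes, , drop = TRUE]
  pop <- matrix(pop, nrow = length(enzymes),
                dimnames = list(enzymes, NULL))
  mean_fcc <- rowMeans(pop)
  q <- apply(pop, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  tab <- data.frame(enzyme = enzymes, mean_fcc = unname(mean_fcc),
                    abs_mean = abs(unname(mean_fcc)),
                    q25 = q[1, ], q75 = q[2, ],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$abs_mean, tab$enzyme), ]
  rownames(tab) <- NULL
  methods::new("RankingReport", table = tab, target = targetFlux,
               topK = as.integer(topK))
}

#' Pairwise union of two models' top controllers
#'
#' Mirrors the side-by-side comparison of two models' strongest growth
#' controllers: takes the union of each ensemble's top-k enzymes (over the
#' shared enzyme set) and reports both models' means and quartiles.
#'
#' @param ensA,ensB [KineticEnsemble-class] objects.
#' @param targetA,targetB Target flux id in each ensemble.
#' @param sharedEnzymes Enzyme ids comparable across both models.
#' @param topK Per-model top-k (default 9).
#' @return `data.frame` with per-model mean/quartile columns.
#' @export
topControllerUnion <- function(ensA, ensB, targetA, targetB = targetA,
                               sharedEnzymes, topK = 9L) {
  ra <- rankControllers(ensA, targetA, topK, enzymes = sharedEnzymes)@table
  rb <- rankControllers(ensB, targetB, topK, enzymes = sharedEnzymes)@table
  un <- sort(union(utils::head(ra$enzyme, topK), utils::head(rb$enzyme, topK)))
  a <- ra[match(un, ra$enzyme), c("mean_fcc", "q25", "q75")]
  b <- rb[match(un, rb$enzyme), c("mean_fcc", "q25", "q75")]
  names(a) <- paste0(names(a), "_A"); names(b) <- paste0(names(b), "_B")
  cbind(data.frame(enzyme = un, stringsAsFactors = FALSE), a, b)
}

#' Subsystem-wise absolute FCC deviation between two ensembles
#'
#' For reaction `i` and subsystem `j`, sums |mean FCC difference| over the
#' shared enzymes belonging to subsystem `j` — the stacked-bar quantity of
#' the flux-vs-deviation comparison.
#'
#' @param ensA Small-model [KineticEnsemble-class].
#' @param ensB Large-model [KineticEnsemble-class].
#' @param mapping [NestedMapping-class] from A's model into B's.
#' @param modelA,modelB The corresponding models (for subsystem labels and
#'   enzyme kinds).
#' @param reactions Reaction ids (A-side) to report; default: all shared
#'   enzymatic reactions.
#' @return A [SubsystemDeviationReport-class]; reference fluxes are A's.
#' @export
subsystemAbsDeviation <- function(ensA, ensB, mapping, modelA, modelB,
                                  reactions = NULL) {
  toLarge <- stats::setNames(mapping@shared$id_large, mapping@shared$id_small)
  sharedA <- intersect(names(toLarge), .enzymeIds(modelA))
  sharedA <- sharedA[toLarge[sharedA] %in% .enzymeIds(modelB)]
  if (is.null(reactions)) reactions <- sharedA
  if (!all(reactions %in% names(toLarge)))
    stop("reaction(s) not shared: ",
         paste(setdiff(reactions, names(toLarge)), collapse = ", "))
  mA <- meanFCC(ensA); mB <- meanFCC(ensB)
  subs <- modelA@reactions$subsystem[match(sharedA, modelA@reactions$id)]
  subsystems <- sort(unique(subs))
  dev <- matrix(0, length(reactions), length(subsystems),
                dimnames = list(reactions, subsystems))
  diff <- abs(mA[reactions, sharedA, drop = FALSE] -
                mB[toLarge[reactions], toLarge[sharedA], drop = FALSE])
  for (s in subsystems) {
    cols <- sharedA[subs == s]
    if (!length(cols)) { warning("subsystem without shared enzymes: ", s); next }
    dev[, s] <- rowSums(diff[, cols, drop = FALSE])
  }
  methods::new("SubsystemDeviationReport", deviations = dev,
               referenceFlux = fluxes(ensA@state)[reactions])
}

#' Export a DI report (TSV + optional GraphML annotation)
#'
#' @param report A [DIReport-class].
#' @param path Output TSV path.
#' @param graphml Optional path for a GraphML node-annotation export
#'   (reaction -> DI class) for network diagram tools.
#' @return `path`, invisibly.
#' @export
writeDIReport <- function(report, path, graphml = NULL) {
  utils::write.table(report@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    tab <- report@table
    nodes <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="di" for="node" attr.name="deviation_index" attr.type="double"/>',
      '<key id="cls" for="node" attr.name="di_class" attr.type="string"/>',
      '<graph id="DI" edgedefault="directed">',
      sprintf('<node id="%s"><data key="di">%.10g</data><data key="cls">%s</data></node>',
              tab$flux_id, tab$di, tab$percentile_class),
      "</graph>", "</graphml>")
    writeLines(nodes, graphml)
  }
  invisible(path)
}
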