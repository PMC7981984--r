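## Relating nested models: reaction mapping and lumped-reaction comparison.

.stoichSignature <- function(S, j, metMap = identity) {
  col <- S[, j]
  idx <- which(col != 0)
  ids <- metMap(rownames(S)[idx])
  ord <- order(ids)
  paste(sprintf("%s:%.12g", ids[ord], col[idx][ord]), collapse = ";")
}

#' Build the reaction/metabolite mapping between two nested models
#'
#' Reactions are matched by id (optionally through an alias table); a
#' matched pair must have identical stoichiometry.  Every non-lumped
#' small-model reaction must have a large-model counterpart, otherwise the
#' models are not nested and an error is raised.  Lumped reactions are
#' model-specific by construction; unmatched small-model lumps are allowed
#' and simply absent from the mapping.
#'
#' @param small,large [MetabolicModel-class] objects with `small` nested in
#'   `large`.
#' @param alias Optional named character vector mapping small-model
#'   reaction ids to large-model ids.
#' @return A [NestedMapping-class]; id matches with differing stoichiometry
#'   are listed in its `mismatches` slot (and excluded from `shared`).
#' @export
buildNestedMapping <- function(small, large, alias = NULL) {
  sr <- small@reactions; lr <- large@reactions
  target <- sr$id
  if (!is.null(alias)) {
    hit <- target %in% names(alias)
    target[hit] <- alias[target[hit]]
  }
  found <- target %in% lr$id
  core <- sr$kind != "lumped"
  if (any(core & !found))
    stop("models are not nested: small-model core reaction(s) without ",
         "counterpart in '", large@name, "': ",
         paste(sr$id[core & !found], collapse = ", "))

  sharedMet <- intersect(small@metabolites$id, large@metabolites$id)
  mismatch <- character()
  keep <- logical(nrow(sr))
  for (k in which(found)) {
    sig_s <- .stoichSignature(small@S, sr$id[k])
    sig_l <- .stoichSignature(large@S, target[k])
    if (identical(sig_s, sig_l)) keep[k] <- TRUE
    else mismatch <- c(mismatch, sr$id[k])
  }
  shared <- data.frame(id_small = sr$id[found & keep],
                       id_large = target[found & keep],
                       stringsAsFactors = FALSE)
  methods::new("NestedMapping",
    smallName = small@name, largeName = large@name, shared = shared,
    addedReactions = setdiff(lr$id, shared$id_large),
    sharedMetabolites = data.frame(id_small = sharedMet, id_large = sharedMet,
                                   stringsAsFactors = FALSE),
    addedMetabolites = setdiff(large@metabolites$id, sharedMet),
    mismatches = mismatch)
}

#' Compare the lumped-reaction sets of several models
#'
#' Under `criterion = "net_stoichiometry"` two lumps are the same when their
#' signed coefficient maps are identical (no clearing of common factors:
#' `A -> B` differs from `2A -> 2B`).  Under `criterion = "subnetwork"` two
#' lumps are the same when they collapse the same set of constituent
#' reactions; this requires `constituents`.
#'
#' @param models List of [MetabolicModel-class] objects, each with at least
#'   one lumped reaction.
#' @param criterion `"net_stoichiometry"` (default) or `"subnetwork"`.
#' @param constituents For the subnetwork criterion: a list (one element
#'   per model, same order) of named lists mapping lumped reaction id to a
#'   character vector of constituent reaction ids.
#' @return A [LumpComparison-class].
#' @export
compareLumpedSets <- function(models,
                              criterion = c("net_stoichiometry", "subnetwork"),
                              constituents = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(length(models) >= 2)
  names <- vapply(models, modelName, character(1))
  lumpIds <- lapply(models, function(m) m@reactions$id[m@reactions$kind == "lumped"])
  if (any(lengths(lumpIds) == 0))
    stop("every model must contain at least one lumped reaction")

  consUnion <- consCommon <- integer()
  if (criterion == "net_stoichiometry") {
    sigs <- lapply(seq_along(models), function(k) {
      m <- models[[k]]
      unique(vapply(match(lumpIds[[k]], m@reactions$id),
                    function(j) .stoichSignature(m@S, j), character(1)))
    })
  } else {
    if (is.null(constituents))
      stop("criterion 'subnetwork' requires constituent-reaction annotations")
    sigs <- lapply(seq_along(models), function(k) {
      ann <- constituents[[k]]
      if (!all(lumpIds[[k]] %in% names(ann)))
        stop("missing constituent annotation for lump(s) of ", names[k])
      unique(vapply(ann[lumpIds[[k]]],
                    function(v) paste(sort(unique(v)), collapse = ";"),
                    character(1)))
    })
    pools <- lapply(seq_along(models), function(k)
      unique(unlist(constituents[[k]][lumpIds[[k]]])))
    consUnion <- stats::setNames(lengths(pools), names)
    consCommon <- length(Reduce(intersect, pools))
  }

  all_sigs <- unique(unlist(sigs))
  presence <- vapply(sigs, function(s) all_sigs %in% s,
                     logical(length(all_sigs)))
  presence <- matrix(presence, nrow = length(all_sigs))
  nIn <- rowSums(presence)
  common <- sum(nIn == length(models))
  uniq <- vapply(seq_along(models), function(k)
    sum(nIn == 1L & presence[, k]), integer(1))

  methods::new("LumpComparison",
    commonCount = as.integer(common),
    uniqueCounts = stats::setNames(as.integer(uniq), names),
    partialCount = as.integer(sum(nIn > 1L & nIn < length(models))),
    totalDistinct = length(all_sigs),
    constituentUnionCounts = as.integer(consUnion) |>
      stats::setNames(names(consUnion)),
    constituentCommonCount = as.integer(consCommon),
    criterion = criterion)
}

#' Count lumped reactions by id prefix
#'
#' Convenience counter mirroring the deposited models' convention that
#' lumped reaction ids begin with `"LMPD"`.
#'
#' @param model A [MetabolicModel-class].
#' @return Integer count.
#' @export
countLumpedReactions <- function(model) {
  sum(startsWith(model@reactions$id, LUMP_PREFIX) |
        model@reactions$kind == "lumped")
}
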