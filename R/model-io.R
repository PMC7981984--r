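## Model construction, validation and I/O.
##
## The tabular dialect is a TSV with one row per (reaction, metabolite):
## columns rxn_id, metabolite_id, coeff, lb, ub, subsystem, kind, dG0,
## dG0_err.  Reaction-level fields are taken from the first row of each
## reaction.  Metabolite compartments default to the single-letter id suffix
## convention ("g6p_c" -> compartment "c").

.compartmentFromId <- function(id) {
  suf <- sub("^.*_([a-z])$", "\\1", id)
  ifelse(suf != id, suf, "c")
}

.inferKind <- function(id, nmet, kind) {
  out <- as.character(kind)
  miss <- is.na(out) | !nzchar(out)
  out[miss & nmet == 1L] <- "exchange"
  out[is.na(out) | !nzchar(out)] <- "enzymatic"
  ## the LMPD prefix always wins (deposited-model convention)
  out[startsWith(id, LUMP_PREFIX)] <- "lumped"
  out
}

#' Build a MetabolicModel from long-format stoichiometry
#'
#' @param name Model name.
#' @param stoich `data.frame` with columns `rxn_id`, `metabolite_id`,
#'   `coeff` and per-reaction columns `lb`, `ub`, `subsystem`, `kind`,
#'   `dG0`, `dG0_err` (the latter five may be missing/`NA`).
#' @param metabolites Optional metabolite annotation `data.frame` with
#'   columns `id` and any of `name`, `compartment`, `formula`, `is_bbb`.
#'   When supplied, a reaction referencing an undeclared metabolite is an
#'   error.
#' @return A validated [MetabolicModel-class].  Reactions whose id starts
#'   with `"LMPD"` are flagged `kind = "lumped"`.
#' @export
makeModel <- function(name, stoich, metabolites = NULL) {
  stopifnot(all(c("rxn_id", "metabolite_id", "coeff") %in% names(stoich)))
  for (col in c("lb", "ub", "subsystem", "kind", "dG0", "dG0_err")) {
    if (is.null(stoich[[col]])) stoich[[col]] <- NA
  }
  if (any(is.na(stoich$coeff)))
    stop("non-numeric stoichiometric coefficient in reaction(s): ",
         paste(unique(stoich$rxn_id[is.na(stoich$coeff)]), collapse = ", "))

  rids <- unique(stoich$rxn_id)
  if (!is.null(metabolites)) {
    undecl <- setdiff(stoich$metabolite_id, metabolites$id)
    if (length(undecl)) {
      bad <- unique(stoich$rxn_id[stoich$metabolite_id %in% undecl])
      stop("reaction(s) ", paste(bad, collapse = ", "),
           " reference undeclared metabolite(s): ",
           paste(undecl, collapse = ", "))
    }
    mids <- metabolites$id
  } else {
    mids <- unique(stoich$metabolite_id)
  }

  first <- stoich[!duplicated(stoich$rxn_id), , drop = FALSE]
  first <- first[match(rids, first$rxn_id), ]
  nmet <- as.integer(table(factor(stoich$rxn_id, levels = rids)))
  lb <- as.numeric(first$lb); lb[is.na(lb)] <- -1000
  ub <- as.numeric(first$ub); ub[is.na(ub)] <- 1000
  subsystem <- as.character(first$subsystem)
  subsystem[is.na(subsystem)] <- ""
  rxn <- data.frame(id = rids, lb = lb, ub = ub, subsystem = subsystem,
                    kind = .inferKind(rids, nmet, first$kind),
                    dG0 = as.numeric(first$dG0),
                    dG0_err = as.numeric(first$dG0_err),
                    stringsAsFactors = FALSE)

  met <- data.frame(id = mids, name = mids,
                    compartment = .compartmentFromId(mids),
                    formula = NA_character_, is_bbb = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(metabolites)) {
    for (col in c("name", "compartment", "formula", "is_bbb")) {
      if (!is.null(metabolites[[col]]))
        met[[col]] <- metabolites[[col]][match(mids, metabolites$id)]
    }
    met$is_bbb[is.na(met$is_bbb)] <- FALSE
  }

  dup <- stoich[duplicated(stoich[c("rxn_id", "metabolite_id")]), ]
  if (nrow(dup))
    stop("duplicate (reaction, metabolite) rows for reaction(s): ",
         paste(unique(dup$rxn_id), collapse = ", "))
  S <- Matrix::sparseMatrix(
    i = match(stoich$metabolite_id, mids),
    j = match(stoich$rxn_id, rids),
    x = as.numeric(stoich$coeff),
    dims = c(length(mids), length(rids)),
    dimnames = list(mids, rids))

  methods::new("MetabolicModel", name = name, metabolites = met,
               reactions = rxn, S = S)
}

#' Load a stoichiometric model from disk
#'
#' @param path File path.
#' @param format `"tsv"` (the package's tabular dialect), `"sbml"`
#'   (SBML Level 3 with FBC flux bounds), or `NULL` to infer from the file
#'   extension.
#' @param name Model name; defaults to the file stem.
#' @return A [MetabolicModel-class].
#' @export
loadModel <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = , txt = "tsv", xml = , sbml = "sbml",
                     stop("cannot infer model format from extension of ", path))
  }
  format <- match.arg(format, c("tsv", "sbml", "mat"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  switch(format,
         tsv = .readModelTSV(path, name),
         sbml = .readModelSBML(path, name),
         mat = stop("MAT-container models are not supported; export the ",
                    "model to the TSV dialect or SBML first"))
}

.readModelTSV <- function(path, name) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("rxn_id", "metabolite_id", "coeff")
  if (!all(need %in% names(tab)))
    stop("malformed model TSV ", path, ": missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  makeModel(name, tab)
}

#' Write a model in the tabular dialect
#'
#' @param model A [MetabolicModel-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeModelTSV <- function(model, path) {
  S <- methods::as(methods::as(model@S, "generalMatrix"), "TsparseMatrix")
  ord <- order(S@j, S@i)
  rxn <- model@reactions
  j <- S@j[ord] + 1L
  tab <- data.frame(
    rxn_id = rxn$id[j],
    metabolite_id = model@metabolites$id[S@i[ord] + 1L],
    coeff = S@x[ord],
    lb = rxn$lb[j], ub = rxn$ub[j],
    subsystem = rxn$subsystem[j], kind = rxn$kind[j],
    dG0 = rxn$dG0[j], dG0_err = rxn$dG0_err[j],
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- SBML L3 (FBC bounds) ----------------------------------------------

.readModelSBML <- function(path, name) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mids <- xml2::xml_attr(sp, "id")
  met <- data.frame(
    id = mids,
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), mids,
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = NA_character_,
    is_bbb = !is.na(xml2::xml_attr(sp, "isBBB")) &
      xml2::xml_attr(sp, "isBBB") == "true",
    stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rows <- lapply(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    reac <- xml2::xml_find_all(r, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(r, "./listOfProducts/speciesReference")
    spec <- c(xml2::xml_attr(reac, "species"), xml2::xml_attr(prod, "species"))
    if (length(spec) == 0)
      stop("malformed SBML: reaction ", rid, " has no species references")
    coef <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
              as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    lbid <- xml2::xml_attr(r, "lowerFluxBound")
    ubid <- xml2::xml_attr(r, "upperFluxBound")
    data.frame(rxn_id = rid, metabolite_id = spec, coeff = coef,
               lb = if (!is.na(lbid)) pval[[lbid]] else -1000,
               ub = if (!is.na(ubid)) pval[[ubid]] else 1000,
               subsystem = .sbmlAttrOr(r, "subsystem", ""),
               kind = .sbmlAttrOr(r, "kind", NA_character_),
               dG0 = as.numeric(.sbmlAttrOr(r, "dG0", NA)),
               dG0_err = as.numeric(.sbmlAttrOr(r, "dG0err", NA)),
               stringsAsFactors = FALSE)
  })
  makeModel(name, do.call(rbind, rows), metabolites = met)
}

.sbmlAttrOr <- function(node, attr, default) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

#' Write a model as SBML Level 3 with FBC-style flux bounds
#'
#' Subsystem, kind and Gibbs-energy annotations are carried as plain
#' attributes so that a TSV/SBML round trip is lossless within the package.
#'
#' @param model A [MetabolicModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeModelSBML <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  met <- model@metabolites; rxn <- model@reactions; S <- model@S
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('<model id="%s">', esc(model@name)),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>',
            unique(met$compartment)),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf('<species id="%s" name="%s" compartment="%s" isBBB="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            esc(met$id), esc(met$name), esc(met$compartment),
            tolower(as.character(met$is_bbb))),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="lb_%d" value="%.17g" constant="true"/>',
            seq_len(nrow(rxn)), rxn$lb),
    sprintf('<parameter id="ub_%d" value="%.17g" constant="true"/>',
            seq_len(nrow(rxn)), rxn$ub),
    "</listOfParameters>",
    "<listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    col <- S[, j]
    idx <- which(col != 0)
    extra <- sprintf(' subsystem="%s"', esc(rxn$subsystem[j]))
    extra <- paste0(extra, sprintf(' kind="%s"', rxn$kind[j]))
    if (!is.na(rxn$dG0[j]))
      extra <- paste0(extra, sprintf(' dG0="%.17g"', rxn$dG0[j]))
    if (!is.na(rxn$dG0_err[j]))
      extra <- paste0(extra, sprintf(' dG0err="%.17g"', rxn$dG0_err[j]))
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" lowerFluxBound="lb_%d" upperFluxBound="ub_%d"%s>',
      esc(rxn$id[j]), tolower(as.character(rxn$lb[j] < 0)), j, j, extra))
    neg <- idx[col[idx] < 0]; pos <- idx[col[idx] > 0]
    if (length(neg)) lines <- c(lines, "<listOfReactants>",
      sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
              esc(met$id[neg]), -col[neg]), "</listOfReactants>")
    if (length(pos)) lines <- c(lines, "<listOfProducts>",
      sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
              esc(met$id[pos]), col[pos]), "</listOfProducts>")
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

## ---- directionality presets --------------------------------------------

.presetEnv <- new.env(parent = emptyenv())

#' Register or list flux-directionality presets
#'
#' A preset is a table of reaction ids and a direction sign: `+1` restricts
#' the reaction to its forward direction (`lb` raised to 0), `-1` to its
#' backward direction (`ub` lowered to 0).
#'
#' @param name Preset name.
#' @param table `data.frame` with columns `id` and `sign`.
#' @return `registerDirectionalityPreset()` returns `name` invisibly;
#'   `directionalityPresets()` the registered names.
#' @export
registerDirectionalityPreset <- function(name, table) {
  stopifnot(is.character(name), all(c("id", "sign") %in% names(table)),
            all(table$sign %in% c(-1, 1)))
  assign(name, table, envir = .presetEnv)
  invisible(name)
}

#' @rdname registerDirectionalityPreset
#' @export
directionalityPresets <- function() ls(.presetEnv)

## Aerobic E. coli physiology: acetate kinase / phosphotransacetylase toward
## acetate production, succinyl-CoA synthetase toward succinate, FBA
## catabolic, magnesium and phosphate transport toward uptake, and the
## polyphosphate kinases toward polymerisation (iJO1366 id conventions).
.initPresets <- function() {
  registerDirectionalityPreset("none",
    data.frame(id = character(), sign = numeric()))
  registerDirectionalityPreset("aerobic-ecoli", data.frame(
    id = c("ACKr", "PTAr", "SUCOAS", "FBA", "MG2tpp", "PIt2rpp",
           "PPK2r", "PPKr"),
    sign = c(-1, 1, -1, 1, 1, 1, 1, 1)))
}

#' Apply a flux-directionality preset to a model
#'
#' Tightens the bounds of each listed reaction to one sign; reactions the
#' model does not contain are reported in a warning and in the
#' `"preset_missing"` attribute, not treated as fatal.
#'
#' @param model A [MetabolicModel-class].
#' @param preset Preset name (see [directionalityPresets()]).
#' @return The model with tightened bounds.
#' @export
applyDirectionalityPreset <- function(model, preset) {
  if (!exists(preset, envir = .presetEnv))
    stop("unknown preset '", preset, "'; registered presets: ",
         paste(directionalityPresets(), collapse = ", "))
  tab <- get(preset, envir = .presetEnv)
  rxn <- model@reactions
  missing <- setdiff(tab$id, rxn$id)
  if (length(missing))
    warning("preset '", preset, "' lists reaction(s) absent from model: ",
            paste(missing, collapse = ", "))
  for (k in which(tab$id %in% rxn$id)) {
    i <- match(tab$id[k], rxn$id)
    if (tab$sign[k] > 0) rxn$lb[i] <- max(rxn$lb[i], 0)
    else rxn$ub[i] <- min(rxn$ub[i], 0)
  }
  model@reactions <- rxn
  attr(model, "preset_missing") <- missing
  methods::validObject(model)
  model
}

#' Add basal passive transporters for untransported metabolites
#'
#' Every intracellular metabolite lacking a transport or exchange reaction
#' (and not listed in `excluded`, e.g. because it is highly polar or very
#' large) receives a passive transport reaction with lower bound `basal`,
#' so it operates at least at a basal level.
#'
#' @param model A [MetabolicModel-class].
#' @param excluded Metabolite ids to skip.
#' @param basal Minimum flux, default `1e-6` mmol/gDW/h.
#' @param extracellular Compartment labels counted as outside the cell.
#' @return The augmented model; new reactions are named
#'   `TransFlux_<metabolite>`.
#' @export
addBasalTransporters <- function(model, excluded = character(),
                                 basal = 1e-6,
                                 extracellular = c("e", "p")) {
  stopifnot(basal > 0)
  met <- model@metabolites; rxn <- model@reactions; S <- model@S
  boundary <- rxn$kind %in% c("transport", "exchange")
  transported <- if (any(boundary))
    rownames(S)[Matrix::rowSums(S[, boundary, drop = FALSE] != 0) > 0]
  else character()
  todo <- met$id[!(met$compartment %in% extracellular) &
                 !(met$id %in% transported) & !(met$id %in% excluded)]
  if (!length(todo)) return(model)
  add <- data.frame(id = paste0("TransFlux_", todo), lb = basal, ub = 1000,
                    subsystem = "Transport", kind = "transport",
                    dG0 = NA_real_, dG0_err = NA_real_,
                    stringsAsFactors = FALSE)
  Snew <- Matrix::sparseMatrix(i = match(todo, met$id), j = seq_along(todo),
                               x = -1, dims = c(nrow(met), length(todo)),
                               dimnames = list(met$id, add$id))
  model@reactions <- rbind(rxn, add)
  model@S <- cbind(S, Snew)
  methods::validObject(model)
  model
}
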