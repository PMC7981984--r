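## End-to-end workflow orchestration.
##
## One run directory per configuration; every stage writes its outputs to
## files named by level and stage, records seeds and the configuration
## hash, and is skipped on re-run when its outputs already exist (stage
## idempotence).  Stage order per level: TFA build -> sampling ->
## representative (transfer from the previous level when there is one) ->
## saturation sampling (stratified from the previous level) -> stability
## filter -> control coefficients -> deviation reports.

#' Default pipeline configuration
#'
#' @param outputDir Run directory.
#' @param models Character vector of model file paths (smallest first), or
#'   `NULL` to generate the synthetic family.
#' @param physiology Optional path to a physiology bounds TSV.
#' @param preset Directionality preset name (default `"none"`).
#' @param relaxation Transfer band relaxation (default 0.01).
#' @param nFlux,nConc,nKinetic Sample counts (flux vectors, concentration
#'   vectors, kinetic instances).
#' @param seed Master seed; per-stage seeds derive from it.
#' @param target Target flux id for controller rankings.
#' @param delta Equilibrium-exclusion threshold (|ln Gamma| minimum).
#' @return A named list.
#' @export
pipelineConfig <- function(outputDir, models = NULL, physiology = NULL,
                           preset = "none", relaxation = 0.01,
                           nFlux = 1000, nConc = 1000, nKinetic = 200,
                           seed = 1L, target = "EX_BBB", delta = 0.01) {
  list(outputDir = outputDir, models = models, physiology = physiology,
       preset = preset, relaxation = relaxation, nFlux = nFlux,
       nConc = nConc, nKinetic = nKinetic, seed = as.integer(seed),
       target = target, delta = delta)
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config[order(names(config))], f, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(f))
}

.logStage <- function(logPath, stage, level, t0, ...) {
  rec <- c(list(stage = stage, level = level,
                elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = logPath, append = TRUE)
}

.writeState <- function(state, path) {
  jsonlite::write_json(list(model = state@model,
                            fluxes = as.list(fluxes(state)),
                            lnConc = as.list(lnConc(state)),
                            gamma = as.list(displacement(state)),
                            provenance = state@provenance),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
}

#' Read a steady state written by the pipeline
#' @param path JSON path produced by the pipeline or CLI.
#' @return A [SteadyState-class].
#' @export
readSteadyState <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  methods::new("SteadyState", fluxes = num(j$fluxes),
               lnConc = num(j$lnConc), gamma = num(j$gamma),
               model = j$model,
               provenance = lapply(j$provenance, function(v) v))
}

#' Run the full nested-model workflow
#'
#' @param config A list from [pipelineConfig()] or a YAML file path with
#'   the same fields.
#' @param resume Skip stages whose outputs already exist (default TRUE).
#' @return The run directory, invisibly; key outputs per level `k`:
#'   `modelk.tsv`, `statek.json`, `transferk_flux.tsv` /
#'   `transferk_conc.tsv` (k > 1), `ensemblek.json` (counts), `fcck.tsv`
#'   (mean FCCs), `dik.tsv`, `rankingk.tsv`, and `log.jsonl`.
#' @export
runPipeline <- function(config, resume = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outputDir, ...)
  logPath <- out("log.jsonl")
  hash <- .configHash(config)
  jsonlite::write_json(c(config, list(config_hash = hash)),
                       out("config.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")

  ## ---- models
  t0 <- as.numeric(Sys.time())
  if (is.null(config$models)) {
    fam <- generateNestedToys(seed = config$seed)
    models <- fam$models; mappings <- fam$mappings
    physiology <- fam$physiology
  } else {
    models <- lapply(config$models, loadModel)
    mappings <- lapply(seq_len(length(models) - 1L), function(l)
      buildNestedMapping(models[[l]], models[[l + 1L]]))
    physiology <- if (!is.null(config$physiology))
      utils::read.delim(config$physiology) else NULL
  }
  if (!identical(config$preset, "none"))
    models <- lapply(models, applyDirectionalityPreset, preset = config$preset)
  for (m in models) writeModelTSV(m, out(paste0(modelName(m), ".tsv")))
  .logStage(logPath, "models", 0L, t0, n_models = length(models),
            config_hash = hash)

  params <- thermoParams(delta = config$delta)
  nL <- length(models)
  states <- vector("list", nL)
  ensembles <- vector("list", nL)
  saturations <- NULL

  for (l in seq_len(nL)) {
    model <- models[[l]]
    problem <- buildTFAProblem(model, params, physiology = physiology)
    seedL <- config$seed + 100L * l

    ## ---- representative steady state
    t0 <- as.numeric(Sys.time())
    statePath <- out(sprintf("state%d.json", l))
    if (resume && file.exists(statePath)) {
      states[[l]] <- readSteadyState(statePath)
      .logStage(logPath, "steady_state", l, t0, skipped = TRUE)
    } else if (l == 1L) {
      pattern <- fixDirectionalities(problem)
      poolF <- sampleFluxSpace(problem, n = config$nFlux, seed = seedL,
                               pattern = pattern)
      selF <- selectRepresentative(poolF)
      poolC <- sampleConcentrationSpace(problem, selF$values,
                                        n = config$nConc, seed = seedL + 1L)
      selC <- selectRepresentative(poolC)
      states[[l]] <- makeSteadyState(problem, selF$values, selC$values,
                                     provenance = list(seed = seedL,
                                                       method = "pca"))
      .writeState(states[[l]], statePath)
      .logStage(logPath, "steady_state", l, t0, n_flux = config$nFlux)
    } else {
      tr <- transferSteadyState(problem, mappings[[l - 1L]],
                                states[[l - 1L]], n = config$nFlux,
                                seed = seedL,
                                relaxation = config$relaxation)
      states[[l]] <- tr$state
      .writeState(states[[l]], statePath)
      writeTransferReport(tr$fluxReport, out(sprintf("transfer%d_flux.tsv", l)))
      writeTransferReport(tr$concReport, out(sprintf("transfer%d_conc.tsv", l)))
      .logStage(logPath, "steady_state", l, t0,
                flux_violations = tr$fluxReport@objective,
                conc_violations = tr$concReport@objective)
    }

    ## ---- kinetic ensemble (stratified from the previous level)
    t0 <- as.numeric(Sys.time())
    mech <- assignMechanisms(model)
    if (l == 1L) {
      ens <- kineticEnsemble(model, states[[l]], mech,
                             n = config$nKinetic, seed = seedL + 2L)
    } else {
      check <- makeStabilityCheck(model, states[[l]], mech)
      strat <- stratifiedResample(saturations, mappings[[l - 1L]], mech,
                                  seed = seedL + 2L,
                                  stabilityCheck = check)
      ens <- kineticEnsemble(model, states[[l]], mech, saturations = strat)
    }
    ensembles[[l]] <- ens
    saturations <- ens@saturations
    cnt <- ensembleCounts(ens)
    jsonlite::write_json(c(cnt, list(
      retained_fraction = if (l > 1L) saturations@info$retainedFraction
                          else 1)),
      out(sprintf("ensemble%d.json", l)), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(flux = rownames(meanFCC(ens)), meanFCC(ens),
                 check.names = FALSE),
      out(sprintf("fcc%d.tsv", l)), sep = "\t", quote = FALSE,
      row.names = FALSE)
    .logStage(logPath, "kinetics", l, t0, sampled = cnt$sampled,
              stable = cnt$stable)

    ## ---- deviation reports
    t0 <- as.numeric(Sys.time())
    if (l > 1L) {
      sharedLarge <- mappings[[l - 1L]]@shared$id_large
      di <- deviationIndex(ens, sharedLarge)
      di <- percentileClasses(di)
      writeDIReport(di, out(sprintf("di%d.tsv", l)))
      .logStage(logPath, "deviation", l, t0, max_di = max(di@table$di))
    }
    if (config$target %in% reactionIds(model)) {
      rk <- rankControllers(ens, config$target)
      utils::write.table(rk@table, out(sprintf("ranking%d.tsv", l)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(config$outputDir)
}
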