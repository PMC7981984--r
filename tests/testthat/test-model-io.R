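test_that("a small TSV model round-trips with identical S, bounds, kinds", {
  tab <- data.frame(
    rxn_id = c("R1", "R1", "R2", "R2", "LMPD_x", "LMPD_x"),
    metabolite_id = c("a_c", "b_c", "b_c", "c_c", "a_c", "c_c"),
    coeff = c(-1, 1, -2, 2, -0.5, 1),
    lb = c(-5, -5, 0, 0, 0, 0), ub = c(5, 5, 8, 8, 1, 1),
    subsystem = "core", kind = NA, dG0 = c(-3, -3, NA, NA, 2, 2),
    dG0_err = NA)
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- loadModel(f)
  expect_s4_class(m, "MetabolicModel")
  expect_equal(dim(stoichMatrix(m)), c(3L, 3L))
  expect_equal(as.numeric(stoichMatrix(m)["b_c", "R2"]), -2)
  expect_equal(reactions(m)$lb, c(-5, 0, 0))
  ## the LMPD prefix flags a lumped reaction
  expect_equal(reactions(m)$kind[reactions(m)$id == "LMPD_x"], "lumped")

  f2 <- tempfile(fileext = ".tsv")
  writeModelTSV(m, f2)
  m2 <- loadModel(f2, name = modelName(m))
  expect_equal(as.matrix(stoichMatrix(m2)), as.matrix(stoichMatrix(m)))
  expect_equal(reactions(m2), reactions(m))
  expect_equal(metabolites(m2), metabolites(m))
})

test_that("SBML write/read round-trips a generated model", {
  m <- toyFamily()$models[[1]]
  f <- tempfile(fileext = ".xml")
  writeModelSBML(m, f)
  m2 <- loadModel(f, format = "sbml", name = modelName(m))
  expect_equal(as.matrix(stoichMatrix(m2))[metaboliteIds(m), reactionIds(m)],
               as.matrix(stoichMatrix(m)))
  expect_equal(reactions(m2)$lb, reactions(m)$lb)
  expect_equal(reactions(m2)$ub, reactions(m)$ub)
  expect_equal(reactions(m2)$kind, reactions(m)$kind)
  expect_equal(reactions(m2)$dG0, reactions(m)$dG0)
  expect_equal(metabolites(m2)$is_bbb, metabolites(m)$is_bbb)
})

test_that("validation rejects malformed models", {
  ## undeclared metabolite is identified with its reaction
  expect_error(
    makeModel("bad",
              data.frame(rxn_id = "R1", metabolite_id = "ghost_c",
                         coeff = -1),
              metabolites = data.frame(id = "a_c")),
    "R1.*ghost_c")
  ## duplicate (reaction, metabolite) rows
  expect_error(
    makeModel("dup", data.frame(rxn_id = c("R1", "R1"),
                                metabolite_id = c("a_c", "a_c"),
                                coeff = c(-1, -1))),
    "duplicate")
  ## missing required column in a TSV
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(rxn_id = "R1", coeff = 1), f, sep = "\t",
              row.names = FALSE)
  expect_error(loadModel(f), "missing column")
  expect_error(loadModel(tempfile(), format = "tsv"), "not found")
})

test_that("directionality presets tighten listed bounds only", {
  tab <- data.frame(
    rxn_id = c("ACKr", "ACKr", "PTAr", "PTAr", "Other", "Other"),
    metabolite_id = c("ac_c", "actp_c", "accoa_c", "actp_c", "a_c", "b_c"),
    coeff = c(-1, 1, -1, 1, -1, 1),
    lb = -10, ub = 10, subsystem = "s", kind = "enzymatic",
    dG0 = NA, dG0_err = NA)
  m <- makeModel("ecoli_frag", tab)
  m2 <- suppressWarnings(applyDirectionalityPreset(m, "aerobic-ecoli"))
  bnd <- function(mm, id) unlist(reactions(mm)[reactions(mm)$id == id,
                                               c("lb", "ub")],
                                 use.names = FALSE)
  ## acetate kinase runs toward acetate (backward as written), PTA forward
  expect_equal(bnd(m2, "ACKr"), c(-10, 0))
  expect_equal(bnd(m2, "PTAr"), c(0, 10))
  ## untouched reaction keeps its bounds
  expect_equal(bnd(m2, "Other"), c(-10, 10))
  ## reactions the model lacks are warnings, not errors
  expect_equal(length(attr(suppressWarnings(
    applyDirectionalityPreset(m, "aerobic-ecoli")), "preset_missing")), 6)
  expect_warning(applyDirectionalityPreset(m, "aerobic-ecoli"), "SUCOAS")
  ## the empty preset is the identity
  m3 <- applyDirectionalityPreset(m, "none")
  expect_equal(reactions(m3), reactions(m))
  expect_error(applyDirectionalityPreset(m, "no-such"), "registered presets")
})

test_that("basal transporters are added only where needed", {
  tab <- data.frame(
    rxn_id = c("T1", "T1", "R1", "R1"),
    metabolite_id = c("a_e", "a_c", "a_c", "b_c"),
    coeff = c(-1, 1, -1, 1),
    lb = 0, ub = 10, subsystem = "s",
    kind = c("transport", "transport", "enzymatic", "enzymatic"),
    dG0 = NA, dG0_err = NA)
  m <- makeModel("basal", tab)
  m2 <- addBasalTransporters(m)
  ## a_c is already transported, b_c gets a basal transporter at 1e-6
  expect_false("TransFlux_a_c" %in% reactionIds(m2))
  expect_true("TransFlux_b_c" %in% reactionIds(m2))
  expect_equal(reactions(m2)$lb[reactions(m2)$id == "TransFlux_b_c"], 1e-6)
  ## excluded metabolites (highly polar / very large) are skipped
  m3 <- addBasalTransporters(m, excluded = "b_c")
  expect_equal(reactionIds(m3), reactionIds(m))
})
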