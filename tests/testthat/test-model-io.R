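write_rxn_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".rxn",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("reaction grammar parses substrates, products, arrows, bounds, gpr", {
  path <- write_rxn_lines(c(
    "# comment",
    "GS2\tchl_GLU + chl_NH3 + chl_ATP -> chl_GLN + chl_ADP + chl_Pi\t0\t1000\tnitrogen\tGLN1;2",
    "R1\t2 chl_ALA -> chl_PBG + 2 chl_WATER\t0\t1000",
    "R2\tcyt_A <> cyt_B"))
  m <- read_model(path)
  gs2 <- m$reactions[[1]]
  expect_equal(sum(gs2$stoich < 0), 3)
  expect_equal(sum(gs2$stoich > 0), 3)
  expect_false(gs2$reversible)
  expect_identical(gs2$gpr, "GLN1;2")
  r1 <- m$reactions[[2]]
  expect_equal(r1$stoich[["chl_ALA"]], -2)
  expect_equal(r1$stoich[["chl_PBG"]], 1)
  expect_equal(r1$stoich[["chl_WATER"]], 2)
  r2 <- m$reactions[[3]]
  expect_true(r2$reversible)
  expect_lt(r2$lb, 0)
  expect_equal(r2$ub, 1000)
})

test_that("parse errors carry line numbers; unknown prefixes warn", {
  expect_error(read_model(write_rxn_lines("R1\tcyt_A = cyt_B")),
               "line 1.*arrow")
  expect_error(read_model(write_rxn_lines(c("R1\tcyt_A -> cyt_B",
                                            "R1\tcyt_B -> cyt_A"))),
               "line 2.*duplicate")
  expect_error(read_model(write_rxn_lines("R1\ttwo. cyt_A -> cyt_B")),
               "coefficient")
  expect_warning(m <- read_model(write_rxn_lines("R1\tweird_A -> cyt_B")),
                 "unknown compartment.*cytosol")
  expect_identical(m$metabolites[[1]]$compartment, "cytosol")
})

test_that("format round-trip preserves S, bounds, reversibility and gprs", {
  m <- build_leaf_fixture()
  path <- withr::local_tempfile(fileext = ".rxn")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(build_stoichiometric_matrix(m2),
               build_stoichiometric_matrix(m))
  expect_identical(vapply(m2$reactions, `[[`, 0, "lb"),
                   vapply(m$reactions, `[[`, 0, "lb"))
  expect_identical(vapply(m2$reactions, `[[`, 0, "ub"),
                   vapply(m$reactions, `[[`, 0, "ub"))
  expect_identical(vapply(m2$reactions, `[[`, "", "gpr"),
                   vapply(m$reactions, `[[`, "", "gpr"))
  ## second serialisation is byte-identical
  path2 <- withr::local_tempfile(fileext = ".rxn")
  write_model(m2, path2)
  expect_identical(readLines(path2), readLines(path))
  ## rational coefficients survive exactly
  j <- match("mit_ETC", rxn_ids(m2))
  expect_identical(m2$reactions[[j]]$stoich[["cyt_ATP"]], 2.5)
})

test_that("the shipped fixture file equals the programmatic fixture", {
  shipped <- read_model(system.file("extdata", "rice_leaf.rxn",
                                    package = "chlorofba"))
  built <- build_leaf_fixture()
  expect_equal(build_stoichiometric_matrix(shipped),
               build_stoichiometric_matrix(built))
  expect_identical(rxn_ids(shipped), rxn_ids(built))
})

test_that("empty model writes a header-only file", {
  m <- metabolic_model(list(), list())
  path <- withr::local_tempfile(fileext = ".rxn")
  write_model(m, path)
  expect_true(all(startsWith(readLines(path), "#")))
})

sbml_chain <- function() {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="chain"><listOfCompartments>',
    '<compartment id="cytosol"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="cytosol"/>',
    '<species id="B" compartment="cytosol"/>',
    '<species id="Aext" compartment="cytosol" boundaryCondition="true"/>',
    '<species id="Bext" compartment="cytosol" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="imp" reversible="false"><listOfReactants>',
    '<speciesReference species="Aext"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A"/></listOfProducts></reaction>',
    '<reaction id="step" reversible="false"><listOfReactants>',
    '<speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts></reaction>',
    '<reaction id="exp" reversible="false"><listOfReactants>',
    '<speciesReference species="B"/></listOfReactants>',
    '<listOfProducts><speciesReference species="Bext"/></listOfProducts></reaction>',
    '</listOfReactions></model></sbml>')
}

test_that("SBML import: species, boundary conditions, default bounds", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_chain(), path)
  m <- import_sbml(path)
  expect_identical(nrow(build_stoichiometric_matrix(m)), 2L)  # boundary excluded
  expect_true(all(vapply(m$reactions, `[[`, 0, "lb") == 0))
  expect_true(all(vapply(m$reactions, `[[`, 0, "ub") == 1000))
  ## same FBA optimum as the equivalent native-format chain
  s_sbml <- minimize_total_flux(m, fixed = c(exp = 1))
  s_rxn <- minimize_total_flux(toy_chain(), fixed = c(exp = 1))
  expect_equal(s_sbml$objective, s_rxn$objective, tolerance = 1e-9)
  expect_error(import_sbml(write_rxn_lines("not xml")), "SBML import error")
})
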