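test_that("every chain reaction is essential; diamond branches are not", {
  dsc <- scenario("unit-demand", fixed = c(exp = 1))
  chain <- reaction_deletion_scan(toy_chain(), dsc,
                                  candidates = rxn_ids(toy_chain()))
  expect_setequal(chain$report$verdict, "essential")

  dia <- reaction_deletion_scan(toy_diamond(), dsc,
                                candidates = rxn_ids(toy_diamond()))
  ess <- dia$report$reaction[dia$report$verdict == "essential"]
  expect_setequal(ess, c("imp", "exp"))
  expect_identical(dia$counts$n_essential, 2L)
})

test_that("deletion scan matches constructed truth and the brute-force oracle", {
  skip_if_not_installed("pracma")
  for (m in synthetic_cases(100)) {
    dsc <- scenario("unit-demand", fixed = c(exp = 1))
    scan <- reaction_deletion_scan(m, dsc, candidates = rxn_ids(m))
    found <- sort(scan$report$reaction[scan$report$verdict == "essential"])
    expect_identical(found, sort(attr(m, "essential_truth")))
    oracle <- sort(oracle_essential_set(m, fixed = c(exp = 1)))
    expect_identical(found, oracle)
  }
})

test_that("unknown candidates are reported and the scan continues", {
  dsc <- scenario("unit-demand", fixed = c(exp = 1))
  scan <- reaction_deletion_scan(toy_chain(), dsc,
                                 candidates = c("step", "ghost"))
  expect_identical(scan$errors, "ghost")
  expect_identical(scan$report$reaction, "step")
})

test_that("the scan leaves the model untouched", {
  m <- build_leaf_fixture()
  before <- serialize(m, NULL)
  invisible(reaction_deletion_scan(m, leaf_scenario("case1"),
                                   candidates = c("chl_GS2", "cyt_GS1")))
  expect_identical(serialize(m, NULL), before)
})

test_that("GS2 essentiality toggles with the ammonia diffusion route", {
  m <- build_leaf_fixture()
  off <- reaction_deletion_scan(m, leaf_scenario("case1"),
                                candidates = "chl_GS2")
  expect_identical(off$report$verdict, "essential")
  on <- reaction_deletion_scan(m, leaf_scenario("case1", diffusion = TRUE),
                               candidates = "chl_GS2")
  expect_identical(on$report$verdict, "non-essential")
})

test_that("reactions pinned nonzero by relaxed FVA are deletion-essential", {
  m <- build_leaf_fixture()
  sc <- leaf_scenario("case1")
  fva <- classify_by_variability(run_fva(m, sc, relaxation = 1.5))
  implied <- fva$reaction[fva$implied_essential]
  scan <- reaction_deletion_scan(m, sc)
  ess <- scan$report$reaction[scan$report$verdict == "essential"]
  expect_true(all(implied %in% ess))
})

test_that("gene deletions respect AND/OR semantics", {
  mets <- list(metabolite("cyt_A", compartment = "cytosol"),
               metabolite("cyt_B", compartment = "cytosol"),
               metabolite("cyt_C", compartment = "cytosol"),
               metabolite("x_A", compartment = "external"),
               metabolite("x_C", compartment = "external"))
  rxns <- list(
    reaction("imp", c(x_A = -1, cyt_A = 1)),
    reaction("iso", c(cyt_A = -1, cyt_B = 1), gpr = "g1 OR g2"),
    reaction("cplx", c(cyt_B = -1, cyt_C = 1), gpr = "g3 AND g4"),
    reaction("exp", c(cyt_C = -1, x_C = 1)))
  m <- metabolic_model(mets, rxns)
  dsc <- scenario("unit-demand", fixed = c(exp = 1))
  rep <- gene_deletion_scan(m, dsc)$report
  verdict <- setNames(rep$verdict, rep$gene)
  expect_identical(unname(verdict[c("g1", "g2")]),
                   c("non-essential", "non-essential"))   # OR: one isozyme left
  expect_identical(unname(verdict[c("g3", "g4")]),
                   c("essential", "essential"))           # AND: subunit loss closes
  expect_setequal(gene_deletion_scan(m, dsc)$no_gpr_reactions,
                  c("imp", "exp"))
})

test_that("fixture gene verdicts are consistent with reaction verdicts", {
  m <- build_leaf_fixture()
  sc <- leaf_scenario("case1")
  rscan <- reaction_deletion_scan(m, sc, all_reactions = TRUE)
  rv <- setNames(rscan$report$verdict, rscan$report$reaction)
  gscan <- gene_deletion_scan(m, sc)$report
  ## single-gene single-reaction associations must mirror their reaction
  gprs <- setNames(vapply(m$reactions, `[[`, "", "gpr"), rxn_ids(m))
  for (id in names(gprs)[nzchar(gprs)]) {
    genes <- gpr_genes(gprs[[id]])
    tree <- parse_gpr(gprs[[id]])
    if (length(genes) == 1L ||
        (is.list(tree) && tree$op == "AND" &&
         all(vapply(tree$args, is.character, NA)))) {
      ## any single knockout closes this reaction
      carried <- sum(gprs == gprs[[id]])  # isoforms shared across reactions
      if (carried == 1L) {
        for (g in genes) {
          expect_identical(gscan$verdict[gscan$gene == g], unname(rv[id]),
                           label = paste("gene", g, "vs reaction", id))
        }
      }
    }
  }
})

test_that("malformed gene associations fail at parse time", {
  expect_error(parse_gpr("g1 AND (g2 OR"), "malformed gpr")
  expect_error(parse_gpr("AND g1"), "malformed gpr")
  expect_true(eval_gpr("g1 AND (g2 OR g3)", knocked = "g2"))
  expect_false(eval_gpr("g1 AND (g2 OR g3)", knocked = c("g2", "g3")))
  expect_true(is.na(eval_gpr("")))
})

test_that("active pathway extraction groups by compartment and transporter", {
  m <- toy_chain()
  s <- minimize_total_flux(m, fixed = c(exp = 1))
  pw <- extract_active_pathway(s, m)
  expect_identical(pw$counts$total, 3L)
  expect_identical(pw$counts$transporters, 2L)
  expect_equal(unname(pw$counts$by_compartment["cytosol"]), 1L,
               ignore_attr = TRUE)
  bad <- minimize_total_flux(m, fixed = c(exp = 1), blocked = "step")
  expect_error(extract_active_pathway(bad, m), "infeasible")
})

test_that("the case-1 pathway engages the expected machinery", {
  m <- build_leaf_fixture()
  s <- solve_scenario(m, leaf_scenario("case1"))
  pw <- extract_active_pathway(s, m)
  need <- c("cyt_SHMT", "cyt_MTHFR", "cyt_MS", "cyt_SAMS", "cyt_AHC",
            "chl_GS2", "chl_GOGAT", "chl_Mal2OG_tx", "chl_MalGlu_tx",
            "chl_SAM_T1", "chl_AdoHcy_T2", "chl_MalOAA_tx")
  expect_true(all(need %in% pw$pathway$reaction))
  ## no peroxisomal activity without the oxygenase
  expect_false(any(grepl("^per_", pw$pathway$reaction)))
})
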