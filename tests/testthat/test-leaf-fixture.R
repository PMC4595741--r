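test_that("the fixture is structurally clean and nitrogen-balanced", {
  m <- build_leaf_fixture()
  rep <- check_structural_consistency(m)
  expect_identical(nrow(rep$dead_ends), 0L)
  expect_length(rep$orphans, 0)
  audit <- nitrogen_audit(m)
  expect_setequal(audit$status, "balanced")
})

test_that("chlorophyll carries 4 N and its export is the only nitrogen sink", {
  m <- build_leaf_fixture()
  natoms <- setNames(vapply(m$metabolites, `[[`, 0, "n_atoms"), met_ids(m))
  expect_identical(unname(natoms["chl_CHLA"]), 4)
  ## net nitrogen crossing the external boundary, per reaction
  ext <- met_ids(m)[met_external(m)]
  for (r in m$reactions) {
    ext_in <- names(r$stoich) %in% ext
    if (!any(ext_in)) next
    n_flux <- sum(r$stoich[ext_in] * natoms[names(r$stoich)[ext_in]])
    if (r$id == "chlorophyll_tx") {
      expect_equal(n_flux, 4)                       # the sink
    } else if (r$id %in% c("NH_3__tx", "ex_ammonia_tx")) {
      expect_equal(n_flux, -1)                      # the sources
    } else {
      expect_equal(n_flux, 0, label = r$id)         # nitrogen-free exchange
    }
  }
})

test_that("a corrupted stoichiometry is caught by the nitrogen audit", {
  m <- build_leaf_fixture()
  j <- match("chl_GS2", rxn_ids(m))
  m$reactions[[j]]$stoich[["chl_NH3"]] <- -2       # double ammonia uptake
  audit <- nitrogen_audit(m)
  expect_identical(audit$status[audit$reaction == "chl_GS2"], "imbalanced")
  audit2 <- nitrogen_audit(build_leaf_fixture(),
                           atoms = c(chl_GLN = NA_real_))
  expect_true("missing-annotation" %in%
                audit2$status[audit2$reaction == "chl_GS2"])
})

test_that("case-1 optimum reproduces the pinned nitrogen and C1 fluxes", {
  m <- build_leaf_fixture()
  s <- solve_scenario(m, leaf_scenario("case1"))
  expect_identical(s$status, "optimal")
  v <- s$fluxes
  expect_equal(unname(v["chl_GluToALA"]), 8, tolerance = 1e-6)
  expect_equal(unname(v["mit_GDC"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(v["mit_SHMT"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(v["chl_HMBS"]) * 4, 4, tolerance = 1e-6)
  expect_equal(unname(v["chl_GOGAT"]), 8.5, tolerance = 1e-6)
  expect_equal(unname(v["chl_Mal2OG_tx"]), 8.5, tolerance = 1e-6)
  ## GS1 + GS2 fix 8.5 units: 4 imported + 4 from HMB synthase + 0.5 GDC
  expect_equal(unname(v["chl_GS2"] + v["cyt_GS1"]), 8.5, tolerance = 1e-6)
})

test_that("case 2 is feasible and strictly costlier than case 1", {
  m <- build_leaf_fixture()
  s1 <- solve_scenario(m, leaf_scenario("case1"))
  s2 <- solve_scenario(m, leaf_scenario("case2"))
  expect_identical(s2$status, "optimal")
  expect_gt(s2$objective, s1$objective)
  expect_gt(unname(s2$fluxes["photon_tx"]), unname(s1$fluxes["photon_tx"]))
  ## Vc/Vo honoured
  expect_equal(unname(s2$fluxes["chl_RBC_carb"] / s2$fluxes["chl_RBC_oxy"]),
               3, tolerance = 1e-6)
})

test_that("synthetic generator honours declared sizes and truth", {
  ## pure chain: every reaction essential by construction
  m1 <- generate_synthetic_network(4, 5, n_parallel_paths = 1, seed = 2)
  expect_length(m1$reactions, 5)
  expect_setequal(attr(m1, "essential_truth"), rxn_ids(m1))
  ## one duplicated stage: its branches are the only non-essentials
  m2 <- generate_synthetic_network(3, 5, n_parallel_paths = 2, seed = 2)
  truth <- attr(m2, "essential_truth")
  nonessential <- setdiff(rxn_ids(m2), truth)
  expect_length(nonessential, 2)
  expect_length(unique(sub("_b[0-9]+$", "", nonessential)), 1)
  ## reproducible per seed
  a <- generate_synthetic_network(5, 9, 3, seed = 7)
  b <- generate_synthetic_network(5, 9, 3, seed = 7)
  expect_identical(build_stoichiometric_matrix(a),
                   build_stoichiometric_matrix(b))
  expect_identical(vapply(a$reactions, `[[`, 0, "lb"),
                   vapply(b$reactions, `[[`, 0, "lb"))
})

test_that("impossible synthetic sizes are rejected", {
  expect_error(generate_synthetic_network(4, 3, 1, seed = 1), "impossible")
  expect_error(generate_synthetic_network(4, 6, 1, seed = 1), "impossible")
  expect_error(generate_synthetic_network(1, 4, 2, seed = 1), "impossible")
  expect_error(generate_synthetic_network(3, 99, 2, seed = 1), "impossible")
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_synthetic_network(4, 7, 2, seed = 99))
  expect_identical(runif(1), before)
})
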