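test_that("simplex solves, detects infeasibility and unboundedness", {
  ## min x s.t. x >= 2  (as -x <= -2)
  r <- simplex_solve(1, NULL, NULL, Ale = rbind(-1), ble = -2)
  expect_identical(r$status, "optimal")
  expect_equal(r$objective, 2)
  expect_identical(simplex_solve(1, rbind(1), -1)$status, "infeasible")
  expect_identical(simplex_solve(1, NULL, NULL, maximize = TRUE)$status,
                   "unbounded")
})

test_that("degenerate alternate optima have a unique objective", {
  ## diamond: branch split is ambiguous, total flux is not
  m <- toy_diamond()
  z <- replicate(3, minimize_total_flux(m, fixed = c(exp = 1))$objective)
  expect_equal(z, rep(3, 3))
})

test_that("chain with unit demand costs one unit per step", {
  s <- minimize_total_flux(toy_chain(), fixed = c(exp = 1))
  expect_identical(s$status, "optimal")
  expect_equal(s$objective, 3)
  expect_equal(unname(s$fluxes), rep(1, 3))
  expect_lte(s$max_residual, 1e-6)
  expect_setequal(s$active_support, c("imp", "step", "exp"))
})

test_that("ratio coupling forces the 3:1 route split and composes with blocks", {
  m <- toy_two_routes()
  rc <- list(ratio_constraint("Vc", "Vo", 3))
  s <- minimize_total_flux(m, fixed = c(demand = 1), ratios = rc)
  expect_equal(unname(s$fluxes["Vc"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(s$fluxes["Vo"]), 0.25, tolerance = 1e-9)
  ## blocking the coupled partner forces both to zero: demand infeasible
  s2 <- minimize_total_flux(m, fixed = c(demand = 1), ratios = rc,
                            blocked = "Vo")
  expect_identical(s2$status, "infeasible")
  expect_error(minimize_total_flux(m, ratios = list(
    ratio_constraint("Vc", "nope", 3))), "unknown")
})

test_that("fixed fluxes outside bounds and unknown blocks are rejected", {
  m <- toy_chain()
  expect_error(minimize_total_flux(m, fixed = c(step = -1)),
               "outside bounds")
  expect_error(minimize_total_flux(m, blocked = "nope"), "unknown")
})

test_that("objective never decreases as constraints are added", {
  for (s in c(3, 17, 41)) {
    m <- generate_synthetic_network(4, 7, n_parallel_paths = 2, seed = s)
    free <- minimize_total_flux(m, fixed = c(exp = 1))
    harder <- minimize_total_flux(m, fixed = c(exp = 1, imp = 1))
    expect_gte(harder$objective, free$objective - 1e-9)
    branch <- grep("stage", rxn_ids(m), value = TRUE)[1]
    blocked <- minimize_total_flux(m, fixed = c(exp = 1), blocked = branch)
    if (blocked$status == "optimal") {
      expect_gte(blocked$objective, free$objective - 1e-9)
    }
  }
})

test_that("no reaction carries simultaneous forward and backward flux", {
  ## at a total-flux optimum |v| summed equals the objective exactly,
  ## which fails if any split pair is simultaneously active
  m <- build_leaf_fixture()
  s <- solve_scenario(m, leaf_scenario("case1"))
  expect_equal(sum(abs(s$fluxes)), s$objective, tolerance = 1e-6)
})

test_that("both LP backends agree on small problems", {
  skip_if_not_installed("pracma")
  cases <- list(list(m = toy_chain(), demand = "exp"),
                list(m = toy_diamond(), demand = "exp"),
                list(m = toy_two_routes(), demand = "demand"),
                list(m = generate_synthetic_network(4, 8, 3, seed = 9),
                     demand = "exp"))
  for (cs in cases) {
    lp <- build_flux_lp(cs$m, fixed = setNames(1, cs$demand))
    a <- solve_lp(lp, backend = "simplex")
    b <- solve_lp(lp, backend = "pracma")
    expect_identical(a$status, "optimal")
    expect_identical(b$status, "optimal")
    ## the objective is unique even where the optimal vertex is not
    expect_equal(a$objective, b$objective, tolerance = 1e-6)
    S <- build_stoichiometric_matrix(cs$m)
    expect_lte(max(abs(S %*% b$fluxes)), 1e-6)
  }
  ## on a single-route network the flux vectors themselves must agree
  lp <- build_flux_lp(toy_chain(), fixed = c(exp = 1))
  expect_equal(solve_lp(lp, backend = "simplex")$fluxes,
               solve_lp(lp, backend = "pracma")$fluxes, tolerance = 1e-6)
})

test_that("flux minimisation matches the brute-force orthant oracle", {
  skip_if_not_installed("pracma")
  n_failed <- 0
  for (m in synthetic_cases(100)) {
    s <- minimize_total_flux(m, fixed = c(exp = 1))
    o <- oracle_min_total_flux(m, fixed = c(exp = 1))
    n_failed <- n_failed + o$n_failed
    expect_identical(s$status, "optimal")
    expect_identical(o$status, "optimal")
    expect_equal(s$objective, o$objective, tolerance = 1e-6)
    expect_lte(s$max_residual, 1e-6)
  }
  expect_identical(n_failed, 0)
})

test_that("without coupling the flux-minimal leaf solution shuns the oxygenase", {
  m <- build_leaf_fixture()
  s <- minimize_total_flux(m, fixed = c(chlorophyll_tx = 1))
  expect_identical(s$status, "optimal")
  expect_equal(unname(s$fluxes["chl_RBC_oxy"]), 0, tolerance = 1e-9)
})
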