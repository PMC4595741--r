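#' Declarative scenario: a named set of constraint edits
#'
#' A scenario bundles fixed fluxes, blocked reactions, ratio couplings
#' and bound overrides (e.g. reopening the zero-bounded chloroplast to
#' cytosol ammonia diffusion) so that an experimental condition can be
#' applied to a model reproducibly.
#'
#' @param name Scenario name.
#' @param fixed Named numeric vector of fixed fluxes.
#' @param blocked Character vector of reaction ids forced to zero.
#' @param ratios List of [ratio_constraint()] objects.
#' @param bounds Named list of `c(lb, ub)` bound overrides.
#' @return An object of class `cfba_scenario`.
#' @export
scenario <- function(name, fixed = NULL, blocked = character(0),
                     ratios = list(), bounds = list()) {
  structure(list(name = name, fixed = fixed, blocked = blocked,
                 ratios = ratios, bounds = bounds),
            class = "cfba_scenario")
}

#' Bundled scenarios for the leaf fixture
#'
#' Chlorophyll export is fixed at 1.0 flux unit in every bundled
#' scenario. `case1` blocks the Rubisco oxygenase (carboxylase-only
#' metabolism); `case2` couples carboxylase:oxygenase at Vc/Vo = 3
#' (normal air). `diffusion = TRUE` reopens the chloroplast-to-cytosol
#' ammonia diffusion reaction, otherwise bounded to zero.
#'
#' @param case `"case1"` or `"case2"`.
#' @param diffusion Allow chloroplastic ammonia to diffuse to the
#'   cytosol.
#' @param demand Chlorophyll export flux (default 1.0).
#' @return A `cfba_scenario`.
#' @export
leaf_scenario <- function(case = c("case1", "case2"), diffusion = FALSE,
                          demand = 1) {
  case <- match.arg(case)
  sc <- scenario(
    name = paste0(case, if (diffusion) "-diffusion"),
    fixed = c(chlorophyll_tx = demand),
    blocked = if (case == "case1") "chl_RBC_oxy" else character(0),
    ratios = if (case == "case2") {
      list(ratio_constraint("chl_RBC_carb", "chl_RBC_oxy", 3))
    } else list(),
    bounds = if (diffusion) list(am_diff_tx = c(0, 1000)) else list())
  sc
}

#' Apply a scenario's bound overrides to a model
#'
#' Fixed fluxes, blocks and ratios are handled at the LP level by
#' [solve_scenario()]; this applies only the bound edits.
#'
#' @param model A `cfba_model`.
#' @param sc A `cfba_scenario`.
#' @return The edited model.
#' @export
apply_scenario <- function(model, sc) {
  stopifnot(inherits(sc, "cfba_scenario"))
  for (id in names(sc$bounds)) {
    model <- set_bounds(model, id, lb = sc$bounds[[id]][1],
                        ub = sc$bounds[[id]][2])
  }
  model
}

#' Solve the flux-minimisation problem under a scenario
#'
#' @param model A `cfba_model`.
#' @param sc A `cfba_scenario`.
#' @param extra_fixed Additional fixed fluxes layered on top of the
#'   scenario (e.g. a grid point of the ammonia scan).
#' @param extra_blocked Additional blocked reactions (e.g. a deletion
#'   probe).
#' @param backend LP backend.
#' @return A `cfba_solution`.
#' @export
solve_scenario <- function(model, sc, extra_fixed = NULL,
                           extra_blocked = NULL,
                           backend = c("simplex", "pracma")) {
  backend <- match.arg(backend)
  model <- apply_scenario(model, sc)
  fixed <- sc$fixed
  if (!is.null(extra_fixed)) {
    fixed <- c(fixed[setdiff(names(fixed), names(extra_fixed))], extra_fixed)
  }
  minimize_total_flux(model, fixed = fixed, ratios = sc$ratios,
                      blocked = unique(c(sc$blocked, extra_blocked)),
                      backend = backend)
}

#' Ammonia-transporter scan
#'
#' Fixes the chloroplastic ammonia importer (`ex_ammonia_tx`) at each
#' grid value in turn, re-minimises the total flux, and records the
#' fluxes of the transporters and enzymes whose interplay the scan
#' probes: the cytosolic importer, GS1/GS2, the Glu-Gln and Mal-2OG (and
#' Mal-Glu) shuttles, GOGAT, and the mitochondrial GDC/SHMT/ammonia
#' export. Infeasible grid points are reported and the scan continues.
#'
#' @param model The leaf fixture (or any model with the same reaction
#'   ids).
#' @param case `"case1"` or `"case2"`.
#' @param grid Chloroplastic importer values (flux units).
#' @param diffusion Allow chloroplast-to-cytosol ammonia diffusion.
#' @param backend LP backend.
#' @return data.frame, one row per grid point, class `cfba_scan`.
#' @export
run_ammonia_scan <- function(model, case = c("case1", "case2"),
                             grid = 0:4, diffusion = FALSE,
                             backend = c("simplex", "pracma")) {
  case <- match.arg(case)
  backend <- match.arg(backend)
  sc <- leaf_scenario(case, diffusion = diffusion)
  cols <- c(cyt_importer = "NH_3__tx", GS1 = "cyt_GS1", GS2 = "chl_GS2",
            glu_gln_shuttle = "chl_GluGln_tx", mal_2og_shuttle = "chl_Mal2OG_tx",
            mal_glu_shuttle = "chl_MalGlu_tx", GOGAT = "chl_GOGAT",
            mit_ammonia_export = "mit_am_tx", GDC = "mit_GDC",
            SHMT = "mit_SHMT")
  rows <- lapply(grid, function(a) {
    s <- solve_scenario(model, sc, extra_fixed = c(ex_ammonia_tx = a),
                        backend = backend)
    if (s$status != "optimal") {
      out <- as.list(setNames(rep(NA_real_, length(cols)), names(cols)))
      data.frame(chl_importer = a, status = s$status, total_flux = NA_real_,
                 out, stringsAsFactors = FALSE)
    } else {
      data.frame(chl_importer = a, status = "optimal",
                 total_flux = s$objective,
                 as.list(setNames(unname(s$fluxes[cols]), names(cols))),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cfba_scan", class(out))
  attr(out, "case") <- case
  out
}

#' Chloroplastic glutamine synthetase experiment
#'
#' Reproduces the GS2 analysis: with diffusion of chloroplastic ammonia
#' disabled, GS2 is the only fate of the ammonia released by the
#' tetrapyrrole branch plus the mitochondrial import, so it is active and
#' its deletion is infeasible; with diffusion enabled a flux-minimal
#' solution with inactive GS2 exists and the deletion becomes feasible.
#'
#' @param model The leaf fixture.
#' @param diffusion_enabled Allow chloroplast-to-cytosol ammonia
#'   diffusion.
#' @param case `"case1"` or `"case2"`.
#' @param backend LP backend.
#' @return List: scenario status, GS2 flux, ammonia released by the
#'   PBG-to-HMB step, mitochondrial ammonia import, total chloroplastic
#'   ammonia, diffusion flux, and whether GS2 deletion is infeasible
#'   (`gs2_essential`).
#' @export
run_gs2_experiment <- function(model, diffusion_enabled = FALSE,
                               case = c("case1", "case2"),
                               backend = c("simplex", "pracma")) {
  case <- match.arg(case)
  backend <- match.arg(backend)
  sc <- leaf_scenario(case, diffusion = diffusion_enabled)
  base <- solve_scenario(model, sc, backend = backend)
  if (base$status != "optimal") {
    stop("GS2 experiment: scenario ", sc$name, " is ", base$status)
  }
  hmbs_nh3 <- unname(base$fluxes["chl_HMBS"]) *
    model$reactions[[rxn_index(model, "chl_HMBS")]]$stoich[["chl_NH3"]]
  del <- solve_scenario(model, sc, extra_blocked = "chl_GS2",
                        backend = backend)
  list(case = case,
       diffusion_enabled = diffusion_enabled,
       status = base$status,
       gs2_flux = unname(base$fluxes["chl_GS2"]),
       hmbs_ammonia = hmbs_nh3,
       mit_ammonia_import = unname(base$fluxes["mit_am_tx"]),
       chloroplastic_ammonia = hmbs_nh3 + unname(base$fluxes["mit_am_tx"]),
       diffusion_flux = unname(base$fluxes["am_diff_tx"]),
       gs2_essential = del$status != "optimal")
}

#' Contrast carboxylase-only and photorespiring metabolism
#'
#' Solves case 1 and case 2 on the same model and tabulates the
#' quantities the two conditions separate: photon demand, total flux,
#' peroxisomal engagement, the Mal-2OG and Mal-Glu shuttles, and the
#' mitochondrial GDC/SHMT/ammonia fluxes.
#'
#' @param model The leaf fixture.
#' @param backend LP backend.
#' @return data.frame with one row per quantity and columns `case1`,
#'   `case2`.
#' @export
compare_cases <- function(model, backend = c("simplex", "pracma")) {
  backend <- match.arg(backend)
  sols <- lapply(c("case1", "case2"), function(case) {
    s <- solve_scenario(model, leaf_scenario(case), backend = backend)
    if (s$status != "optimal") stop(case, " is ", s$status)
    s
  })
  per_rxns <- rxn_ids(model)[vapply(model$reactions, function(r) {
    any(met_compartment_of(model, names(r$stoich)) == "peroxisome")
  }, NA)]
  grab <- function(s, id) unname(s$fluxes[id])
  quantity <- c("photon_flux", "total_flux", "support_size",
                "peroxisomal_active", "mal_2og_shuttle", "mal_glu_shuttle",
                "GDC", "SHMT", "mit_ammonia_export", "cyclic_light",
                "cyt_importer", "chl_importer")
  val <- function(s) c(grab(s, "photon_tx"), s$objective,
                       length(s$active_support),
                       sum(abs(s$fluxes[per_rxns]) > 1e-9),
                       grab(s, "chl_Mal2OG_tx"), grab(s, "chl_MalGlu_tx"),
                       grab(s, "mit_GDC"), grab(s, "mit_SHMT"),
                       grab(s, "mit_am_tx"), grab(s, "chl_LightCyclic"),
                       grab(s, "NH_3__tx"), grab(s, "ex_ammonia_tx"))
  data.frame(quantity = quantity, case1 = val(sols[[1]]),
             case2 = val(sols[[2]]), stringsAsFactors = FALSE)
}

#' Load scenario definitions from a YAML config file
#'
#' Each entry may define `fixed` (map), `blocked` (list), `ratios`
#' (list of `{a, b, r}` maps) and `bounds` (map id -> [lb, ub]).
#'
#' @param path YAML file; defaults to the bundled scenario file.
#' @return Named list of `cfba_scenario` objects.
#' @export
load_scenarios <- function(path = system.file("extdata", "scenarios.yaml",
                                              package = "chlorofba")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    scenario(nm,
             fixed = if (!is.null(e$fixed)) unlist(e$fixed),
             blocked = as.character(unlist(e$blocked)),
             ratios = lapply(e$ratios, function(r) {
               ratio_constraint(r$a, r$b, r$r)
             }),
             bounds = lapply(e$bounds, as.numeric))
  })
  names(out) <- names(raw)
  out
}
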