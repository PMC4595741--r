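#' Flux variability analysis at strict or relaxed optimum
#'
#' First minimises the total absolute flux under the scenario, then, with
#' the summed absolute flux bounded by `relaxation` times that optimum,
#' minimises and maximises every reaction's net flux. At `relaxation = 1`
#' the budget equals the optimum itself; on a network with a unique
#' flux-minimal solution every reaction is then pinned at its FBA value.
#'
#' @param model A `cfba_model`.
#' @param scenario Optional `cfba_scenario`; `NULL` analyses the bare
#'   model (no fixed demand).
#' @param relaxation Objective relaxation factor (>= 1), e.g. 1.5 or 2.
#' @param reactions Reaction ids to analyse (default: all).
#' @param backend LP backend.
#' @return data.frame (class `cfba_fva`) with `reaction`, `fva_min`,
#'   `fba_val`, `fva_max`; attributes `objective_bound` and `relaxation`.
#' @export
run_fva <- function(model, scenario = NULL, relaxation = 1,
                    reactions = NULL,
                    backend = c("simplex", "pracma")) {
  backend <- match.arg(backend)
  stopifnot(relaxation >= 1)
  if (is.null(scenario)) scenario <- scenario("free")
  base <- solve_scenario(model, scenario, backend = backend)
  if (base$status != "optimal") {
    stop("FVA: scenario '", scenario$name, "' is ", base$status,
         "; no per-reaction analysis possible")
  }
  model_sc <- apply_scenario(model, scenario)
  lp <- build_flux_lp(model_sc, fixed = scenario$fixed,
                      ratios = scenario$ratios, blocked = scenario$blocked)
  budget <- relaxation * base$objective + 1e-7
  lp <- add_total_flux_budget(lp, budget)
  ids <- if (is.null(reactions)) rxn_ids(model) else reactions
  rxn_index(model, ids)   # validate
  res <- lapply(ids, function(id) {
    j <- match(id, lp$rxn_ids)
    obj <- numeric(length(lp$var_rxn))
    sel <- lp$var_rxn == j
    obj[sel] <- lp$var_sign[sel]
    if (!any(sel)) {                      # reaction pinned to zero by bounds
      return(data.frame(reaction = id, fva_min = 0,
                        fba_val = unname(base$fluxes[id]), fva_max = 0,
                        stringsAsFactors = FALSE))
    }
    lo <- solve_lp(lp, objective = obj, maximize = FALSE, backend = backend)
    hi <- solve_lp(lp, objective = obj, maximize = TRUE, backend = backend)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem for '", id, "' returned ", lo$status, "/", hi$status)
    }
    ## recover the net flux of reaction j at each vertex
    data.frame(reaction = id,
               fva_min = unname(lo$fluxes[id]),
               fba_val = unname(base$fluxes[id]),
               fva_max = unname(hi$fluxes[id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("cfba_fva", class(out))
  attr(out, "objective_bound") <- budget
  attr(out, "relaxation") <- relaxation
  attr(out, "scenario") <- scenario$name
  out
}

#' Partition reactions by their flux variability
#'
#' Classes follow the variability patterns of relaxed-optimum FVA:
#' `pinned` (fva_min = fba_val = fva_max), `essential_bounded`
#' (the range cannot reach zero, or is pinned at the FBA value on one
#' side with a nonzero value), and `variable` (fva_min < fba_val <
#' fva_max; irreversible reactions reach fva_min = 0, reversible ones may
#' have fva_min < 0). Reactions whose allowable range excludes zero are
#' flagged `implied_essential`: they cannot be switched off within the
#' relaxed flux budget, so the deletion scan must find them essential.
#'
#' @param fva A `cfba_fva` from [run_fva()].
#' @param tol Values closer than this are treated as equal.
#' @return The input with `class` and `implied_essential` columns.
#' @export
classify_by_variability <- function(fva, tol = 1e-6) {
  stopifnot(inherits(fva, "cfba_fva"))
  cls <- character(nrow(fva))
  for (i in seq_len(nrow(fva))) {
    lo <- fva$fva_min[i]; mid <- fva$fba_val[i]; hi <- fva$fva_max[i]
    cls[i] <- if (hi - lo <= tol) {
      "pinned"
    } else if (lo > tol || hi < -tol) {
      "essential_bounded"
    } else if ((abs(lo - mid) <= tol && mid > tol) ||
               (abs(hi - mid) <= tol && mid < -tol)) {
      "essential_bounded"
    } else {
      "variable"
    }
  }
  fva$class <- cls
  fva$implied_essential <- (fva$fva_min > tol) | (fva$fva_max < -tol)
  fva
}
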