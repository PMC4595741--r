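#' Single-reaction deletion scan
#'
#' For each candidate reaction, forces its flux to zero (both directions
#' for reversible reactions) and re-tests feasibility of the scenario's
#' fixed demand. A reaction is essential exactly when the deletion LP is
#' infeasible — the strict no-solution-space criterion, not a reduced
#' optimum. The model is never modified; each probe builds its own LP.
#'
#' @param model A `cfba_model`.
#' @param scenario A `cfba_scenario` (must be feasible without
#'   deletions).
#' @param candidates Reaction ids to probe; defaults to the active
#'   support of the scenario's flux-minimal optimum (the predicted
#'   pathway), mirroring how deletion scans are scoped in practice. Use
#'   `candidates = rxn_ids(model)` wrapped via `all_reactions = TRUE` to
#'   scan everything.
#' @param all_reactions Scan every reaction instead of the active
#'   pathway.
#' @param backend LP backend.
#' @return Object of class `cfba_essentiality`: data.frame `report`
#'   (reaction, verdict, status, compartment, is_transporter), aggregate
#'   `counts`, and `errors` (unknown candidate ids).
#' @export
reaction_deletion_scan <- function(model, scenario, candidates = NULL,
                                   all_reactions = FALSE,
                                   backend = c("simplex", "pracma")) {
  backend <- match.arg(backend)
  stopifnot(inherits(scenario, "cfba_scenario"))
  base <- solve_scenario(model, scenario, backend = backend)
  if (base$status != "optimal") {
    stop("deletion scan: scenario '", scenario$name, "' is ", base$status,
         " before any deletion")
  }
  if (is.null(candidates)) {
    candidates <- if (all_reactions) rxn_ids(model) else base$active_support
  }
  unknown <- setdiff(candidates, rxn_ids(model))
  candidates <- setdiff(candidates, unknown)
  comp <- rxn_compartments(model)
  names(comp) <- rxn_ids(model)
  is_tx <- vapply(model$reactions, `[[`, NA, "is_transporter")
  names(is_tx) <- rxn_ids(model)
  rows <- lapply(candidates, function(id) {
    fixed_val <- scenario$fixed[id]
    if (!is.na(fixed_val) && abs(fixed_val) > 1e-12) {
      ## deleting a reaction whose flux the scenario fixes nonzero is
      ## infeasible by construction
      status <- "infeasible"
    } else {
      s <- solve_scenario(model, scenario, extra_blocked = id,
                          backend = backend)
      status <- s$status
    }
    data.frame(reaction = id,
               verdict = if (status == "optimal") "non-essential" else "essential",
               status = status,
               compartment = unname(comp[id]),
               is_transporter = unname(is_tx[id]),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ess <- report[report$verdict == "essential", ]
  counts <- list(
    n_tested = nrow(report),
    n_essential = nrow(ess),
    by_compartment = table(ess$compartment),
    transporters = sum(ess$is_transporter))
  structure(list(report = report, counts = counts, errors = unknown,
                 scenario = scenario$name),
            class = "cfba_essentiality")
}

#' @export
print.cfba_essentiality <- function(x, ...) {
  cat("<cfba_essentiality> scenario ", x$scenario, ": ",
      x$counts$n_essential, " essential of ", x$counts$n_tested,
      " tested (", x$counts$transporters, " transporters)\n", sep = "")
  if (length(x$errors)) cat("  unknown ids:", paste(x$errors, collapse = ", "), "\n")
  invisible(x)
}

#' Gene-level deletion scan through gene associations
#'
#' Every gene referenced by any gene association is knocked out in turn;
#' all reactions whose association then evaluates false are blocked
#' simultaneously and feasibility of the scenario demand is re-tested.
#' Reactions without gene data are never blocked, so genes absent from
#' all associations can never be called essential.
#'
#' @param model A `cfba_model` with at least one gene association.
#' @param scenario A `cfba_scenario`.
#' @param genes Genes to test (default: all genes in the model).
#' @param backend LP backend.
#' @return List with data.frame `report` (gene, n_reactions_disabled,
#'   verdict, status) and `no_gpr_reactions` (ids without gene data).
#' @export
gene_deletion_scan <- function(model, scenario, genes = NULL,
                               backend = c("simplex", "pracma")) {
  backend <- match.arg(backend)
  gprs <- vapply(model$reactions, `[[`, "", "gpr")
  names(gprs) <- rxn_ids(model)
  trees <- lapply(gprs, parse_gpr)     # malformed gprs error here, not mid-scan
  if (!any(!vapply(trees, is.null, NA))) {
    stop("gene deletion scan requires at least one gene association")
  }
  if (is.null(genes)) genes <- model_genes(model)
  rows <- lapply(genes, function(g) {
    disabled <- names(trees)[vapply(trees, function(tr) {
      !is.null(tr) && !isTRUE(eval_gpr(tr, knocked = g))
    }, NA)]
    if (!length(disabled)) {
      status <- "optimal"
    } else {
      s <- solve_scenario(model, scenario, extra_blocked = disabled,
                          backend = backend)
      status <- s$status
    }
    data.frame(gene = g, n_reactions_disabled = length(disabled),
               verdict = if (status == "optimal") "non-essential" else "essential",
               status = status, stringsAsFactors = FALSE)
  })
  list(report = do.call(rbind, rows),
       no_gpr_reactions = names(gprs)[!nzchar(gprs)])
}

#' Extract the active pathway from a flux solution
#'
#' Lists the reactions carrying flux above the support tolerance,
#' grouped the way pathway sizes are reported: per-compartment counts
#' for reactions confined to one compartment, with inter-compartment
#' transporters counted as their own group.
#'
#' @param solution An optimal `cfba_solution`.
#' @param model The model it was solved on.
#' @param support_tol Magnitude threshold for activity.
#' @return List with data.frame `pathway` (reaction, flux, compartment,
#'   is_transporter, subsystem) and `counts` (by compartment,
#'   transporters, total).
#' @export
extract_active_pathway <- function(solution, model, support_tol = 1e-9) {
  stopifnot(inherits(solution, "cfba_solution"))
  if (solution$status != "optimal") {
    stop("no pathway can be extracted from a solution with status '",
         solution$status, "'")
  }
  v <- solution$fluxes
  act <- names(v)[abs(v) > support_tol]
  idx <- rxn_index(model, act)
  comp <- rxn_compartments(model)[idx]
  is_tx <- vapply(model$reactions[idx], `[[`, NA, "is_transporter")
  df <- data.frame(reaction = act, flux = unname(v[act]), compartment = comp,
                   is_transporter = is_tx,
                   subsystem = vapply(model$reactions[idx], `[[`, "", "subsystem"),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  by_comp <- table(df$compartment[!df$is_transporter])
  list(pathway = df,
       counts = list(by_compartment = by_comp,
                     transporters = sum(df$is_transporter),
                     total = nrow(df)))
}
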