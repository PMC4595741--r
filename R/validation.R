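#' Energy and redox conservation (leak) test
#'
#' Closes every exchange with the external space (bounds to zero) and
#' then maximises the flux through a transient dissipation sink for each
#' probe couple (ATP to ADP + Pi, NADPH to NADP, NADH to NAD, per
#' compartment where the couple exists). In a conserved network nothing
#' can regenerate the charged species once the inputs are closed, so the
#' maximal sink flux is zero; a nonzero maximum exposes an erroneous
#' energy-generating cycle. All reaction bounds are honoured during the
#' probe maximisation, so a leak reports the (finite) cycle capacity.
#'
#' @param model A `cfba_model`.
#' @param probes Optional list of probes, each
#'   `list(id =, consume = named coefs, produce = named coefs)`;
#'   defaults to ATP/NADPH/NADH couples discovered per compartment.
#' @param leak_tol Flux above which a probe is declared leaking.
#' @param backend LP backend.
#' @return Object of class `cfba_leak`: data.frame `report` (probe,
#'   max_flux, verdict) and logical `conserved`.
#' @export
energy_redox_leak_test <- function(model, probes = NULL, leak_tol = 1e-6,
                                   backend = c("simplex", "pracma")) {
  backend <- match.arg(backend)
  mids <- met_ids(model)
  ext <- mids[met_external(model)]
  ## close every exchange
  closed <- model
  for (j in seq_along(closed$reactions)) {
    if (any(names(closed$reactions[[j]]$stoich) %in% ext)) {
      closed$reactions[[j]]$lb <- 0
      closed$reactions[[j]]$ub <- 0
      closed$reactions[[j]]$reversible <- FALSE
    }
  }
  if (is.null(probes)) probes <- default_leak_probes(model)
  if (!length(probes)) stop("no probe couples found in the model")
  rows <- lapply(probes, function(pr) {
    st <- c(-pr$consume, pr$produce)
    sink <- reaction(pr$id, st, lb = 0, ub = 1000, subsystem = "probe")
    probed <- closed
    probed$reactions <- c(probed$reactions, list(sink))
    probed <- validate_model(probed)
    lp <- build_flux_lp(probed, inf_bound = Inf)
    j <- match(pr$id, lp$rxn_ids)
    obj <- numeric(length(lp$var_rxn))
    sel <- lp$var_rxn == j
    obj[sel] <- lp$var_sign[sel]
    res <- solve_lp(lp, objective = obj, maximize = TRUE, backend = backend)
    mx <- if (res$status == "optimal") res$objective else Inf
    data.frame(probe = pr$id, max_flux = mx,
               verdict = if (mx <= leak_tol) "conserved" else "leaking",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  structure(list(report = report, conserved = all(report$verdict == "conserved")),
            class = "cfba_leak")
}

#' @export
print.cfba_leak <- function(x, ...) {
  cat("<cfba_leak> ", if (x$conserved) "conserved" else "LEAKING", "\n", sep = "")
  print(x$report)
  invisible(x)
}

default_leak_probes <- function(model) {
  mids <- met_ids(model)
  couples <- list(c("ATP", "ADP"), c("NADPH", "NADP"), c("NADH", "NAD"))
  probes <- list()
  for (pre in c("cyt", "chl", "mit", "per")) {
    for (cp in couples) {
      hi <- paste0(pre, "_", cp[1])
      lo <- paste0(pre, "_", cp[2])
      if (hi %in% mids && lo %in% mids) {
        consume <- setNames(1, hi)
        produce <- setNames(1, lo)
        if (cp[1] == "ATP" && paste0(pre, "_Pi") %in% mids) {
          produce <- c(produce, setNames(1, paste0(pre, "_Pi")))
          if (paste0(pre, "_H2O") %in% mids) {
            consume <- c(consume, setNames(1, paste0(pre, "_H2O")))
          }
        }
        probes[[length(probes) + 1L]] <-
          list(id = paste0("probe_", pre, "_", cp[1]),
               consume = consume, produce = produce)
      }
    }
  }
  probes
}

#' Audit a flux solution against the model
#'
#' Recomputes the steady-state residual for every internal metabolite
#' and checks every flux against its bounds (closed interval; a flux
#' exactly at a bound is not a violation).
#'
#' @param solution An optimal `cfba_solution`.
#' @param model The model it was solved on.
#' @param tol Residual / bound tolerance.
#' @return List with `max_residual`, named `residuals`, and data.frame
#'   `violations` (empty when the solution is clean).
#' @export
audit_solution <- function(solution, model, tol = 1e-6) {
  stopifnot(inherits(solution, "cfba_solution"))
  if (solution$status != "optimal") stop("cannot audit a non-optimal solution")
  S <- build_stoichiometric_matrix(model)
  v <- solution$fluxes[colnames(S)]
  resid <- as.vector(S %*% v)
  names(resid) <- rownames(S)
  lb <- rxn_lb(model); ub <- rxn_ub(model)
  bad <- which(v < lb - tol | v > ub + tol)
  violations <- data.frame(reaction = names(v)[bad], flux = unname(v[bad]),
                           lb = lb[bad], ub = ub[bad],
                           stringsAsFactors = FALSE)
  list(max_residual = if (length(resid)) max(abs(resid)) else 0,
       residuals = resid, violations = violations)
}
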