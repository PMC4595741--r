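#' Flux-minimising flux balance analysis
#'
#' Solves the parsimonious FBA problem: minimise the summed
#' absolute flux (the economy of the enzymic machinery) subject to the
#' steady-state balance `S v = 0`, reaction bounds, fixed fluxes, ratio
#' couplings and blocked reactions. Infeasibility of a fixed demand is
#' meaningful: it is the essentiality criterion used by
#' [reaction_deletion_scan()].
#'
#' @param model A `cfba_model`.
#' @param fixed Named numeric vector of fixed fluxes (e.g.
#'   `c(chlorophyll_tx = 1)`).
#' @param ratios List of [ratio_constraint()] objects.
#' @param blocked Character vector of reaction ids forced to zero.
#' @param backend LP backend passed to [solve_lp()].
#' @param support_tol Fluxes with magnitude above this belong to the
#'   active support.
#' @param balance_tol Permitted steady-state residual.
#' @return An object of class `cfba_solution`: `status`, objective `Z`
#'   (total absolute flux), named `fluxes`, `active_support`, and the
#'   maximal mass-balance residual.
#' @export
minimize_total_flux <- function(model, fixed = NULL, ratios = NULL,
                                blocked = NULL,
                                backend = c("simplex", "pracma"),
                                support_tol = 1e-9, balance_tol = 1e-6) {
  backend <- match.arg(backend)
  lp <- build_flux_lp(model, fixed = fixed, ratios = ratios,
                      blocked = blocked)
  res <- solve_lp(lp, backend = backend)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective = NA_real_,
                          fluxes = NULL, active_support = character(0),
                          max_residual = NA_real_, model_id = model$id),
                     class = "cfba_solution"))
  }
  v <- res$fluxes
  S <- build_stoichiometric_matrix(model)
  resid <- if (nrow(S)) max(abs(S %*% v)) else 0
  if (resid > balance_tol) {
    warning("steady-state residual ", format(resid), " exceeds balance_tol")
  }
  structure(list(status = "optimal", objective = res$objective,
                 fluxes = v,
                 active_support = names(v)[abs(v) > support_tol],
                 max_residual = resid, model_id = model$id),
            class = "cfba_solution")
}

#' @export
print.cfba_solution <- function(x, ...) {
  cat("<cfba_solution> model ", x$model_id, ": status ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", Z = ", format(x$objective),
        ", |support| = ", length(x$active_support),
        ", max |S v| = ", format(x$max_residual), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tabulate a flux solution
#'
#' @param x A `cfba_solution`.
#' @param ... Unused.
#' @return data.frame with reaction id and net flux (model order).
#' @export
as.data.frame.cfba_solution <- function(x, ...) {
  if (x$status != "optimal") stop("no flux vector: solution status is ", x$status)
  data.frame(reaction = names(x$fluxes), flux = unname(x$fluxes),
             stringsAsFactors = FALSE)
}
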