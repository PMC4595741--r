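## Translation of a metabolic model plus scenario constraints into a
## nonnegative-variable linear program.
##
## Every reaction is split into forward and backward half-variables
## (v = p - n, p,n >= 0), which linearises |v| exactly: at any optimum of
## min sum(p + n) the two halves are never simultaneously active.

INF_BOUND <- 1000

#' Ratio coupling between two reactions
#'
#' Adds the equality `v_a - ratio * v_b = 0` to a flux problem, e.g. the
#' Rubisco carboxylase:oxygenase coupling Vc/Vo = 3.
#'
#' @param reaction_a,reaction_b Reaction ids.
#' @param ratio Positive dimensionless ratio, `v_a = ratio * v_b`.
#' @return An object of class `cfba_ratio`.
#' @export
ratio_constraint <- function(reaction_a, reaction_b, ratio) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0)
  structure(list(a = reaction_a, b = reaction_b, r = as.numeric(ratio)),
            class = "cfba_ratio")
}

#' Build the flux linear program for a model
#'
#' Constructs the split-variable LP: steady-state rows `S v = 0` over the
#' internal metabolites, equality rows for fixed fluxes and ratio
#' couplings, and inequality rows for genuinely finite bounds. Bounds
#' whose magnitude reaches `inf_bound` play the role of "unbounded"
#' (the conventional 1000 flux-unit default).
#'
#' @param model A `cfba_model`.
#' @param fixed Named numeric vector of fixed fluxes (reaction id ->
#'   value), enforced as equality rows.
#' @param ratios List of [ratio_constraint()] objects.
#' @param blocked Character vector of reaction ids forced to zero flux.
#' @param inf_bound Magnitude from which a bound is treated as infinite.
#' @return An object of class `cfba_lp` holding the constraint blocks and
#'   the variable-to-reaction mapping.
#' @export
build_flux_lp <- function(model, fixed = NULL, ratios = NULL,
                          blocked = NULL, inf_bound = INF_BOUND) {
  validate_model(model)
  rids <- rxn_ids(model)
  nr <- length(rids)
  lb <- rxn_lb(model)
  ub <- rxn_ub(model)
  if (!is.null(blocked) && length(blocked)) {
    idx <- rxn_index(model, blocked, "blocked reaction")
    lb[idx] <- 0
    ub[idx] <- 0
  }
  if (!is.null(fixed) && length(fixed)) {
    idx <- rxn_index(model, names(fixed), "fixed reaction")
    bad <- fixed < lb[idx] - 1e-9 | fixed > ub[idx] + 1e-9
    if (any(bad)) {
      stop("fixed flux outside bounds for: ",
           paste(names(fixed)[bad], collapse = ", "))
    }
  }

  ## half-variables
  var_rxn <- integer(0)
  var_sign <- numeric(0)
  for (j in seq_len(nr)) {
    if (ub[j] > 0) { var_rxn <- c(var_rxn, j); var_sign <- c(var_sign, 1) }
    if (lb[j] < 0) { var_rxn <- c(var_rxn, j); var_sign <- c(var_sign, -1) }
  }
  nv <- length(var_rxn)

  S <- build_stoichiometric_matrix(model)
  A <- matrix(0, nrow(S), nv)
  for (k in seq_len(nv)) A[, k] <- var_sign[k] * S[, var_rxn[k]]
  rownames(A) <- rownames(S)
  b <- numeric(nrow(S))

  net_row <- function(j) {
    row <- numeric(nv)
    sel <- var_rxn == j
    row[sel] <- var_sign[sel]
    row
  }

  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      A <- rbind(A, net_row(rxn_index(model, nm)))
      b <- c(b, fixed[[nm]])
    }
  }
  if (!is.null(ratios)) {
    for (rc in ratios) {
      stopifnot(inherits(rc, "cfba_ratio"))
      ia <- rxn_index(model, rc$a, "ratio reaction")
      ib <- rxn_index(model, rc$b, "ratio reaction")
      A <- rbind(A, net_row(ia) - rc$r * net_row(ib))
      b <- c(b, 0)
    }
  }

  ## finite-bound inequality rows
  Ale <- NULL; ble <- numeric(0)
  add_le <- function(row, rhs) {
    Ale <<- rbind(Ale, row); ble <<- c(ble, rhs)
  }
  for (j in seq_len(nr)) {
    if (ub[j] > 0 && ub[j] < inf_bound) add_le(pmax(net_row(j), 0), ub[j])
    if (lb[j] < 0 && lb[j] > -inf_bound) add_le(pmax(-net_row(j), 0), -lb[j])
    if (lb[j] > 0) add_le(-net_row(j), -lb[j])
    if (ub[j] < 0) add_le(net_row(j), ub[j])
  }

  structure(list(cvec = rep(1, nv), A = A, b = b, Ale = Ale, ble = ble,
                 var_rxn = var_rxn, var_sign = var_sign,
                 rxn_ids = rids, model_id = model$id),
            class = "cfba_lp")
}

#' Append a ratio-coupling row to an existing flux LP
#'
#' @param lp A `cfba_lp` from [build_flux_lp()].
#' @param rc A [ratio_constraint()].
#' @return The LP with one extra equality row.
#' @export
add_ratio_constraint <- function(lp, rc) {
  stopifnot(inherits(lp, "cfba_lp"), inherits(rc, "cfba_ratio"))
  ia <- match(rc$a, lp$rxn_ids)
  ib <- match(rc$b, lp$rxn_ids)
  if (is.na(ia) || is.na(ib)) {
    stop("unknown reaction id in ratio constraint: ",
         paste(c(rc$a, rc$b)[c(is.na(ia), is.na(ib))], collapse = ", "))
  }
  row <- numeric(length(lp$var_rxn))
  row[lp$var_rxn == ia] <- lp$var_sign[lp$var_rxn == ia]
  row[lp$var_rxn == ib] <- row[lp$var_rxn == ib] -
    rc$r * lp$var_sign[lp$var_rxn == ib]
  lp$A <- rbind(lp$A, row)
  lp$b <- c(lp$b, 0)
  lp
}

#' Add a total-flux budget row (sum of |v| <= budget)
#'
#' Used by flux variability analysis to pin the solution space to the
#' (possibly relaxed) optimum of the flux-minimisation objective.
#'
#' @param lp A `cfba_lp`.
#' @param budget Upper bound on the summed absolute flux.
#' @return The LP with one extra inequality row.
#' @export
add_total_flux_budget <- function(lp, budget) {
  stopifnot(inherits(lp, "cfba_lp"), is.numeric(budget), budget >= 0)
  lp$Ale <- rbind(lp$Ale, rep(1, length(lp$var_rxn)))
  lp$ble <- c(lp$ble, budget)
  lp
}

#' Solve a flux LP
#'
#' Backend-agnostic solve. The `"simplex"` backend is the bundled
#' deterministic two-phase simplex; `"pracma"` delegates to
#' [pracma::linprog()] and serves as an independent cross-check. Both
#' receive the identical constraint blocks and must agree to 1e-6.
#'
#' @param lp A `cfba_lp`.
#' @param objective Optional per-variable objective overriding the
#'   total-flux objective (length = number of split variables).
#' @param maximize Maximize instead of minimize.
#' @param backend `"simplex"` or `"pracma"`.
#' @return List with `status`, `objective`, `x` (split-variable values)
#'   and `fluxes` (named net flux per reaction).
#' @export
solve_lp <- function(lp, objective = NULL, maximize = FALSE,
                     backend = c("simplex", "pracma")) {
  stopifnot(inherits(lp, "cfba_lp"))
  backend <- match.arg(backend)
  cc <- if (is.null(objective)) lp$cvec else objective
  stopifnot(length(cc) == length(lp$var_rxn))
  if (backend == "simplex") {
    res <- simplex_solve(cc, lp$A, lp$b, lp$Ale, lp$ble, maximize = maximize)
  } else {
    if (!requireNamespace("pracma", quietly = TRUE)) {
      stop("backend 'pracma' requires the pracma package")
    }
    pr <- tryCatch(
      suppressWarnings(pracma::linprog(
        cc = if (maximize) -cc else cc,
        A = lp$Ale, b = lp$ble, Aeq = lp$A, beq = lp$b,
        maxiter = 10000)),
      error = function(e) list(errno = -9, message = conditionMessage(e)))
    if (!identical(pr$errno, 1)) {
      status <- if (isTRUE(pr$errno == -2)) {
        "infeasible"
      } else if (isTRUE(pr$errno == -3)) "unbounded" else "failed"
      if (status == "failed") {
        stop("pracma::linprog failed: ", pr$message)
      }
      res <- list(status = status, x = NULL, objective = NA_real_)
    } else {
      res <- list(status = "optimal", x = pr$x, objective = sum(cc * pr$x))
    }
  }
  fluxes <- NULL
  if (res$status == "optimal") {
    fluxes <- recover_net_fluxes(lp, res$x)
  }
  list(status = res$status, objective = res$objective, x = res$x,
       fluxes = fluxes)
}

recover_net_fluxes <- function(lp, x) {
  v <- numeric(length(lp$rxn_ids))
  for (k in seq_along(x)) {
    v[lp$var_rxn[k]] <- v[lp$var_rxn[k]] + lp$var_sign[k] * x[k]
  }
  names(v) <- lp$rxn_ids
  v
}
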