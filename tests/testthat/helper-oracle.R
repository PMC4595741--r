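## Independent brute-force oracles for small networks.
##
## The oracle never uses the package's split-variable LP construction:
## it enumerates sign patterns (orthants) of the reversible reactions,
## rewrites each orthant as a plain nonnegative LP with explicit bound
## rows, and solves it with pracma::linprog. Results are combined across
## orthants.

oracle_orthants <- function(model, blocked = character(0)) {
  rids <- vapply(model$reactions, `[[`, "", "id")
  keep <- !(rids %in% blocked)
  rev <- vapply(model$reactions, `[[`, NA, "reversible") & keep
  k <- sum(rev)
  signs_list <- if (k == 0) list(integer(0)) else
    lapply(seq_len(2^k) - 1, function(x) as.integer(intToBits(x))[seq_len(k)])
  list(rids = rids, keep = keep, rev = which(rev), signs_list = signs_list)
}

## solve one orthant LP: min cc'u (or max) s.t. steady state, fixed rows,
## u <= bound rows, optional total-flux budget
oracle_orthant_lp <- function(model, sigma, keep, fixed = NULL,
                              budget = NULL, obj_rxn = NULL,
                              maximize = FALSE) {
  rids <- vapply(model$reactions, `[[`, "", "id")
  S <- build_stoichiometric_matrix(model)
  idx <- which(keep)
  n <- length(idx)
  Aeq <- S[, idx, drop = FALSE]
  ub_eff <- numeric(n)
  for (k in seq_len(n)) {
    j <- idx[k]
    Aeq[, k] <- Aeq[, k] * sigma[k]
    ub_eff[k] <- if (sigma[k] > 0) model$reactions[[j]]$ub else -model$reactions[[j]]$lb
  }
  beq <- rep(0, nrow(Aeq))
  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      row <- numeric(n)
      k <- match(match(nm, rids), idx)
      if (is.na(k)) {
        if (abs(fixed[[nm]]) > 1e-12) return(list(status = "infeasible"))
        next
      }
      row[k] <- sigma[k]
      Aeq <- rbind(Aeq, row)
      beq <- c(beq, fixed[[nm]])
    }
  }
  A <- diag(n); b <- ub_eff
  if (!is.null(budget)) { A <- rbind(A, rep(1, n)); b <- c(b, budget) }
  cc <- if (is.null(obj_rxn)) rep(1, n) else {
    k <- match(match(obj_rxn, rids), idx)
    v <- numeric(n)
    if (!is.na(k)) v[k] <- sigma[k]
    v
  }
  pr <- tryCatch(
    suppressWarnings(pracma::linprog(if (maximize) -cc else cc,
                                     A = A, b = b, Aeq = Aeq, beq = beq,
                                     maxiter = 2000)),
    error = function(e) list(errno = -99))
  if (isTRUE(pr$errno == 1)) {
    x <- pr$x
  } else if (isTRUE(pr$errno == -2)) {
    return(list(status = "infeasible"))
  } else {
    ## pracma's textbook simplex occasionally hits a singular basis on
    ## degenerate instances; re-solve the identical orthant formulation
    ## (still no variable splitting) with the package solver
    alt <- simplex_solve(cc, Aeq, beq, Ale = A, ble = b, maximize = maximize)
    if (alt$status != "optimal") return(list(status = alt$status))
    x <- alt$x
  }
  obj <- sum(cc * x)    # value under the *original* coefficients
  v <- numeric(length(rids)); names(v) <- rids
  v[idx] <- sigma * x
  list(status = "optimal", objective = obj, fluxes = v)
}

oracle_sigma <- function(orth, keep_idx, bits) {
  sigma <- rep(1, length(keep_idx))
  if (length(orth$rev)) {
    revpos <- match(orth$rev, keep_idx)
    sigma[revpos] <- ifelse(bits > 0, -1, 1)
  }
  sigma
}

## brute-force flux minimisation over all orthants
oracle_min_total_flux <- function(model, fixed = NULL, blocked = character(0)) {
  orth <- oracle_orthants(model, blocked)
  keep_idx <- which(orth$keep)
  best <- NULL; n_failed <- 0
  for (bits in orth$signs_list) {
    sigma <- oracle_sigma(orth, keep_idx, bits)
    r <- oracle_orthant_lp(model, sigma, orth$keep, fixed = fixed)
    if (r$status == "failed") n_failed <- n_failed + 1
    if (r$status == "optimal" &&
        (is.null(best) || r$objective < best$objective - 1e-12)) best <- r
  }
  if (is.null(best)) list(status = "infeasible", n_failed = n_failed)
  else c(best, list(n_failed = n_failed))
}

oracle_feasible <- function(model, fixed = NULL, blocked = character(0)) {
  oracle_min_total_flux(model, fixed, blocked)$status == "optimal"
}

## brute-force essential set for a fixed demand
oracle_essential_set <- function(model, fixed, candidates = NULL) {
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (is.null(candidates)) candidates <- rids
  candidates[vapply(candidates, function(id) {
    if (id %in% names(fixed) && abs(fixed[[id]]) > 1e-12) return(TRUE)
    !oracle_feasible(model, fixed, blocked = id)
  }, NA)]
}

## brute-force FVA range for one reaction under a total-flux budget
oracle_fva_range <- function(model, fixed, rxn, budget) {
  orth <- oracle_orthants(model)
  keep_idx <- which(orth$keep)
  lo <- Inf; hi <- -Inf
  for (bits in orth$signs_list) {
    sigma <- oracle_sigma(orth, keep_idx, bits)
    rmin <- oracle_orthant_lp(model, sigma, orth$keep, fixed = fixed,
                              budget = budget, obj_rxn = rxn)
    rmax <- oracle_orthant_lp(model, sigma, orth$keep, fixed = fixed,
                              budget = budget, obj_rxn = rxn, maximize = TRUE)
    if (rmin$status == "optimal") lo <- min(lo, rmin$objective)
    if (rmax$status == "optimal") hi <- max(hi, rmax$objective)
  }
  c(lo, hi)
}
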