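## Dense two-phase primal simplex.
##
## Solves   min (or max)  c'x
##          s.t.  A  x  =  b
##                Ale x <= ble
##                x >= 0
##
## Deterministic: Dantzig pricing with lowest-index tie-breaks, switching
## to Bland's rule after a fixed iteration budget so cycling on degenerate
## vertices cannot occur. The basis is refactorised (the tableau is
## recomputed from the original constraint matrix) at regular intervals
## and at every phase boundary, which keeps accumulated pivoting error in
## check on long runs. Intended problem sizes are a few hundred rows and
## columns.

#' Solve a linear program in nonnegative standard form
#'
#' Bundled reference LP solver used by the flux engine. Not usually called
#' directly; see [solve_lp()] for the backend-agnostic interface.
#'
#' @param cc Objective coefficient vector (length n).
#' @param A,b Equality block `A x = b` (may have zero rows).
#' @param Ale,ble Optional inequality block `Ale x <= ble`.
#' @param maximize Maximize instead of minimize.
#' @param tol Pivot / feasibility tolerance.
#' @param maxit Total pivot limit.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, `NULL` unless optimal) and `objective`.
#' @export
simplex_solve <- function(cc, A, b, Ale = NULL, ble = NULL,
                          maximize = FALSE, tol = 1e-9, maxit = 50000L) {
  n <- length(cc)
  if (is.null(A)) { A <- matrix(0, 0, n); b <- numeric(0) }
  if (!is.null(Ale) && nrow(Ale) > 0L) {
    nsl <- nrow(Ale)
    Afull <- rbind(cbind(A, matrix(0, nrow(A), nsl)),
                   cbind(Ale, diag(nsl)))
    bfull <- c(b, ble)
  } else {
    nsl <- 0L
    Afull <- A
    bfull <- b
  }
  m <- nrow(Afull)
  ntot <- ncol(Afull)
  if (m == 0L) {
    cobj <- if (maximize) -cc else cc
    if (any(cobj < -tol)) {
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    }
    return(list(status = "optimal", x = numeric(n), objective = 0))
  }
  neg <- bfull < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  bfull[neg] <- -bfull[neg]

  ## original matrix including artificial identity columns
  A0 <- cbind(Afull, diag(m))
  b0 <- bfull
  ncols <- ntot + m
  art <- ntot + seq_len(m)
  basis <- art
  tab <- cbind(A0, b0)
  eligible <- rep(TRUE, ncols)
  rows_keep <- seq_len(m)

  refactor <- function(tab, basis) {
    B <- A0[rows_keep, basis, drop = FALSE]
    out <- tryCatch(solve(B, cbind(A0[rows_keep, , drop = FALSE],
                                   b0[rows_keep])),
                    error = function(e) NULL)
    if (is.null(out)) return(tab)      # keep current tableau if singular
    rhs <- out[, ncols + 1L]
    rhs[rhs < 0 & rhs > -1e-7] <- 0
    out[, ncols + 1L] <- rhs
    out
  }

  run_phase <- function(tab, basis, cost, eligible, iter0) {
    rhs_col <- ncols + 1L
    it <- iter0
    bland_after <- 2000L + 10L * m
    since_refac <- 0L
    repeat {
      it <- it + 1L
      since_refac <- since_refac + 1L
      if (it > maxit) stop("simplex: iteration limit reached")
      if (since_refac >= 60L) {
        tab <- refactor(tab, basis)
        since_refac <- 0L
      }
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% tab[, seq_len(ncols), drop = FALSE])
      red[!eligible] <- Inf
      cand <- which(red < -tol)
      if (!length(cand)) {
        tab <- refactor(tab, basis)
        red <- cost - as.vector(cost[basis] %*% tab[, seq_len(ncols), drop = FALSE])
        red[!eligible] <- Inf
        cand <- which(red < -tol)
        if (!length(cand)) {
          return(list(tab = tab, basis = basis, status = "optimal", iter = it))
        }
      }
      q <- if (it > bland_after) cand[1L] else cand[which.min(red[cand])][1L]
      col <- tab[, q]
      pos <- which(col > tol)
      if (!length(pos)) {
        tab <- refactor(tab, basis)
        col <- tab[, q]
        pos <- which(col > tol)
        if (!length(pos)) {
          return(list(tab = tab, basis = basis, status = "unbounded", iter = it))
        }
      }
      ratios <- tab[pos, rhs_col] / col[pos]
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol]
      p <- ties[which.min(basis[ties])][1L]
      piv <- tab[p, ] / tab[p, q]
      tab <- tab - outer(tab[, q], piv)
      tab[p, ] <- piv
      basis[p] <- q
    }
  }

  ## Phase I: minimise the sum of artificials
  cost1 <- c(rep(0, ntot), rep(1, length(rows_keep)))
  ph1 <- run_phase(tab, basis, cost1, eligible, 0L)
  if (ph1$status != "optimal") stop("simplex: phase I failed unexpectedly")
  tab <- ph1$tab; basis <- ph1$basis
  infeas <- sum(tab[basis > ntot, ncols + 1L])
  if (infeas > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  ## drive residual zero-level artificials out of the basis
  drop_rows <- integer(0)
  for (i in which(basis > ntot)) {
    row <- tab[i, seq_len(ntot)]
    j <- which(abs(row) > 1e-7)[1L]
    if (is.na(j)) {
      drop_rows <- c(drop_rows, i)        # redundant constraint
    } else {
      piv <- tab[i, ] / tab[i, j]
      tab <- tab - outer(tab[, j], piv)
      tab[i, ] <- piv
      basis[i] <- j
    }
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(nrow(tab)), drop_rows)
    tab <- tab[keep, , drop = FALSE]
    basis <- basis[keep]
    rows_keep <- rows_keep[keep]
  }
  eligible[art] <- FALSE

  ## Phase II
  cost2 <- c(if (maximize) -cc else cc, rep(0, nsl), rep(0, m))
  ph2 <- run_phase(tab, basis, cost2, eligible, ph1$iter)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  tab <- ph2$tab; basis <- ph2$basis
  x <- numeric(ncols)
  x[basis] <- tab[, ncols + 1L]
  x[x < 0 & x > -1e-9] <- 0
  xout <- x[seq_len(n)]
  obj <- sum(cc * xout)
  list(status = "optimal", x = xout, objective = obj)
}
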