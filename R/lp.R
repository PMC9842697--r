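#' Solve a box-constrained linear program
#'
#' Dense two-phase primal simplex for problems of the form
#' maximise (or minimise) \eqn{c'v} subject to \eqn{S v = b} and
#' \eqn{lb \le v \le ub}. This is the solver behind [run_fba()] and
#' [run_fva()]; metabolic LPs are small (tens of reactions), so a dense
#' tableau with Bland's anti-cycling rule is both adequate and fully
#' deterministic.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param S constraint matrix (`m` x `n`); may be dense or anything
#'   coercible with `as.matrix()`.
#' @param b right-hand side, length `m` (default all zero, the
#'   steady-state case).
#' @param lb,ub variable bounds, length `n`, all finite.
#' @param maximize logical; minimise when `FALSE`.
#' @param tol pivot tolerance.
#'
#' @return list with `status` (`"optimal"` or `"infeasible"`),
#'   `objective`, and `x` (primal solution, length `n`). Box bounds make
#'   unboundedness impossible; it is still reported as a status
#'   defensively.
#' @export
solve_lp <- function(obj, S, b = NULL, lb, ub, maximize = TRUE, tol = 1e-9) {
  S <- as.matrix(S)
  m <- nrow(S)
  n <- ncol(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (is.null(b)) b <- rep(0, m)
  stopifnot(length(b) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp() requires finite bounds; use a large box for open bounds")
  if (any(lb > ub + 1e-12))
    stop("lower bound exceeds upper bound")

  ## shift x = v - lb so x >= 0; add slack rows x_j + s_j = u_j
  u <- ub - lb
  beq <- as.numeric(b - S %*% lb)
  sense <- if (maximize) 1 else -1
  cx <- sense * obj

  ## tableau columns: n structural | n bound slacks | m artificials
  ## rows: m equality rows (sign-normalised) then n bound rows
  sgn <- ifelse(beq < 0, -1, 1)
  Teq <- cbind(S * sgn, matrix(0, m, n), diag(m))
  Tub <- cbind(diag(n), diag(n), matrix(0, n, m))
  Tab <- rbind(Teq, Tub)
  rhs <- c(abs(beq), u)
  basis <- c(2L * n + seq_len(m), n + seq_len(n))

  ncols <- 2L * n + m
  res <- .simplex_iterate(Tab, rhs, basis,
                          cost = c(rep(0, 2L * n), rep(-1, m)), tol = tol)
  Tab <- res$Tab; rhs <- res$rhs; basis <- res$basis
  if (res$status != "optimal" || res$objective < -1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))

  ## drive lingering zero-level artificials out of the basis
  art <- which(basis > 2L * n)
  keep_rows <- rep(TRUE, nrow(Tab))
  for (i in art) {
    piv <- which(abs(Tab[i, seq_len(2L * n)]) > 1e-8)
    if (length(piv)) {
      j <- piv[1L]
      res2 <- .simplex_pivot(Tab, rhs, basis, i, j)
      Tab <- res2$Tab; rhs <- res2$rhs; basis <- res2$basis
    } else {
      keep_rows[i] <- FALSE          # redundant constraint row
    }
  }
  Tab <- Tab[keep_rows, , drop = FALSE]
  rhs <- rhs[keep_rows]
  basis <- basis[keep_rows]
  Tab <- Tab[, seq_len(2L * n), drop = FALSE]   # drop artificial columns

  res <- .simplex_iterate(Tab, rhs, basis, cost = c(cx, rep(0, n)), tol = tol)
  if (res$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  x <- rep(0, n)
  hit <- res$basis <= n
  x[res$basis[hit]] <- res$rhs[hit]
  v <- x + lb
  list(status = "optimal", objective = sum(obj * v), x = v)
}

## One simplex phase on an explicit tableau, maximising `cost`.
## Bland's rule throughout: entering = lowest-index improving column,
## leaving = lowest basis index among minimum ratios. Guarantees finite
## termination on the degenerate LPs that FVA produces.
.simplex_iterate <- function(Tab, rhs, basis, cost, tol = 1e-9,
                             max_iter = 100000L) {
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    red <- as.numeric(crossprod(cb, Tab)) - cost
    enter <- which(red < -tol)
    if (!length(enter)) {
      return(list(status = "optimal", Tab = Tab, rhs = rhs, basis = basis,
                  objective = sum(cb * rhs)))
    }
    j <- enter[1L]
    col <- Tab[, j]
    ok <- col > tol
    if (!any(ok))
      return(list(status = "unbounded", Tab = Tab, rhs = rhs, basis = basis,
                  objective = Inf))
    ratio <- rhs[ok] / col[ok]
    rmin <- min(ratio)
    cand <- which(ok)[ratio <= rmin + 1e-12]
    i <- cand[which.min(basis[cand])]
    res <- .simplex_pivot(Tab, rhs, basis, i, j)
    Tab <- res$Tab; rhs <- res$rhs; basis <- res$basis
  }
  stop("simplex failed to terminate")
}

.simplex_pivot <- function(Tab, rhs, basis, i, j) {
  piv <- Tab[i, j]
  Tab[i, ] <- Tab[i, ] / piv
  rhs[i] <- rhs[i] / piv
  other <- setdiff(seq_len(nrow(Tab)), i)
  fac <- Tab[other, j]
  Tab[other, ] <- Tab[other, , drop = FALSE] - outer(fac, Tab[i, ])
  rhs[other] <- rhs[other] - fac * rhs[i]
  Tab[, j] <- 0; Tab[i, j] <- 1
  basis[i] <- j
  list(Tab = Tab, rhs = rhs, basis = basis)
}
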