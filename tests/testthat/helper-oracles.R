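# Independent oracles used to certify the computational kernels.
# These deliberately share no code with the implementations they check.

# Exhaustive vertex enumeration over {S v = b, lb <= v <= ub}: every
# vertex is a basic solution with n - rank(S) variables at a bound and
# the rest solved from the equality system. Exponential, so only for
# networks with <= 8 reactions.
oracle_lp <- function(obj, S, b = NULL, lb, ub, maximize = TRUE,
                      tol = 1e-7) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(b)) b <- rep(0, nrow(S))
  r <- qr(S)$rank
  k <- n - r
  best <- NULL
  consider <- function(v) {
    if (all(v >= lb - tol) && all(v <= ub + tol)) {
      z <- sum(obj * v)
      if (is.null(best) || (maximize && z > best) || (!maximize && z < best))
        best <<- z
    }
  }
  if (k == 0) {
    v <- qr.solve(S, b)
    consider(v)
    return(best)
  }
  sets <- utils::combn(n, k)
  signs <- as.matrix(expand.grid(rep(list(c(1, 2)), k)))
  for (ci in seq_len(ncol(sets))) {
    Fix <- sets[, ci]
    Afree <- S[, -Fix, drop = FALSE]
    qa <- qr(Afree)
    if (qa$rank < n - k) next
    for (si in seq_len(nrow(signs))) {
      vF <- ifelse(signs[si, ] == 1, lb[Fix], ub[Fix])
      rhs <- b - S[, Fix, drop = FALSE] %*% vF
      vfree <- tryCatch(qr.coef(qa, rhs), error = function(e) NULL)
      if (is.null(vfree) || anyNA(vfree)) next
      if (max(abs(Afree %*% vfree - rhs)) > tol) next
      v <- numeric(n)
      v[Fix] <- vF
      v[-Fix] <- vfree
      consider(v)
    }
  }
  best
}

oracle_fba_objective <- function(model) {
  S <- model_matrix(model)
  bounds <- model_bounds(model)
  obj <- as.numeric(names(model$reactions) == model$objective)
  oracle_lp(obj, S, lb = bounds[, "lb"], ub = bounds[, "ub"])
}

# FVA oracle at objective fraction 1: vertex enumeration over the
# optimal face {S v = 0, c'v = z*}.
oracle_fva_range <- function(model, reaction, z_opt) {
  S <- model_matrix(model)
  bounds <- model_bounds(model)
  cvec <- as.numeric(names(model$reactions) == model$objective)
  S2 <- rbind(S, cvec)
  b2 <- c(rep(0, nrow(S)), z_opt)
  e <- as.numeric(names(model$reactions) == reaction)
  c(oracle_lp(e, S2, b2, bounds[, "lb"], bounds[, "ub"], maximize = FALSE),
    oracle_lp(e, S2, b2, bounds[, "lb"], bounds[, "ub"], maximize = TRUE))
}

# Memoised textbook recursion for DTW (symmetric step, absolute cost).
oracle_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- abs(x[i] - y[j])
    v <- if (i == 1 && j == 1) cost
    else cost + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# Per-window quadratic least-squares derivative via lm(), for checking
# the MRI filter.
oracle_window_slope <- function(y, idx, centre, dt) {
  x <- (idx - centre) * dt
  unname(stats::coef(stats::lm(y[idx] ~ x + I(x^2)))[2])
}
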