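# Dense two-phase simplex for small flux-balance linear programs.
#
# The preinstalled stack has no LP package, and every model this package
# solves is desk-scale (tens of reactions), so a plain tableau simplex with
# Bland's anti-cycling rule is adequate and fully reproducible. Variables
# must have finite bounds (FBA bounds default to +/-1000, so this is never a
# restriction in practice).

#' Solve a small dense linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `mat %*% x (dir) rhs` and
#' `lb <= x <= ub`, using a two-phase tableau simplex with Bland's rule.
#' Intended for flux-balance problems with tens of variables; all bounds must
#' be finite.
#'
#' @param obj numeric objective coefficients, length n.
#' @param mat constraint matrix (m x n); may have zero rows (m = 0).
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `">="`, `"="`.
#' @param rhs numeric right-hand sides, length m.
#' @param lb,ub finite variable bounds, length n.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @param maxit iteration cap across both phases.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objval` and solution `x` (NA-filled unless optimal).
#' @keywords internal
lp_solve <- function(obj, mat, dir, rhs, lb, ub,
                     maximize = TRUE, tol = 1e-9, maxit = 100000L) {
  n <- length(obj)
  if (is.null(mat)) mat <- matrix(0, 0L, n)
  mat <- matrix(as.numeric(mat), nrow = length(rhs), ncol = n)
  stopifnot(length(dir) == length(rhs), length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))

  # Shift x = lb + y, y in [0, ub - lb]; fold upper bounds in as <= rows.
  span <- ub - lb
  b0 <- rhs - as.vector(mat %*% lb)
  A <- rbind(mat, diag(1, n))
  d <- c(dir, rep("<=", n))
  b <- c(b0, span)

  m <- nrow(A)
  # Slack/surplus columns for inequality rows.
  ineq <- which(d != "=")
  ns <- length(ineq)
  S <- matrix(0, m, ns)
  for (k in seq_len(ns)) S[ineq[k], k] <- if (d[ineq[k]] == "<=") 1 else -1
  A <- cbind(A, S)
  # Normalize to b >= 0.
  neg <- which(b < 0)
  if (length(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  nv <- ncol(A)
  # Artificials for every row: trivially valid identity start basis.
  A <- cbind(A, diag(1, m))
  basis <- nv + seq_len(m)

  cost1 <- c(rep(0, nv), rep(1, m))
  ph1 <- simplex_iterate(A, b, cost1, basis, tol, maxit)
  if (ph1$status != "optimal")
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  if (sum(cost1[ph1$basis] * ph1$b) > 1e-7)
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  A <- ph1$A; b <- ph1$b; basis <- ph1$basis

  # Pivot any degenerate artificial out of the basis; drop redundant rows.
  art <- which(basis > nv)
  drop_rows <- integer(0)
  for (i in art) {
    row <- A[i, seq_len(nv)]
    j <- which(abs(row) > tol)[1]
    if (is.na(j)) { drop_rows <- c(drop_rows, i); next }
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv; b[i] <- b[i] / piv
    oth <- setdiff(seq_len(nrow(A)), i)
    f <- A[oth, j]
    A[oth, ] <- A[oth, , drop = FALSE] - outer(f, A[i, ])
    b[oth] <- b[oth] - f * b[i]
    basis[i] <- j
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(nrow(A)), drop_rows)
    A <- A[keep, , drop = FALSE]; b <- b[keep]; basis <- basis[keep]
  }
  A <- A[, seq_len(nv), drop = FALSE]

  cost2 <- c(if (maximize) -obj else obj, rep(0, nv - n))
  ph2 <- simplex_iterate(A, b, cost2, basis, tol, maxit)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", objval = NA_real_, x = rep(NA_real_, n)))
  if (ph2$status != "optimal")
    stop("lp_solve: iteration limit reached")

  y <- numeric(nv)
  y[ph2$basis] <- ph2$b
  x <- lb + y[seq_len(n)]
  objval <- sum(obj * x)
  list(status = "optimal", objval = objval, x = x)
}

# One simplex phase on tableau (A | b) with Bland's rule.
# Assumes A[, basis] is (a permuted) identity and b >= 0.
simplex_iterate <- function(A, b, cost, basis, tol, maxit) {
  m <- nrow(A)
  if (m == 0L) return(list(status = "optimal", A = A, b = b, basis = basis))
  for (iter in seq_len(maxit)) {
    red <- cost - as.vector(crossprod(A, cost[basis]))
    red[basis] <- 0
    ent <- which(red < -1e-9)
    if (!length(ent))
      return(list(status = "optimal", A = A, b = b, basis = basis))
    j <- ent[1L]                       # Bland: lowest entering index
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])]  # Bland: lowest leaving basis index
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    oth <- setdiff(seq_len(m), i)
    f <- A[oth, j]
    A[oth, ] <- A[oth, , drop = FALSE] - outer(f, A[i, ])
    b[oth] <- b[oth] - f * b[i]
    b[b < 0 & b > -tol] <- 0
    basis[i] <- j
  }
  list(status = "maxit")
}
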