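# Independent brute-force LP oracle: enumerate candidate vertices as the
# solutions of every n-subset of constraint hyperplanes (equality rows,
# inequality rows, variable bounds), keep the feasible ones, and take the
# best objective. All variables are box-bounded, so a nonempty feasible
# region has a vertex and the enumeration is exhaustive.
bf_lp_max <- function(obj, mat, dir, rhs, lb, ub, tol = 1e-7) {
  n <- length(obj)
  if (is.null(mat)) mat <- matrix(0, 0, n)
  A <- rbind(mat, diag(1, n), diag(1, n))
  b <- c(rhs, lb, ub)
  type <- c(dir, rep(">=", n), rep("<=", n))
  ncon <- nrow(A)
  feasible <- function(x) {
    lhs <- as.vector(A[seq_along(rhs), , drop = FALSE] %*% x)
    ok <- TRUE
    if (length(rhs)) {
      for (i in seq_along(rhs)) {
        ok <- ok && switch(dir[i],
          "="  = abs(lhs[i] - rhs[i]) <= tol,
          "<=" = lhs[i] <= rhs[i] + tol,
          ">=" = lhs[i] >= rhs[i] - tol)
      }
    }
    ok && all(x >= lb - tol) && all(x <= ub + tol)
  }
  best <- NA_real_
  for (idx in utils::combn(ncon, n, simplify = FALSE)) {
    M <- A[idx, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- tryCatch(solve(M, b[idx]), error = function(e) NULL)
    if (is.null(x) || !feasible(x)) next
    val <- sum(obj * x)
    if (is.na(best) || val > best) best <- val
  }
  if (is.na(best)) list(status = "infeasible", objval = NA_real_)
  else list(status = "optimal", objval = best)
}

# Flatten a small model (no scenario) into the LP that FBA solves, for
# oracle comparisons: S v = 0 over internal metabolites, box bounds.
model_to_lp <- function(model) {
  rxns <- model$reactions
  rids <- names(rxns)
  int_met <- names(model$metabolites)[
    !vapply(model$metabolites, function(m) m$is_external, TRUE)]
  S <- matrix(0, length(int_met), length(rxns),
              dimnames = list(int_met, rids))
  for (j in seq_along(rxns)) {
    sto <- rxns[[j]]$stoichiometry
    keep <- intersect(names(sto), int_met)
    S[keep, j] <- sto[keep]
  }
  list(obj = vapply(rxns, function(r) r$objective_coefficient, 0),
       mat = S, dir = rep("=", nrow(S)), rhs = rep(0, nrow(S)),
       lb = vapply(rxns, function(r) r$lower_bound, 0),
       ub = vapply(rxns, function(r) r$upper_bound, 0))
}
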