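# Independent oracles used by the unit and acceptance tests. These never call
# the solver paths they check.

# Global maximum of the cost-sensitive SVM dual by active-set enumeration:
# every alpha_i is assigned lower bound / upper bound / free, the free block
# is solved with the equality multiplier, and the best feasible stationary
# candidate wins. Exact (up to linear-solver precision) for small L.
brute_force_svm_dual <- function(K, y, c_pos, c_neg) {
  L <- length(y)
  Ci <- ifelse(y > 0, c_pos, c_neg)
  Q <- K * outer(y, y)
  best <- -Inf
  best_alpha <- NULL
  states <- expand.grid(rep(list(0:2), L))  # 0 = lower, 1 = upper, 2 = free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    alpha <- ifelse(st == 1L, Ci, 0)
    Fr <- which(st == 2L)
    if (length(Fr) > 0L) {
      Bd <- which(st != 2L)
      rhs_top <- rep(1, length(Fr))
      if (length(Bd)) {
        rhs_top <- rhs_top - as.numeric(Q[Fr, Bd, drop = FALSE] %*% alpha[Bd])
      }
      rhs <- c(rhs_top, -sum(y[Bd] * alpha[Bd]))
      A <- rbind(cbind(Q[Fr, Fr, drop = FALSE], -y[Fr]), c(y[Fr], 0))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      aF <- sol[seq_along(Fr)]
      if (any(aF < -1e-9) || any(aF > Ci[Fr] + 1e-9)) next
      alpha[Fr] <- pmin(pmax(aF, 0), Ci[Fr])
    }
    if (abs(sum(y * alpha)) > 1e-9 * max(1, max(Ci))) next
    obj <- sum(alpha) - 0.5 * as.numeric(t(alpha * y) %*% K %*% (alpha * y))
    if (obj > best) { best <- obj; best_alpha <- alpha }
  }
  list(objective = best, alphas = best_alpha)
}

# k-NN by full exhaustive distance sort (stable tie-break toward lower index).
brute_force_knn <- function(train_X, train_y, x, k) {
  d <- sqrt(colSums((t(train_X) - x)^2))
  nn <- order(d)[seq_len(k)]
  if (sum(train_y[nn] > 0) > k / 2) 1 else -1
}

# tau^2 by full pairwise feature-space distance sort.
brute_force_tau <- function(points, i, N, sigma) {
  d2 <- apply(points, 1L, function(p) 2 - 2 * gaussian_kernel(points[i, ], p, sigma))
  mean(sort(d2[-i])[seq_len(N)])
}

# Karush-Kuhn-Tucker residuals of a fitted cost-sensitive SVM on its
# training set. Returns the largest complementarity residual.
kt_residuals <- function(model, X, y) {
  D <- decision_function(model, X)
  # map training rows to alphas (0 for non-SVs)
  alpha <- numeric(nrow(X))
  sv <- model$sv_vectors
  used <- rep(FALSE, nrow(sv))
  for (r in seq_len(nrow(X))) {
    for (s in which(!used)) {
      if (max(abs(X[r, ] - sv[s, ])) < 1e-12) {
        alpha[r] <- model$sv_alphas[s]; used[s] <- TRUE; break
      }
    }
  }
  Ci <- ifelse(y > 0, model$c_pos, model$c_neg)
  xi <- pmax(0, 1 - y * D)
  r1 <- alpha * pmax(0, y * D - 1)          # alpha > 0 forces y D <= 1
  r2 <- (Ci - alpha) * xi                   # xi > 0 forces alpha = C
  max(c(r1, r2))
}
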