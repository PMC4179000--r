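## ---- cost-sensitive SVM dual solver ----------------------------------------

#' Solve the cost-sensitive SVM dual on a precomputed Gram matrix
#'
#' Maximizes `sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij` subject to
#' `0 <= alpha_i <= C+` for positive-label points, `0 <= alpha_i <= C-` for
#' negative-label points, and `sum(alpha_i y_i) = 0`. With `C+ = C-` this is
#' the conventional soft-margin SVM dual. Solved with sequential minimal
#' optimization using maximal-violating-pair working-set selection,
#' deterministic initialization at `alpha = 0`.
#'
#' The bias is averaged over all free support vectors (those with `alpha`
#' strictly inside the box); if none exist it is the midpoint of the
#' Karush-Kuhn-Tucker feasibility interval.
#'
#' @param K Symmetric positive semidefinite Gram matrix, `L x L`.
#' @param labels +-1 labels, length `L`.
#' @param c_pos,c_neg Penalty weights `C+`, `C-` (positive).
#' @param tol Working-pair violation tolerance for termination.
#' @param max_iter Iteration cap.
#' @return List with `alphas`, `bias`, `objective` (dual objective value) and
#'   `iterations`.
#' @export
solve_isvm_dual <- function(K, labels, c_pos, c_neg, tol = 1e-8,
                            max_iter = 1e5) {
  K <- as.matrix(K)
  L <- nrow(K)
  y <- as.numeric(labels)
  if (length(y) != L || ncol(K) != L) stop("Gram/label size mismatch")
  if (!all(y %in% c(-1, 1))) stop("labels must be coded +1 / -1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (c_pos <= 0 || c_neg <= 0) stop("penalty weights must be positive")

  Ci <- ifelse(y > 0, c_pos, c_neg)
  alpha <- numeric(L)
  Ka <- numeric(L)           # (K alpha*y)_i, so s_i = Ka_i
  eps <- 1e-12 * max(Ci)
  it <- 0L
  repeat {
    it <- it + 1L
    grad <- y - Ka           # -y_i * gradient_i = y_i - s_i
    up <- (y > 0 & alpha < Ci - eps) | (y < 0 & alpha > eps)
    lo <- (y < 0 & alpha < Ci - eps) | (y > 0 & alpha > eps)
    if (!any(up) || !any(lo)) break
    gi_up <- ifelse(up, grad, -Inf)
    gi_lo <- ifelse(lo, grad, Inf)
    i <- which.max(gi_up)
    j <- which.min(gi_lo)
    m <- grad[i]; M <- grad[j]
    if (m - M < tol || it > max_iter) break
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 1e-12) quad <- 1e-12
    t_step <- (m - M) / quad
    t_max_i <- if (y[i] > 0) Ci[i] - alpha[i] else alpha[i]
    t_max_j <- if (y[j] > 0) alpha[j] else Ci[j] - alpha[j]
    t_step <- min(t_step, t_max_i, t_max_j)
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    Ka <- Ka + t_step * (K[, i] - K[, j])
  }
  if (it > max_iter) {
    warning("SMO did not reach tolerance within ", max_iter, " iterations")
  }

  thr <- 1e-8 * max(Ci)
  free <- alpha > thr & alpha < Ci - thr
  b <- if (any(free)) {
    mean(y[free] - Ka[free])
  } else {
    grad <- y - Ka
    up <- (y > 0 & alpha < Ci - eps) | (y < 0 & alpha > eps)
    lo <- (y < 0 & alpha < Ci - eps) | (y > 0 & alpha > eps)
    (max(grad[up]) + min(grad[lo])) / 2
  }
  obj <- sum(alpha) - 0.5 * sum(alpha * y * Ka)
  list(alphas = alpha, bias = b, objective = obj, iterations = it)
}

# Dual objective for a given alpha (used by tests and diagnostics).
isvm_dual_objective <- function(K, labels, alphas) {
  ay <- alphas * labels
  sum(alphas) - 0.5 * as.numeric(t(ay) %*% K %*% ay)
}

## ---- model construction and prediction -------------------------------------

new_isvm_model <- function(X, y, sol, sigma, c_pos, c_neg, qk = NULL,
                           q_train = NULL) {
  thr <- 1e-8 * max(c_pos, c_neg)
  sv <- sol$alphas > thr
  structure(
    list(sv_vectors = as.matrix(X)[sv, , drop = FALSE],
         sv_alphas = sol$alphas[sv],
         sv_labels = y[sv],
         bias = sol$bias,
         c_pos = c_pos, c_neg = c_neg,
         sigma = sigma,
         transformed = !is.null(qk),
         qk = qk,
         sv_q = if (is.null(q_train)) NULL else q_train[sv]),
    class = "isvm_model")
}

#' @export
print.isvm_model <- function(x, ...) {
  cat(sprintf(
    "<isvm_model: %d SVs, C+ = %.4g, C- = %.4g, sigma = %.4g, kernel = %s>\n",
    length(x$sv_alphas), x$c_pos, x$c_neg, x$sigma,
    if (isTRUE(x$transformed)) "quasiconformal" else "gaussian"))
  invisible(x)
}

#' SVM decision function
#'
#' `D(x) = sum_i alpha_i y_i K(x_i, x) + b` over the support vectors, using
#' the model's kernel (plain Gaussian, or the quasiconformal transformation
#' when the model was trained in two steps). `D(x) > 0` classifies positive;
#' ties at exactly zero are classified negative.
#'
#' @param model An `isvm_model`.
#' @param X Numeric vector (one point) or matrix with points in rows.
#' @return Numeric vector of decision values.
#' @export
decision_function <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$sv_vectors)) stop("dimension mismatch")
  Kx <- gaussian_gram(X, model$sv_vectors, model$sigma)   # m x nSV
  w <- model$sv_alphas * model$sv_labels
  if (isTRUE(model$transformed)) {
    qx <- quasiconformal_q(X, model$qk)
    Kx <- (qx %o% model$sv_q) * Kx
  }
  as.numeric(Kx %*% w) + model$bias
}

#' @rdname decision_function
#' @export
predict.isvm_model <- function(object, newdata, ...) {
  ifelse(decision_function(object, newdata) > 0, 1, -1)
}

## ---- quasiconformal transformation -----------------------------------------

#' Squared distance between Gaussian-kernel feature maps
#'
#' For the Gaussian kernel `||phi(x) - phi(x')||^2 = 2 - 2 K(x, x')` since
#' `K(x, x) = 1`.
#'
#' @param x_i,x_j Numeric vectors of equal length.
#' @param sigma Gaussian kernel width.
#' @return Nonnegative scalar in [0, 2).
#' @export
feature_space_sqdist <- function(x_i, x_j, sigma) {
  2 - 2 * gaussian_kernel(x_i, x_j, sigma)
}

#' Local feature-space scale of a training point
#'
#' `tau_i^2` is the mean squared feature-space distance from `phi(x_i)` to
#' its `N` nearest neighbours among the other training points (ranked by
#' feature-space distance).
#'
#' @param points Numeric matrix of training points in rows.
#' @param i Row index of the point of interest.
#' @param N Number of nearest neighbours (default 3).
#' @param sigma Gaussian kernel width.
#' @return Positive scalar `tau_i^2`.
#' @export
compute_tau <- function(points, i, N = 3L, sigma) {
  points <- as.matrix(points)
  L <- nrow(points)
  if (L < N + 1L) stop("need at least N + 1 points")
  Krow <- gaussian_gram(points[i, , drop = FALSE], points, sigma)[1L, ]
  d2 <- 2 - 2 * Krow
  d2 <- d2[-i]
  tau2 <- mean(sort(d2)[seq_len(N)])
  if (tau2 <= 0) stop("tau^2 is zero: point has N exact duplicates")
  tau2
}

#' Construct a quasiconformal kernel specification
#'
#' Packages the within-margin support vectors `T` with their local scales
#' `tau^2` and the primary Gaussian width into the object that defines
#' `Q(x)` and the transformed kernel.
#'
#' The neighbour pool for `tau^2` is the within-margin set itself (with `N`
#' capped at `|T| - 1`), so the bump widths follow the spacing of the margin
#' region rather than the overall sampling density; a singleton `T` falls
#' back to neighbours from the full training set.
#'
#' @param X Full training matrix.
#' @param t_idx Indices into `X` of the within-margin support vectors.
#' @param sigma Primary Gaussian kernel width.
#' @param N Neighbour count for `tau^2` (default 3).
#' @return An object of class `qk_spec`.
#' @export
quasiconformal_spec <- function(X, t_idx, sigma, N = 3L) {
  X <- as.matrix(X)
  if (length(t_idx) < 1L) stop("within-margin set T is empty")
  tau_sq <- if (length(t_idx) >= 2L) {
    Tm <- X[t_idx, , drop = FALSE]
    Nt <- min(N, length(t_idx) - 1L)
    vapply(seq_along(t_idx), function(i) compute_tau(Tm, i, Nt, sigma),
           numeric(1))
  } else {
    vapply(t_idx, function(i) compute_tau(X, i, N, sigma), numeric(1))
  }
  structure(
    list(primary_sigma = sigma,
         t_points = X[t_idx, , drop = FALSE],
         tau_sq = tau_sq,
         neighbor_count = as.integer(N)),
    class = "qk_spec")
}

#' Quasiconformal scaling function Q(x)
#'
#' `Q(x) = sum_{x_i in T} exp(-||phi(x) - phi(x_i)||^2 / tau_i^2)`: a sum of
#' Gaussian bumps in feature space, largest near the within-margin support
#' vectors and decaying with distance from them. `0 < Q(x) <= |T|`.
#'
#' @param X Numeric vector (one point) or matrix with points in rows.
#' @param spec A [quasiconformal_spec()].
#' @return Numeric vector of `Q` values.
#' @export
quasiconformal_q <- function(X, spec) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  Kt <- gaussian_gram(X, spec$t_points, spec$primary_sigma)  # m x |T|
  d2 <- 2 - 2 * Kt
  as.numeric(exp(-sweep(d2, 2L, spec$tau_sq, "/")) %*% rep(1, ncol(Kt)))
}

#' Quasiconformal kernel
#'
#' The transformed kernel `K~(x, x') = Q(x) Q(x') K(x, x')`. Because it is a
#' positive diagonal scaling of a Gaussian Gram matrix, any Gram matrix of
#' `K~` stays positive semidefinite.
#'
#' @param x,x_prime Numeric vectors.
#' @param spec A [quasiconformal_spec()].
#' @return Kernel value.
#' @export
quasiconformal_kernel <- function(x, x_prime, spec) {
  quasiconformal_q(x, spec) * quasiconformal_q(x_prime, spec) *
    gaussian_kernel(x, x_prime, spec$primary_sigma)
}

## ---- two-step training -----------------------------------------------------

#' Within-margin support vectors of a fitted SVM
#'
#' Returns the indices of training points that are support vectors and whose
#' decision values satisfy `-1 <= D(x_i) <= 1` (inclusive, with a small
#' numerical tolerance for points sitting exactly on the margin).
#'
#' @param model An `isvm_model` from the first training step.
#' @param X Training matrix the model was fitted on.
#' @param margin_tol Numerical slack on the margin boundaries.
#' @return Integer vector of row indices into `X` (possibly empty).
#' @export
find_within_margin_svs <- function(model, X, margin_tol = 1e-4) {
  X <- as.matrix(X)
  D <- decision_function(model, X)
  thr <- 1e-8 * max(model$c_pos, model$c_neg)
  # match rows of X against stored support vectors
  is_sv <- rep(FALSE, nrow(X))
  sv <- model$sv_vectors
  used <- rep(FALSE, nrow(sv))
  for (r in seq_len(nrow(X))) {
    for (s in which(!used)) {
      if (isTRUE(all.equal(X[r, ], sv[s, ], tolerance = 1e-12,
                           check.attributes = FALSE))) {
        is_sv[r] <- TRUE; used[s] <- TRUE; break
      }
    }
  }
  which(is_sv & D >= -1 - margin_tol & D <= 1 + margin_tol)
}

#' Train an imbalanced quasiconformal-kernel SVM
#'
#' Two-step procedure. Step 1 fits a cost-sensitive SVM with the primary
#' Gaussian kernel, with penalty weights split between the classes by
#' [penalty_weights()] (the minority class receives the larger weight).
#' Step 2 collects the within-margin support vectors `T`, builds the
#' quasiconformal scaling `Q` from them, and re-solves the dual on the same
#' training set with the transformed Gram `Q(x_i) Q(x_j) K_ij` and the same
#' penalty weights. The returned model evaluates the transformed kernel at
#' test time.
#'
#' If step 1 is separable with no within-margin support vectors, the kernel
#' needs no re-shaping and the step-1 model is returned (flagged
#' `transformed = FALSE`) with a warning.
#'
#' @param X Numeric matrix of training points (e.g. KFDA projections) in rows.
#' @param y +-1 labels.
#' @param sigma Gaussian kernel width.
#' @param c_total Total penalty budget `C = C+ + C-`.
#' @param N Neighbour count for the local scales (default 3).
#' @param two_step Set `FALSE` to stop after step 1 (a plain imbalanced SVM).
#' @param weights `"dec"` (default) splits `c_total` by class frequency;
#'   `"equal"` uses `C+ = C- = c_total / 2` (the conventional SVM).
#' @return An `isvm_model`.
#' @export
train_iqk_svm <- function(X, y, sigma, c_total, N = 3L, two_step = TRUE,
                          weights = c("dec", "equal")) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  weights <- match.arg(weights)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  cw <- if (weights == "dec") {
    penalty_weights(n_pos, n_neg, c_total)
  } else {
    list(c_pos = c_total / 2, c_neg = c_total / 2)
  }

  K <- gaussian_gram(X, sigma = sigma)
  sol1 <- solve_isvm_dual(K, y, cw$c_pos, cw$c_neg)
  model1 <- new_isvm_model(X, y, sol1, sigma, cw$c_pos, cw$c_neg)
  if (!two_step) return(model1)

  # same rule as find_within_margin_svs(), evaluated directly on the step-1
  # dual solution to avoid re-matching rows against stored support vectors
  thr <- 1e-8 * max(cw$c_pos, cw$c_neg)
  D1 <- as.numeric(K %*% (sol1$alphas * y)) + sol1$bias
  t_idx <- which(sol1$alphas > thr & D1 >= -1 - 1e-4 & D1 <= 1 + 1e-4)
  if (length(t_idx) == 0L) {
    warning("no within-margin support vectors; returning untransformed model")
    return(model1)
  }
  spec <- tryCatch(quasiconformal_spec(X, t_idx, sigma, N),
                   error = function(e) NULL)
  if (is.null(spec)) {
    # degenerate local scales (e.g. a collapsed kernel width makes training
    # points coincide in feature space): the transformation is undefined
    warning("degenerate local scales; returning untransformed model")
    return(model1)
  }
  q <- quasiconformal_q(X, spec)
  K2 <- (q %o% q) * K
  sol2 <- solve_isvm_dual(K2, y, cw$c_pos, cw$c_neg)
  new_isvm_model(X, y, sol2, sigma, cw$c_pos, cw$c_neg, qk = spec,
                 q_train = q)
}
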