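#' Gaussian kernel
#'
#' `K(z, z') = exp(-||z - z'||^2 / (2 sigma^2))`.
#'
#' @param z_i,z_j Numeric vectors of equal length.
#' @param sigma Kernel width, positive.
#' @return Kernel value in (0, 1].
#' @export
gaussian_kernel <- function(z_i, z_j, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(z_i) != length(z_j)) stop("vector length mismatch")
  exp(-sum((z_i - z_j)^2) / (2 * sigma^2))
}

# Gram matrix of the Gaussian kernel between rows of X and rows of Y.
gaussian_gram <- function(X, Y = X, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

# Median pairwise Euclidean distance between rows; standard reference scale
# for kernel-width grids.
median_pairwise_dist <- function(X) {
  d <- stats::dist(as.matrix(X))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

# Mean pairwise distance. Used as the kernel-width reference for the SVM
# layer: discriminant projections can collapse each class to a near-point,
# which drives the median distance to the (vanishing) within-class scale,
# while the mean stays at the between-class scale.
mean_pairwise_dist <- function(X) {
  d <- stats::dist(as.matrix(X))
  m <- mean(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

#' Double-center a kernel matrix
#'
#' Centers the implicitly mapped data to zero mean in feature space:
#' `Kc = K - J K - K J + J K J` with `J` the matrix of entries `1/L`. Every
#' row and column of `Kc` sums to zero.
#'
#' @param K Symmetric kernel matrix.
#' @return List with `Kc` (centered matrix) and `stats` (per-column means and
#'   grand mean, needed to center test kernel columns consistently).
#' @export
center_kernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  col_means <- colMeans(K)
  grand_mean <- mean(K)
  Kc <- K - matrix(col_means, nrow(K), ncol(K), byrow = TRUE) -
    matrix(colMeans(t(K)), nrow(K), ncol(K)) + grand_mean
  list(Kc = Kc, stats = list(col_means = col_means, grand_mean = grand_mean))
}

#' Center a test kernel column with training statistics
#'
#' Applies the training-set centering transform to the vector of kernel
#' evaluations between one test point and the `L` training points.
#'
#' @param k Numeric vector of length `L`.
#' @param stats Centering statistics from [center_kernel()].
#' @return Centered column of length `L`.
#' @export
center_test_column <- function(k, stats) {
  if (length(k) != length(stats$col_means)) stop("kernel column length mismatch")
  k - stats$col_means - mean(k) + stats$grand_mean
}

#' Fit a two-class kernel Fisher discriminant model
#'
#' Maximizes the ratio of between-class to total scatter of the kernel-mapped,
#' feature-space-centered data over projection directions
#' `v = sum_i a_i phi(z_i)`. In coefficient space this is the generalized
#' symmetric eigenproblem `B a = lambda (W + mu I) a` with
#' `B = (1/L) sum_p (1/n_p) (Kc 1_p)(Kc 1_p)^t` and `W = (1/L) Kc^2`, solved
#' by symmetric whitening of the regularized `W`. Each returned coefficient
#' column is rescaled so that `a^t Kc a = 1` and given a deterministic sign
#' (largest-magnitude entry positive).
#'
#' For two classes the between-class matrix has rank one, so only the first
#' eigenvalue is substantially positive; directions beyond the first are
#' ordered by the same regularized Rayleigh quotient.
#'
#' @param Z Numeric matrix, `L x n`, training vectors in rows.
#' @param labels Vector of +-1 class labels, length `L`.
#' @param sigma Gaussian kernel width.
#' @param d Number of projection directions, `1 <= d <= L`.
#' @param mu Ridge added to the scatter denominator; default
#'   `1e-6 * trace(W)/L`.
#' @return An object of class `kfda_model`.
#' @export
kfda_fit <- function(Z, labels, sigma, d = 1L, mu = NULL) {
  Z <- as.matrix(Z)
  L <- nrow(Z)
  labels <- as.numeric(labels)
  if (length(labels) != L) stop("labels length must match rows of Z")
  if (!all(labels %in% c(-1, 1))) stop("labels must be coded +1 / -1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (d < 1L || d > L) stop("d must satisfy 1 <= d <= L")
  if (sigma <= 0) stop("sigma must be positive")

  K <- gaussian_gram(Z, sigma = sigma)
  cen <- center_kernel(K)
  Kc <- cen$Kc

  W <- (Kc %*% Kc) / L
  B <- matrix(0, L, L)
  for (cls in c(1, -1)) {
    idx <- labels == cls
    mvec <- rowSums(Kc[, idx, drop = FALSE])
    B <- B + tcrossprod(mvec) / sum(idx)
  }
  B <- B / L

  if (is.null(mu)) mu <- 1e-6 * sum(diag(W)) / L
  S <- W + diag(mu, L)

  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  tol_ev <- max(es$values) * 1e-12
  if (any(es$values <= tol_ev)) {
    if (mu == 0) stop("scatter matrix numerically singular; use mu > 0")
    es$values <- pmax(es$values, tol_ev)
  }
  S_half_inv <- es$vectors %*% (t(es$vectors) / sqrt(es$values))

  C <- S_half_inv %*% B %*% S_half_inv
  ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ord <- seq_len(d)
  A <- S_half_inv %*% ec$vectors[, ord, drop = FALSE]
  eigenvalues <- ec$values[ord]

  # normalize a^t Kc a = 1 and fix signs
  for (j in seq_len(d)) {
    a <- A[, j]
    q <- as.numeric(t(a) %*% Kc %*% a)
    if (q <= 0) q <- .Machine$double.eps
    a <- a / sqrt(q)
    if (a[which.max(abs(a))] < 0) a <- -a
    A[, j] <- a
  }

  structure(
    list(training_vectors = Z,
         class_sizes = c(sum(labels == 1), sum(labels == -1)),
         sigma = sigma,
         d = as.integer(d),
         coefficients = A,
         eigenvalues = eigenvalues,
         centering_stats = cen$stats,
         regularization = mu),
    class = "kfda_model")
}

#' @export
print.kfda_model <- function(x, ...) {
  cat(sprintf(
    "<kfda_model: L = %d (%d/%d), n = %d, sigma = %.4g, d = %d, lambda1 = %.4g>\n",
    nrow(x$training_vectors), x$class_sizes[1], x$class_sizes[2],
    ncol(x$training_vectors), x$sigma, x$d, x$eigenvalues[1]))
  invisible(x)
}

#' Project data through a fitted KFDA model
#'
#' Computes the d-dimensional discriminant projections
#' `x^i = sum_j a_j^i K(z_j, z)` using centered test kernel columns.
#'
#' @param model A [kfda_fit()] model.
#' @param Z Numeric vector (one point) or matrix with points in rows.
#' @return Numeric matrix, one row of `d` projection values per input point.
#' @export
kfda_transform <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  Z <- as.matrix(Z)
  if (ncol(Z) != ncol(model$training_vectors)) {
    stop("dimension mismatch: expected ", ncol(model$training_vectors),
         " columns")
  }
  Kt <- gaussian_gram(model$training_vectors, Z, model$sigma)  # L x m
  Ktc <- apply(Kt, 2L, center_test_column, stats = model$centering_stats)
  if (is.null(dim(Ktc))) Ktc <- matrix(Ktc, ncol = ncol(Kt))
  t(crossprod(model$coefficients, Ktc))                        # m x d
}
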