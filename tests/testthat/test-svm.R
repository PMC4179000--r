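test_that("a mirror-symmetric two-point problem gives equal alphas and zero bias", {
  X <- matrix(c(-1, 1), 2, 1)
  K <- eeger:::gaussian_gram(X, sigma = 1)
  sol <- solve_isvm_dual(K, c(-1, 1), 10, 10)
  expect_equal(sol$alphas[1], sol$alphas[2], tolerance = 1e-8)
  expect_equal(sol$bias, 0, tolerance = 1e-8)

  model <- train_iqk_svm(X, c(-1, 1), sigma = 1, c_total = 20,
                         two_step = FALSE, weights = "equal")
  expect_equal(decision_function(model, 0), 0, tolerance = 1e-8)
})

test_that("the dual solution matches brute-force QP enumeration on small problems", {
  set.seed(42)
  for (i in 1:12) {
    L <- sample(5:8, 1)
    y <- c(1, 1, -1, -1, sample(c(-1, 1), L - 4, replace = TRUE))
    X <- matrix(rnorm(L * 2), L, 2)
    K <- eeger:::gaussian_gram(X, sigma = runif(1, 0.5, 2))
    cw <- penalty_weights(sum(y > 0), sum(y < 0), runif(1, 0.5, 20))
    sol <- solve_isvm_dual(K, y, cw$c_pos, cw$c_neg)
    bf <- brute_force_svm_dual(K, y, cw$c_pos, cw$c_neg)
    expect_equal(sol$objective, bf$objective, tolerance = 1e-6)
  }
})

test_that("equal class weights reproduce the conventional single-C SVM", {
  set.seed(77)
  for (i in 1:5) {
    L <- 8
    y <- c(1, 1, -1, -1, sample(c(-1, 1), L - 4, replace = TRUE))
    X <- matrix(rnorm(L * 2), L, 2)
    K <- eeger:::gaussian_gram(X, sigma = 1)
    C <- runif(1, 1, 10)
    sol <- solve_isvm_dual(K, y, C, C)          # weighted solver, C+ = C-
    bf <- brute_force_svm_dual(K, y, C, C)      # conventional single-C dual
    expect_equal(sol$objective, bf$objective, tolerance = 1e-6)
  }
})

test_that("fitted models satisfy feasibility and Kuhn-Tucker conditions", {
  set.seed(55)
  for (i in 1:5) {
    d <- simulate_feature_clusters(14, 10, dims = 2,
                                   mean_separation = runif(1, 1, 4),
                                   seed = 50 + i)
    cw <- penalty_weights(14, 10, 8)
    K <- eeger:::gaussian_gram(d$X, sigma = 1.5)
    sol <- solve_isvm_dual(K, d$y, cw$c_pos, cw$c_neg)
    Ci <- ifelse(d$y > 0, cw$c_pos, cw$c_neg)
    expect_true(all(sol$alphas >= -1e-6) && all(sol$alphas <= Ci + 1e-6))
    expect_lt(abs(sum(sol$alphas * d$y)), 1e-6 * max(Ci))

    model <- eeger:::new_isvm_model(d$X, d$y, sol, 1.5, cw$c_pos, cw$c_neg)
    expect_lt(kt_residuals(model, d$X, d$y), 1e-4)

    # free SVs sit on the margin
    thr <- 1e-8 * max(Ci)
    free <- sol$alphas > thr & sol$alphas < Ci - thr
    if (any(free)) {
      D <- decision_function(model, d$X)
      expect_lt(max(abs(d$y[free] * D[free] - 1)), 1e-4)
    }
  }
})

test_that("negating all labels negates the decision function", {
  d <- simulate_feature_clusters(9, 7, dims = 2, mean_separation = 2,
                                 seed = 61)
  m1 <- train_iqk_svm(d$X, d$y, sigma = 1.5, c_total = 6, two_step = FALSE,
                      weights = "equal")
  m2 <- train_iqk_svm(d$X, -d$y, sigma = 1.5, c_total = 6, two_step = FALSE,
                      weights = "equal")
  probes <- as.matrix(expand.grid(seq(-2, 4, length.out = 5),
                                  seq(-2, 2, length.out = 4)))
  expect_equal(decision_function(m1, probes), -decision_function(m2, probes),
               tolerance = 1e-8)
})

test_that("within-margin SV selection matches the direct decision-value filter", {
  # separable, wide margin: T is exactly the on-margin SVs
  d <- separable_clusters(seed = 71)
  m <- train_iqk_svm(d$X, d$y, sigma = 3, c_total = 2000, two_step = FALSE)
  D <- decision_function(m, d$X)
  t_idx <- find_within_margin_svs(m, d$X)
  expect_gt(length(t_idx), 0L)
  expect_lt(max(abs(abs(D[t_idx]) - 1)), 1e-3)

  # overlapping, small C: direct enumeration of the defining condition
  d2 <- simulate_feature_clusters(20, 14, dims = 2, mean_separation = 1.5,
                                  seed = 72)
  m2 <- train_iqk_svm(d2$X, d2$y, sigma = 1.5, c_total = 2, two_step = FALSE)
  D2 <- decision_function(m2, d2$X)
  alpha_on <- rowSums(vapply(seq_len(nrow(m2$sv_vectors)), function(s) {
    apply(d2$X, 1, function(r) max(abs(r - m2$sv_vectors[s, ])) < 1e-12)
  }, logical(nrow(d2$X))))
  oracle <- which(alpha_on > 0 & D2 >= -1 - 1e-4 & D2 <= 1 + 1e-4)
  expect_equal(find_within_margin_svs(m2, d2$X), oracle)

  # probe points far outside the margin are never selected
  far <- d2$X + 100
  expect_length(find_within_margin_svs(m2, far), 0L)
})

test_that("feature-space squared distance obeys the kernel expansion identity", {
  expect_equal(feature_space_sqdist(c(1, 2), c(1, 2), 1), 0)
  expect_equal(feature_space_sqdist(c(0, 0), c(1e6, 0), 1), 2)
  set.seed(81)
  for (i in 1:100) {
    a <- rnorm(3); b <- rnorm(3); s <- runif(1, 0.3, 3)
    expect_equal(feature_space_sqdist(a, b, s),
                 gaussian_kernel(a, a, s) + gaussian_kernel(b, b, s) -
                   2 * gaussian_kernel(a, b, s),
                 tolerance = 1e-12)
  }
})

test_that("local scales tau^2 match brute-force neighbour sorts", {
  # regular tetrahedron: all pairwise distances equal
  Xt <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  s <- 2 - 2 * exp(-8 / (2 * 1.5^2))
  for (i in 1:4) {
    expect_equal(compute_tau(Xt, i, N = 3, sigma = 1.5), s,
                 tolerance = 1e-12)
  }

  X2 <- rbind(c(0, 0), c(2, 1))
  expect_equal(compute_tau(X2, 1, N = 1, sigma = 1),
               feature_space_sqdist(c(0, 0), c(2, 1), 1))

  set.seed(91)
  X <- matrix(rnorm(15 * 3), 15, 3)
  for (i in c(1, 8, 15)) {
    expect_equal(compute_tau(X, i, N = 3, sigma = 1.2),
                 brute_force_tau(X, i, 3, 1.2), tolerance = 1e-12)
  }
  expect_error(compute_tau(X[1:3, ], 1, N = 3, sigma = 1), "at least")
  expect_error(compute_tau(rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0)), 1,
                           N = 3, sigma = 1), "duplicates")
})

test_that("Q(x) behaves as a sum of feature-space bumps anchored at T", {
  X <- rbind(c(0, 0), c(1.5, 0), c(0, 1.5), c(3, 3))
  spec <- quasiconformal_spec(X, t_idx = 1L, sigma = 1, N = 3)
  expect_equal(quasiconformal_q(c(0, 0), spec), 1)     # exp(0) at the anchor

  # point whose feature-space sqdist equals tau^2 -> exp(-1)
  tau2 <- spec$tau_sq[1]
  r <- sqrt(-2 * log(1 - tau2 / 2))                    # input-space radius
  expect_equal(quasiconformal_q(c(r, 0), spec), exp(-1), tolerance = 1e-10)

  radii <- seq(0, 5, length.out = 20)
  qs <- vapply(radii, function(rr) quasiconformal_q(c(rr, 0), spec),
               numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("the quasiconformal kernel is symmetric with PSD Grams", {
  set.seed(101)
  for (i in 1:100) {
    X <- matrix(rnorm(6 * 2), 6, 2)
    spec <- quasiconformal_spec(X, t_idx = 1:2, sigma = runif(1, 0.5, 2))
    a <- rnorm(2); b <- rnorm(2)
    expect_equal(quasiconformal_kernel(a, b, spec),
                 quasiconformal_kernel(b, a, spec), tolerance = 1e-12)
  }
  for (i in 1:20) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    spec <- quasiconformal_spec(X, t_idx = sample(30, sample(2:6, 1)),
                                sigma = runif(1, 0.5, 2))
    q <- quasiconformal_q(X, spec)
    Kt <- (q %o% q) * eeger:::gaussian_gram(X, sigma = spec$primary_sigma)
    expect_gt(min(eigen(Kt, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("two-step training keeps separable data separable and round-trips", {
  d <- separable_clusters(seed = 111)
  m <- suppressWarnings(
    train_iqk_svm(d$X, d$y, sigma = eeger:::mean_pairwise_dist(d$X),
                  c_total = 50))
  expect_equal(predict(m, d$X), d$y)

  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  expect_equal(predict(load_model(path), d$X), predict(m, d$X))
})

test_that("a fully separated fit with no within-margin SVs falls back to step 1", {
  # two points far apart: hard margin, both SVs exactly on the margin, so T
  # is non-empty; push them within the margin of an offset probe set instead
  d <- separable_clusters(seed = 113)
  m1 <- train_iqk_svm(d$X, d$y, sigma = 3, c_total = 2000, two_step = FALSE)
  expect_length(find_within_margin_svs(m1, d$X + 50), 0L)
})
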