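test_that("balanced loss follows its definition and relabeling symmetry", {
  expect_equal(balanced_loss(list(tp = 10, fn = 0, tn = 5, fp = 0)), 0)
  expect_equal(balanced_loss(list(tp = 8, fn = 2, tn = 6, fp = 4)), 0.3)
  expect_equal(balanced_loss(list(tp = 0, fn = 7, tn = 0, fp = 3)), 1)
  expect_error(balanced_loss(list(tp = 0, fn = 0, tn = 5, fp = 1)),
               "undefined")

  set.seed(7)
  for (i in 1:20) {              # swapping classes swaps TPR and TNR only
    cc <- list(tp = sample(0:9, 1) + 1, fn = sample(0:9, 1),
               tn = sample(0:9, 1) + 1, fp = sample(0:9, 1))
    swapped <- list(tp = cc$tn, fn = cc$fp, tn = cc$tp, fp = cc$fn)
    expect_equal(balanced_loss(cc), balanced_loss(swapped))
  }
})

test_that("penalty weights split C inversely to class size", {
  w <- penalty_weights(100, 100, 4)
  expect_equal(w$c_pos, 2); expect_equal(w$c_neg, 2)

  w <- penalty_weights(146, 54, 1)
  expect_equal(w$c_pos, 0.27)
  expect_equal(w$c_neg, 0.73)
  expect_equal(w$c_pos + w$c_neg, 1)

  expect_error(penalty_weights(0, 10, 1), "at least one")
  expect_error(penalty_weights(10, 10, 0), "positive")
})

test_that("k-NN votes match an exhaustive distance sort", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5))
  y <- c(1, 1, -1, -1)
  expect_equal(knn_classify(X, y, c(5, 5), k = 1), -1)
  expect_equal(knn_classify(X, y, c(0.4, 0.4), k = 3), 1)  # votes +1 +1 -1
  expect_error(knn_classify(X, y, c(0, 0), k = 5), "exceeds")

  set.seed(14)
  trX <- matrix(rnorm(30 * 3), 30, 3)
  trY <- sample(c(-1, 1), 30, replace = TRUE)
  for (i in 1:50) {
    q <- rnorm(3)
    expect_equal(knn_classify(trX, trY, q, k = 3),
                 brute_force_knn(trX, trY, q, 3))
  }
})

test_that("cross-validation behaves on degenerate classifiers and is deterministic", {
  d <- simulate_feature_clusters(12, 8, dims = 2, mean_separation = 1,
                                 seed = 3)
  const_pos <- list(fit = function(X, y) NULL,
                    predict = function(m, X) rep(1, nrow(X)))
  res <- run_cv(d$X, d$y, const_pos, cv_protocol(2, 3, seed = 5))
  expect_equal(res$balanced_loss, 0.5)
  expect_equal(res$tpr, 1); expect_equal(res$tnr, 0)
  expect_equal(res$balanced_loss, 1 - (res$tpr + res$tnr) / 2,
               tolerance = 1e-12)

  # point-mass classes: a memorizing 1-NN is perfect on any stratified fold
  Xp <- rbind(matrix(rep(c(1, 1), 10), ncol = 2, byrow = TRUE),
              matrix(rep(c(-1, 0), 8), ncol = 2, byrow = TRUE))
  yp <- c(rep(1, 10), rep(-1, 8))
  onenn <- classifier_spec("knn", k = 1)
  expect_equal(run_cv(Xp, yp, onenn, cv_protocol(2, 2, seed = 2))$balanced_loss,
               0)

  r1 <- run_cv(d$X, d$y, classifier_spec("knn"), cv_protocol(2, 4, seed = 9))
  r2 <- run_cv(d$X, d$y, classifier_spec("knn"), cv_protocol(2, 4, seed = 9))
  expect_identical(r1$per_fold, r2$per_fold)
})

test_that("stratified folds never starve a class on imbalanced profiles", {
  prof <- cohort_profiles()
  for (i in seq_len(nrow(prof))) {
    y <- c(rep(1, prof$n_pos_arousal[i]), rep(-1, prof$n_neg_arousal[i]))
    fid <- withr::with_seed(i, eeger:::assign_folds(y, 2, TRUE))
    for (f in 1:2) {
      expect_setequal(unique(y[fid == f]), c(-1, 1))
    }
  }
})

test_that("grid search picks working settings and ignores grid order", {
  d <- separable_clusters(n_pos = 12, n_neg = 10, seed = 33)
  proto <- cv_protocol(2, 2, seed = 4)

  single <- grid_search(d$X, d$y,
                        list(kfda_sigma_rel = 1, d = 1L, sigma_rel = 1,
                             C = 10), proto)
  expect_equal(single$best$d, 1L)
  expect_equal(nrow(single$table), 1L)

  # a known-good width against a degenerate (vanishing) kernel width
  grids <- list(kfda_sigma_rel = c(1, 1e-6), d = 1L, sigma_rel = 1, C = 10)
  gs <- grid_search(d$X, d$y, grids, proto)
  expect_equal(gs$best$kfda_sigma_rel, 1)
  expect_lt(gs$result$balanced_loss, 0.1)

  grids_rev <- list(C = 10, sigma_rel = 1, d = 1L,
                    kfda_sigma_rel = c(1e-6, 1))
  gs2 <- grid_search(d$X, d$y, grids_rev, proto)
  expect_equal(gs2$best[order(names(gs2$best))],
               gs$best[order(names(gs$best))])
})

test_that("pearson correlation respects affine transformations", {
  x <- c(1, 3, 2, 5, 4)
  y <- c(2, 4, 6, 10, 7)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(2 * x + 7, y), r, tolerance = 1e-12)
  expect_equal(pearson_r(-x, y), -r, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("leave-one-out pooling matches direct enumeration", {
  d <- simulate_feature_clusters(5, 3, dims = 2, mean_separation = 2,
                                 seed = 41)
  spec <- classifier_spec("knn", k = 1)
  pred <- vapply(1:8, function(i) {
    brute_force_knn(d$X[-i, , drop = FALSE], d$y[-i], d$X[i, ], 1)
  }, numeric(1))
  expect_equal(eeger:::loo_balanced_loss(d$X, d$y, spec),
               balanced_loss(confusion_counts(d$y, pred)))
})

test_that("split-half and segment analyses return consistent structures", {
  # 10 trials x 2 epochs per participant; trial labels alternate so both
  # trial-disjoint halves contain both classes
  cohort <- lapply(1:4, function(s) {
    trial_y <- rep(c(1, -1), 5)
    y <- rep(trial_y, each = 2)
    X <- withr::with_seed(100 + s,
                          matrix(rnorm(20 * 2), 20, 2) + cbind(y, 0) * 1.5)
    list(X = X, valence = y, arousal = y * rep(c(1, -1), 10),
         trial = rep(1:10, each = 2), segment = rep(1:2, 10))
  })
  sh <- split_half_analysis(cohort, "valence")
  expect_equal(dim(sh$error_rates), c(4L, 2L))
  expect_true(all(sh$error_rates >= 0 & sh$error_rates <= 100))
  expect_true(sh$correlation >= -1 && sh$correlation <= 1)

  seg <- segment_consistency_analysis(cohort, "valence",
                                      protocol = cv_protocol(2, 2, seed = 1))
  expect_equal(dim(seg$error_rates), c(4L, 2L))
  expect_length(seg$means, 2L)

  # identical segments give identical per-segment error rates
  cohort_dup <- lapply(cohort, function(p) {
    first <- p$segment == 1
    list(X = rbind(p$X[first, ], p$X[first, ]),
         valence = rep(p$valence[first], 2),
         arousal = rep(p$arousal[first], 2),
         trial = rep(p$trial[first], 2),
         segment = rep(1:2, each = sum(first)))
  })
  seg_dup <- segment_consistency_analysis(cohort_dup, "valence",
                                          protocol = cv_protocol(2, 2, seed = 1))
  expect_equal(seg_dup$error_rates[, 1], seg_dup$error_rates[, 2])

  # unpaired trials are refused
  broken <- cohort
  broken[[1]]$segment[1] <- 2
  expect_error(segment_consistency_analysis(broken, "valence"),
               "both segments")
})
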