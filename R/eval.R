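#' Confusion counts for binary +-1 predictions
#'
#' @param truth,pred +-1 vectors of equal length.
#' @return List with fields `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth > 0 & pred > 0),
       fn = sum(truth > 0 & pred <= 0),
       tn = sum(truth <= 0 & pred <= 0),
       fp = sum(truth <= 0 & pred > 0))
}

#' Balanced loss
#'
#' `BL = 1 - (TPR + TNR) / 2` with `TPR = TP / (TP + FN)` and
#' `TNR = TN / (TN + FP)`. Insensitive to class imbalance; 0 for a perfect
#' classifier, 0.5 for any constant classifier, 1 for an always-wrong one.
#'
#' @param counts Confusion counts from [confusion_counts()] (or any list with
#'   fields `tp`, `fn`, `tn`, `fp`).
#' @return Balanced loss in [0, 1].
#' @export
balanced_loss <- function(counts) {
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$tn + counts$fp
  if (n_pos == 0 || n_neg == 0) {
    stop("balanced loss undefined: a class has no members")
  }
  1 - (counts$tp / n_pos + counts$tn / n_neg) / 2
}

#' Class penalty weights from label counts
#'
#' Splits the total penalty budget `C` between the classes in inverse
#' proportion to their sizes: `C+ = #N / (#P + #N) * C` and
#' `C- = #P / (#P + #N) * C`, so the smaller class receives the larger
#' penalty and `C+ + C- = C`.
#'
#' @param n_pos,n_neg Class sizes (positive integers).
#' @param c_total Total penalty budget `C > 0`.
#' @return List with `c_pos`, `c_neg`.
#' @export
penalty_weights <- function(n_pos, n_neg, c_total) {
  if (n_pos < 1 || n_neg < 1) stop("both classes need at least one member")
  if (c_total <= 0) stop("c_total must be positive")
  list(c_pos = n_neg / (n_pos + n_neg) * c_total,
       c_neg = n_pos / (n_pos + n_neg) * c_total)
}

#' k-nearest-neighbour baseline classifier
#'
#' Majority vote among the `k` nearest training points by Euclidean distance.
#' Distance ties are broken toward the lower training index; a tied vote
#' (possible only for even `k`) classifies negative.
#'
#' @param train_X Training matrix, points in rows.
#' @param train_y +-1 training labels.
#' @param X Query vector or matrix of queries in rows.
#' @param k Neighbour count (default 3).
#' @return +-1 predictions.
#' @export
knn_classify <- function(train_X, train_y, X, k = 3L) {
  train_X <- as.matrix(train_X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (k > nrow(train_X)) stop("k exceeds number of training points")
  d2 <- outer(rowSums(X^2), rowSums(train_X^2), "+") - 2 * tcrossprod(X, train_X)
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]   # stable: ties -> lower index
    if (sum(train_y[nn] > 0) > k / 2) 1 else -1
  })
}

#' Cross-validation protocol description
#'
#' The reference protocol is 2-fold cross-validation repeated over 10
#' independent runs, stratified by label; run `r` reshuffles with seed
#' `seed + r`.
#'
#' @param folds Number of folds (>= 2).
#' @param runs Number of independent repetitions.
#' @param seed Base seed.
#' @param stratified Stratify folds by label (default `TRUE`).
#' @return An object of class `cv_protocol`.
#' @export
cv_protocol <- function(folds = 2L, runs = 10L, seed = 1L, stratified = TRUE) {
  if (folds < 2L) stop("folds must be >= 2")
  if (runs < 1L) stop("runs must be >= 1")
  structure(list(folds = as.integer(folds), runs = as.integer(runs),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "cv_protocol")
}

# Fold assignment for one run. Returns an integer vector of fold ids.
assign_folds <- function(y, folds, stratified) {
  n <- length(y)
  fold_id <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds) stop("class too small for stratified split")
      fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold_id[sample.int(n)] <- rep_len(seq_len(folds), n)
  }
  fold_id
}

#' Run repeated stratified cross-validation
#'
#' For each run the data are reshuffled (seed `protocol$seed + run`) and
#' split into stratified folds; the method is fitted on the training portion
#' of each fold (any feature learning, e.g. the KFDA projection, happens
#' inside the fold) and evaluated on the held-out fold with the balanced
#' loss. Aggregate TPR/TNR are fold averages.
#'
#' @param X Feature matrix, points in rows.
#' @param y +-1 labels.
#' @param spec Method specification from [classifier_spec()] or
#'   [pipeline_spec()] — any list with `fit(X, y)` and
#'   `predict(model, X)`.
#' @param protocol A [cv_protocol()].
#' @return An object of class `evaluation_result` with aggregate `tpr`,
#'   `tnr`, `balanced_loss` and a `per_fold` data frame.
#' @export
run_cv <- function(X, y, spec, protocol = cv_protocol()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  rows <- list()
  for (run in seq_len(protocol$runs)) {
    fold_id <- withr::with_seed(protocol$seed + run,
                                assign_folds(y, protocol$folds,
                                             protocol$stratified))
    for (f in seq_len(protocol$folds)) {
      tr <- fold_id != f
      model <- spec$fit(X[tr, , drop = FALSE], y[tr])
      pred <- spec$predict(model, X[!tr, , drop = FALSE])
      cc <- confusion_counts(y[!tr], pred)
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, fold = f,
        tpr = cc$tp / (cc$tp + cc$fn), tnr = cc$tn / (cc$tn + cc$fp),
        balanced_loss = balanced_loss(cc))
    }
  }
  per_fold <- do.call(rbind, rows)
  tpr <- mean(per_fold$tpr); tnr <- mean(per_fold$tnr)
  structure(list(tpr = tpr, tnr = tnr,
                 balanced_loss = 1 - (tpr + tnr) / 2,
                 per_fold = per_fold),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result: BL = %.4f (TPR = %.4f, TNR = %.4f) over %d folds>\n",
    x$balanced_loss, x$tpr, x$tnr, nrow(x$per_fold)))
  invisible(x)
}

#' Build a classifier specification
#'
#' Produces the `fit`/`predict` pair used by [run_cv()] for one of the
#' supported classifiers. Kernel widths are given relative to the median
#' pairwise training distance (`sigma = sigma_rel * median distance`),
#' recomputed inside every training fold.
#'
#' * `knn` — [knn_classify()] baseline (`k`).
#' * `svm` — conventional soft-margin SVM: equal class weights, Gaussian
#'   kernel (`sigma_rel`, `C`).
#' * `isvm` — cost-sensitive SVM with frequency-split weights (step 1 only).
#' * `iqksvm` — full two-step quasiconformal training.
#'
#' @param classifier One of `"knn"`, `"svm"`, `"isvm"`, `"iqksvm"`.
#' @param k Neighbour count for `knn`.
#' @param sigma_rel Relative Gaussian width for the SVM family.
#' @param C Total penalty budget.
#' @param N Neighbour count for the quasiconformal scales.
#' @return A method specification list.
#' @export
classifier_spec <- function(classifier = c("knn", "svm", "isvm", "iqksvm"),
                            k = 3L, sigma_rel = 1, C = 1, N = 3L) {
  classifier <- match.arg(classifier)
  if (classifier == "knn") {
    return(list(
      name = "knn",
      fit = function(X, y) list(X = as.matrix(X), y = y),
      predict = function(model, X) knn_classify(model$X, model$y, X, k = k)))
  }
  two_step <- classifier == "iqksvm"
  weights <- if (classifier == "svm") "equal" else "dec"
  list(
    name = classifier,
    fit = function(X, y) {
      sigma <- sigma_rel * mean_pairwise_dist(X)
      suppressWarnings(
        train_iqk_svm(X, y, sigma = sigma, c_total = C, N = N,
                      two_step = two_step, weights = weights))
    },
    predict = function(model, X) predict(model, X))
}

#' Build a two-layer (KFDA + classifier) specification
#'
#' Fits the KFDA projection inside each training fold (no leakage) and runs
#' the inner classifier on the projections.
#'
#' @param classifier Inner classifier spec, e.g. from [classifier_spec()].
#' @param kfda_sigma_rel KFDA kernel width relative to the median pairwise
#'   training distance.
#' @param d Number of projection directions.
#' @return A method specification list.
#' @export
pipeline_spec <- function(classifier = classifier_spec("iqksvm"),
                          kfda_sigma_rel = 1, d = 1L) {
  list(
    name = paste0("kfep+", classifier$name),
    fit = function(X, y) {
      sigma <- kfda_sigma_rel * median_pairwise_dist(X)
      proj <- kfda_fit(X, y, sigma = sigma, d = d)
      feats <- kfda_transform(proj, X)
      list(proj = proj, inner = classifier$fit(feats, y))
    },
    predict = function(model, X) {
      classifier$predict(model$inner, kfda_transform(model$proj, X))
    })
}

#' Exhaustive grid search under the cross-validation protocol
#'
#' Evaluates every grid point with [run_cv()] and returns the setting with
#' the lowest mean balanced loss. Ties are broken toward smaller `d`, then
#' smaller `C`, then smaller kernel widths, so the result is independent of
#' the order the grids are given in.
#'
#' @param X,y Features and +-1 labels.
#' @param grids Named list of parameter vectors; names are passed to
#'   `builder`.
#' @param protocol A [cv_protocol()].
#' @param builder Function taking one named parameter set (as a list) and
#'   returning a method specification; default builds a KFDA + IQK-SVM
#'   pipeline from `kfda_sigma_rel`, `d`, `sigma_rel`, `C`.
#' @return List with `best` (parameter list), `result` (its
#'   [run_cv()] output) and `table` (per-setting mean balanced losses).
#' @export
grid_search <- function(X, y, grids, protocol = cv_protocol(),
                        builder = NULL) {
  if (length(grids) == 0L) stop("empty grid")
  if (is.null(builder)) {
    builder <- function(p) {
      pipeline_spec(
        classifier_spec("iqksvm", sigma_rel = p$sigma_rel, C = p$C),
        kfda_sigma_rel = p$kfda_sigma_rel, d = p$d)
    }
  }
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  tie_cols <- intersect(c("d", "C", "sigma_rel", "kfda_sigma_rel", "k"),
                        names(grid))
  if (length(tie_cols) > 0L) {
    grid <- grid[do.call(base::order, grid[tie_cols]), , drop = FALSE]
  }
  results <- vector("list", nrow(grid))
  losses <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, , drop = FALSE])
    results[[i]] <- run_cv(X, y, builder(params), protocol)
    losses[i] <- results[[i]]$balanced_loss
  }
  best_i <- which.min(losses)   # first minimum after deterministic ordering
  list(best = as.list(grid[best_i, , drop = FALSE]),
       result = results[[best_i]],
       table = cbind(grid, balanced_loss = losses))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(x, y, method = "pearson")
}

# Leave-one-out balanced loss of a method on one dataset.
loo_balanced_loss <- function(X, y, spec) {
  X <- as.matrix(X)
  pred <- vapply(seq_len(nrow(X)), function(i) {
    model <- spec$fit(X[-i, , drop = FALSE], y[-i])
    spec$predict(model, X[i, , drop = FALSE])
  }, numeric(1))
  balanced_loss(confusion_counts(y, pred))
}

#' Split-half reliability analysis
#'
#' Splits each participant's epochs into two trial-disjoint subsets (by
#' default the first half of the trials versus the second), estimates the
#' leave-one-out balanced loss on each subset independently, and correlates
#' the two per-participant error-rate columns.
#'
#' @param cohort List of participants, each a list with fields `X` (feature
#'   matrix), `valence`, `arousal` (+-1 vectors) and `trial` (trial index per
#'   epoch).
#' @param task `"valence"` or `"arousal"`.
#' @param spec Method specification (default the k-NN baseline).
#' @return List with `error_rates` (participants x 2 matrix, percent) and
#'   `correlation`.
#' @export
split_half_analysis <- function(cohort, task = c("valence", "arousal"),
                                spec = classifier_spec("knn")) {
  task <- match.arg(task)
  err <- t(vapply(cohort, function(p) {
    y <- p[[task]]
    trials <- sort(unique(p$trial))
    half <- trials[seq_len(length(trials) %/% 2)]
    in_a <- p$trial %in% half
    if (length(unique(y[in_a])) < 2L || length(unique(y[!in_a])) < 2L) {
      stop("subset contains a single class")
    }
    c(a = loo_balanced_loss(p$X[in_a, , drop = FALSE], y[in_a], spec),
      b = loo_balanced_loss(p$X[!in_a, , drop = FALSE], y[!in_a], spec))
  }, numeric(2))) * 100
  list(error_rates = err, correlation = pearson_r(err[, 1], err[, 2]))
}

#' Segment-consistency analysis
#'
#' Runs the cross-validation protocol independently on the first-segment and
#' second-segment epochs of each participant (segments are the two halves of
#' each trial's recording) and correlates the per-participant error rates of
#' the two segments.
#'
#' @param cohort As in [split_half_analysis()], with an additional `segment`
#'   field (1 or 2 per epoch); every trial must have both segments.
#' @param task `"valence"` or `"arousal"`.
#' @param spec Method specification (default the k-NN baseline).
#' @param protocol A [cv_protocol()].
#' @return List with `error_rates` (participants x 2 matrix, percent),
#'   `means` (per-segment averages) and `correlation`.
#' @export
segment_consistency_analysis <- function(cohort,
                                         task = c("valence", "arousal"),
                                         spec = classifier_spec("knn"),
                                         protocol = cv_protocol()) {
  task <- match.arg(task)
  err <- t(vapply(cohort, function(p) {
    for (tr in unique(p$trial)) {
      if (!setequal(p$segment[p$trial == tr], 1:2)) {
        stop("trial ", tr, " does not have both segments")
      }
    }
    vapply(1:2, function(s) {
      sel <- p$segment == s
      run_cv(p$X[sel, , drop = FALSE], p[[task]][sel], spec,
             protocol)$balanced_loss
    }, numeric(1))
  }, numeric(2))) * 100
  colnames(err) <- c("first", "second")
  list(error_rates = err, means = colMeans(err),
       correlation = pearson_r(err[, 1], err[, 2]))
}
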