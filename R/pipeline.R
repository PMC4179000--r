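#' Train the full three-layer emotion recognizer
#'
#' Extracts one band-power vector per epoch, then trains the valence and
#' arousal branches independently: each branch grid-searches its KFDA width,
#' projection count and SVM parameters under the cross-validation protocol
#' (the KFDA projection is refitted inside every training fold) and finally
#' refits on all epochs at the selected setting. High valence and high
#' arousal are the positive classes.
#'
#' @param epochs List of [epoch_record()] objects.
#' @param labels Data frame with columns `epoch_id`, `valence`, `arousal`
#'   (+-1), one row per epoch.
#' @param grids Named list of parameter vectors `kfda_sigma_rel`, `d`,
#'   `sigma_rel`, `C`.
#' @param protocol A [cv_protocol()].
#' @param bands Band definitions (default [default_bands()]).
#' @return An object of class `recognizer_model` carrying both branches and
#'   their cross-validated selections.
#' @export
train_recognizer <- function(epochs, labels,
                             grids = list(kfda_sigma_rel = c(0.5, 1, 2),
                                          d = 1:3,
                                          sigma_rel = c(0.5, 1, 2),
                                          C = c(1, 10)),
                             protocol = cv_protocol(),
                             bands = default_bands()) {
  ids <- vapply(epochs, `[[`, character(1), "epoch_id")
  m <- match(ids, labels$epoch_id)
  if (anyNA(m)) stop("missing labels for epochs: ",
                     paste(utils::head(ids[is.na(m)], 3L), collapse = ", "))
  labels <- labels[m, ]
  if (anyNA(labels$valence) || anyNA(labels$arousal)) {
    stop("every epoch needs both a valence and an arousal label")
  }
  X <- t(vapply(epochs, extract_sp_vector, bands = bands,
                numeric(length(bands) * nrow(epochs[[1]]$signal))))

  fit_branch <- function(y) {
    if (length(unique(y)) < 2L) stop("branch has a single class")
    gs <- grid_search(X, y, grids, protocol)
    p <- gs$best
    sigma_k <- p$kfda_sigma_rel * median_pairwise_dist(X)
    proj <- kfda_fit(X, y, sigma = sigma_k, d = p$d)
    feats <- kfda_transform(proj, X)
    sigma_s <- p$sigma_rel * mean_pairwise_dist(feats)
    svm <- suppressWarnings(
      train_iqk_svm(feats, y, sigma = sigma_s, c_total = p$C))
    list(kfda = proj, svm = svm, selected = p, cv = gs$result)
  }

  vb <- fit_branch(labels$valence)
  ab <- fit_branch(labels$arousal)
  structure(
    list(bands = bands,
         kfda_valence = vb$kfda, kfda_arousal = ab$kfda,
         svm_valence = vb$svm, svm_arousal = ab$svm,
         selected = list(valence = vb$selected, arousal = ab$selected),
         cv = list(valence = vb$cv, arousal = ab$cv)),
    class = "recognizer_model")
}

#' @export
print.recognizer_model <- function(x, ...) {
  cat("<recognizer_model>\n  valence branch: ")
  print(x$svm_valence)
  cat("  arousal branch: ")
  print(x$svm_arousal)
  if (!is.null(x$cv)) {
    cat(sprintf("  CV balanced loss: valence %.4f, arousal %.4f\n",
                x$cv$valence$balanced_loss, x$cv$arousal$balanced_loss))
  }
  invisible(x)
}

#' Classify the valence and arousal of epochs
#'
#' Runs each epoch through band-power extraction, both KFDA projections and
#' both SVM branches. A decision value above zero maps to `"high"`.
#'
#' @param model A [train_recognizer()] model.
#' @param epochs One [epoch_record()] or a list of them.
#' @return Data frame with columns `epoch_id`, `valence`, `arousal`
#'   (`"high"`/`"low"`).
#' @export
recognize <- function(model, epochs) {
  if (inherits(epochs, "epoch_record")) epochs <- list(epochs)
  n_ch <- ncol(model$kfda_valence$training_vectors) / length(model$bands)
  for (ep in epochs) {
    if (nrow(ep$signal) != n_ch) {
      stop("channel count mismatch: model expects ", n_ch, " channels")
    }
  }
  X <- t(vapply(epochs, extract_sp_vector, bands = model$bands,
                numeric(length(model$bands) * n_ch)))
  lab <- function(kfda, svm) {
    d <- decision_function(svm, kfda_transform(kfda, X))
    ifelse(d > 0, "high", "low")
  }
  data.frame(
    epoch_id = vapply(epochs, `[[`, character(1), "epoch_id"),
    valence = lab(model$kfda_valence, model$svm_valence),
    arousal = lab(model$kfda_arousal, model$svm_arousal),
    stringsAsFactors = FALSE)
}
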