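#' Construct an EEG epoch record
#'
#' An epoch is one contiguous multi-channel EEG segment stored as a
#' channels-by-samples matrix of microvolt values together with its sampling
#' rate and identifiers.
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param epoch_id Epoch identifier (string).
#' @param participant_id Participant identifier (string).
#' @return An object of class `epoch_record`.
#' @export
epoch_record <- function(signal, sampling_rate, epoch_id = "epoch",
                         participant_id = "participant") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("epoch signal must be numeric")
  if (nrow(signal) < 1L) stop("epoch must have at least one channel")
  if (ncol(signal) < 2L) stop("epoch must have at least two samples")
  if (!all(is.finite(signal))) stop("epoch signal contains non-finite samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  structure(
    list(epoch_id = as.character(epoch_id),
         participant_id = as.character(participant_id),
         signal = unname(signal),
         sampling_rate = as.numeric(sampling_rate)),
    class = "epoch_record")
}

#' @export
print.epoch_record <- function(x, ...) {
  cat(sprintf("<epoch_record %s/%s: %d channels x %d samples @ %g Hz>\n",
              x$participant_id, x$epoch_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate))
  invisible(x)
}

#' Write epochs to a directory of CSV matrices with a manifest
#'
#' Each epoch is stored as one CSV file (rows = channels, no header) and the
#' directory gains a `manifest.tsv` with columns `epoch_id`, `participant_id`,
#' `file`, `sampling_rate`. Channel order is file row order.
#'
#' @param epochs List of [epoch_record()] objects.
#' @param path Directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  if (length(epochs) == 0L) stop("no epochs to write")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  rows <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    stopifnot(inherits(ep, "epoch_record"))
    file <- sprintf("epoch_%04d.csv", i - 1L)  # 0-based file index
    utils::write.table(ep$signal, file.path(path, file), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    rows[[i]] <- data.frame(epoch_id = ep$epoch_id,
                            participant_id = ep$participant_id,
                            file = file,
                            sampling_rate = ep$sampling_rate,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read epochs from a manifest directory
#'
#' Reads the layout written by [write_epochs()]. Every CSV row must have the
#' same length; a ragged or non-numeric file is a format error naming the
#' offending epoch.
#'
#' @param path Directory containing `manifest.tsv` and epoch CSVs.
#' @param n_channels Optional declared channel count; epochs with a different
#'   number of rows are rejected.
#' @return List of [epoch_record()] objects in manifest order.
#' @export
read_epochs <- function(path, n_channels = NULL) {
  manifest_path <- file.path(path, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("manifest.tsv not found in ", path)
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    f <- file.path(path, row$file)
    if (!file.exists(f)) stop("epoch file missing: ", row$file)
    lines <- readLines(f)
    cells <- strsplit(lines, ",", fixed = TRUE)
    lens <- lengths(cells)
    if (length(unique(lens)) != 1L) {
      stop("format error in epoch '", row$epoch_id, "': ragged rows")
    }
    vals <- suppressWarnings(as.numeric(unlist(cells)))
    if (anyNA(vals)) {
      stop("format error in epoch '", row$epoch_id, "': non-numeric cell")
    }
    sig <- matrix(vals, nrow = length(lines), byrow = TRUE)
    if (!is.null(n_channels) && nrow(sig) != n_channels) {
      stop("format error in epoch '", row$epoch_id, "': expected ",
           n_channels, " channels, found ", nrow(sig))
    }
    epoch_record(sig, row$sampling_rate, row$epoch_id, row$participant_id)
  })
}

#' Read a per-epoch label table
#'
#' The TSV must have a header with columns `epoch_id`, `valence`, `arousal`.
#' Labels may be given as `high`/`low` tokens or as `+1`/`-1`; both map onto
#' the internal +1 (high) / -1 (low) coding.
#'
#' @param path Label TSV path.
#' @return Data frame with columns `epoch_id`, `valence`, `arousal` (+-1).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("epoch_id", "valence", "arousal")
  if (!all(need %in% names(tab))) {
    stop("label file must have columns: ", paste(need, collapse = ", "))
  }
  decode <- function(v) {
    v <- as.character(v)
    out <- ifelse(v %in% c("high", "+1", "1"), 1L,
                  ifelse(v %in% c("low", "-1"), -1L, NA_integer_))
    if (anyNA(out)) {
      stop("unknown label token: ",
           paste(unique(v[is.na(out)]), collapse = ", "))
    }
    out
  }
  if (anyDuplicated(tab$epoch_id)) stop("duplicate epoch_id in label file")
  data.frame(epoch_id = as.character(tab$epoch_id),
             valence = decode(tab$valence),
             arousal = decode(tab$arousal),
             stringsAsFactors = FALSE)
}

#' Write a per-epoch label table
#'
#' @param labels Data frame with columns `epoch_id`, `valence`, `arousal`
#'   coded +-1.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- data.frame(
    epoch_id = labels$epoch_id,
    valence = ifelse(labels$valence > 0, "high", "low"),
    arousal = ifelse(labels$arousal > 0, "high", "low"))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- model serialization ---------------------------------------------------

MODEL_SCHEMA_VERSION <- "1"

mat_to_json <- function(m) if (is.null(m)) NULL else unname(apply(m, 1L, as.numeric, simplify = FALSE))
json_to_mat <- function(l) if (is.null(l)) NULL else do.call(rbind, lapply(l, as.numeric))

serialize_model <- function(model) {
  if (inherits(model, "kfda_model")) {
    list(schema_version = MODEL_SCHEMA_VERSION,
         type = "kfda_model",
         training_vectors = mat_to_json(model$training_vectors),
         class_sizes = model$class_sizes,
         sigma = model$sigma,
         d = model$d,
         coefficients = mat_to_json(model$coefficients),
         eigenvalues = model$eigenvalues,
         centering_col_means = model$centering_stats$col_means,
         centering_grand_mean = model$centering_stats$grand_mean,
         regularization = model$regularization)
  } else if (inherits(model, "isvm_model")) {
    list(schema_version = MODEL_SCHEMA_VERSION,
         type = "isvm_model",
         sv_vectors = mat_to_json(model$sv_vectors),
         sv_alphas = model$sv_alphas,
         sv_labels = model$sv_labels,
         bias = model$bias,
         c_pos = model$c_pos,
         c_neg = model$c_neg,
         sigma = model$sigma,
         transformed = isTRUE(model$transformed),
         qk = if (is.null(model$qk)) NULL else list(
           primary_sigma = model$qk$primary_sigma,
           t_points = mat_to_json(model$qk$t_points),
           tau_sq = model$qk$tau_sq,
           neighbor_count = model$qk$neighbor_count),
         sv_q = model$sv_q)
  } else if (inherits(model, "recognizer_model")) {
    list(schema_version = MODEL_SCHEMA_VERSION,
         type = "recognizer_model",
         bands = lapply(model$bands, unclass),
         kfda_valence = serialize_model(model$kfda_valence),
         kfda_arousal = serialize_model(model$kfda_arousal),
         svm_valence = serialize_model(model$svm_valence),
         svm_arousal = serialize_model(model$svm_arousal))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
}

deserialize_model <- function(obj) {
  if (!identical(as.character(obj$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("model schema version mismatch: found ", obj$schema_version,
         ", expected ", MODEL_SCHEMA_VERSION)
  }
  switch(obj$type,
    kfda_model = structure(
      list(training_vectors = json_to_mat(obj$training_vectors),
           class_sizes = as.numeric(obj$class_sizes),
           sigma = obj$sigma,
           d = as.integer(obj$d),
           coefficients = json_to_mat(obj$coefficients),
           eigenvalues = as.numeric(obj$eigenvalues),
           centering_stats = list(
             col_means = as.numeric(obj$centering_col_means),
             grand_mean = as.numeric(obj$centering_grand_mean)),
           regularization = obj$regularization),
      class = "kfda_model"),
    isvm_model = structure(
      list(sv_vectors = json_to_mat(obj$sv_vectors),
           sv_alphas = as.numeric(obj$sv_alphas),
           sv_labels = as.numeric(obj$sv_labels),
           bias = obj$bias,
           c_pos = obj$c_pos,
           c_neg = obj$c_neg,
           sigma = obj$sigma,
           transformed = isTRUE(obj$transformed),
           qk = if (is.null(obj$qk)) NULL else structure(list(
             primary_sigma = obj$qk$primary_sigma,
             t_points = json_to_mat(obj$qk$t_points),
             tau_sq = as.numeric(obj$qk$tau_sq),
             neighbor_count = as.integer(obj$qk$neighbor_count)),
             class = "qk_spec"),
           sv_q = if (is.null(obj$sv_q)) NULL else as.numeric(obj$sv_q)),
      class = "isvm_model"),
    recognizer_model = structure(
      list(bands = lapply(obj$bands, function(b)
             frequency_band(b$name, b$low, b$high)),
           kfda_valence = deserialize_model(obj$kfda_valence),
           kfda_arousal = deserialize_model(obj$kfda_arousal),
           svm_valence = deserialize_model(obj$svm_valence),
           svm_arousal = deserialize_model(obj$svm_arousal)),
      class = "recognizer_model"),
    stop("unknown model type: ", obj$type))
}

#' Save a trained model as JSON
#'
#' Serializes `kfda_model`, `isvm_model` and `recognizer_model` objects into a
#' versioned JSON schema; [load_model()] restores them so that decision values
#' agree with the original model to well below 1e-9.
#'
#' @param model Trained model object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  deserialize_model(jsonlite::read_json(path, simplifyVector = FALSE))
}
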