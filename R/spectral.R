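#' Define a frequency band
#'
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  structure(list(name = as.character(name), low = as.numeric(low),
                 high = as.numeric(high)),
            class = "frequency_band")
}

#' Default EEG frequency bands
#'
#' The five standard bands used for band-power feature extraction: theta
#' (4-8 Hz), alpha (8-13 Hz), low beta (13-20 Hz), high beta (20-30 Hz) and
#' gamma (30-45 Hz).
#'
#' @return List of [frequency_band()] objects.
#' @export
default_bands <- function() {
  list(frequency_band("theta", 4, 8),
       frequency_band("alpha", 8, 13),
       frequency_band("low_beta", 13, 20),
       frequency_band("high_beta", 20, 30),
       frequency_band("gamma", 30, 45))
}

#' Load band definitions from a JSON config
#'
#' The JSON is an array of objects with fields `name`, `low`, `high`.
#'
#' @param path JSON file path.
#' @return List of [frequency_band()] objects.
#' @export
read_bands_config <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(spec, function(b) frequency_band(b$name, b$low, b$high))
}

## ---- Butterworth band-pass in second-order sections ------------------------

# Design a Butterworth band-pass of the given order as cascaded biquads.
# The analog low-pass prototype poles are transformed with signal::sftrans
# (low-pass -> band-pass) and signal::bilinear; working in zero-pole-gain
# form end to end avoids the ill-conditioned high-degree polynomial that the
# direct-form design produces for narrow bands at EEG sampling rates.
# Returns a list of sections, each with numerator b (length 3) and
# denominator a (length 3, a[1] = 1).
butter_bandpass_sos <- function(low, high, sampling_rate, order = 5L) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && high > low && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  k <- seq_len(order)
  proto <- signal::Zpg(zero = numeric(0),
                       pole = exp(1i * pi * (2 * k + order - 1) / (2 * order)),
                       gain = 1)
  Tbl <- 2
  warped <- (2 / Tbl) * tan(pi * c(low, high) / sampling_rate)
  zpg <- signal::bilinear(signal::sftrans(proto, W = warped, stop = FALSE),
                          T = Tbl)
  poles <- zpg$pole
  # conjugate pole pairs: take poles in the upper half plane, each paired
  # with its conjugate; a strictly real pole (possible only through rounding)
  # would be rejected by the finiteness checks downstream
  upper <- poles[Im(poles) > 0]
  upper <- upper[order(Mod(upper))]
  if (length(upper) != order) stop("internal error: unpaired filter poles")
  gs <- abs(zpg$gain)^(1 / order)
  lapply(upper, function(p) {
    list(b = gs * c(1, 0, -1),              # zeros at z = +1 and z = -1
         a = c(1, -2 * Re(p), Mod(p)^2))
  })
}

# Apply cascaded biquads causally (zero initial state) using stats::filter
# for the moving-average and recursive parts.
sos_apply <- function(sos, x) {
  for (sec in sos) {
    u <- stats::filter(c(x[1] * 0, x[1] * 0, x), sec$b, method = "convolution",
                       sides = 1)
    u <- as.numeric(u)[-(1:2)]
    x <- as.numeric(stats::filter(u, -sec$a[2:3], method = "recursive"))
  }
  x
}

# Complex frequency response of a section cascade at frequency f (Hz).
sos_response <- function(sos, f, sampling_rate) {
  z1 <- exp(-1i * 2 * pi * f / sampling_rate)
  H <- rep(1 + 0i, length(f))
  for (sec in sos) {
    H <- H * (sec$b[1] + sec$b[2] * z1 + sec$b[3] * z1^2) /
      (sec$a[1] + sec$a[2] * z1 + sec$a[3] * z1^2)
  }
  H
}

#' Band-pass filter a single-channel signal
#'
#' Causal (forward-only) Butterworth band-pass of the given order, realized
#' as cascaded second-order sections. Optional zero-phase mode runs the
#' cascade forward and backward.
#'
#' @param x Numeric vector, one channel of samples.
#' @param band A [frequency_band()].
#' @param sampling_rate Sampling rate in Hz.
#' @param order Filter order of the low-pass prototype (default 5).
#' @param zero_phase Apply forward-backward filtering (default `FALSE`).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, band, sampling_rate, order = 5L,
                            zero_phase = FALSE) {
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  if (length(x) < 3L * order) stop("signal too short for filter order")
  sos <- butter_bandpass_sos(band$low, band$high, sampling_rate, order)
  y <- sos_apply(sos, x)
  if (zero_phase) y <- rev(sos_apply(sos, rev(y)))
  y
}

#' Band power of a filtered signal
#'
#' The power of a frequency band is the mean of the squared samples of the
#' band-pass-filtered signal.
#'
#' @param x Numeric vector (already filtered).
#' @return Nonnegative scalar, microvolts squared.
#' @export
band_power <- function(x) {
  if (length(x) < 1L) stop("empty signal")
  mean(x^2)
}

#' Extract the spectral-power vector of an epoch
#'
#' Filters every channel into each band and computes band powers; the
#' per-channel 5-vectors (in declared band order) are concatenated in channel
#' order, giving a vector of length `bands x channels` (310 for 62 channels
#' and the five default bands).
#'
#' @param epoch An [epoch_record()].
#' @param bands List of [frequency_band()]s (default [default_bands()]).
#' @param zero_phase Passed to [bandpass_filter()].
#' @return Named numeric vector of length `length(bands) * n_channels`.
#' @export
extract_sp_vector <- function(epoch, bands = default_bands(),
                              zero_phase = FALSE) {
  stopifnot(inherits(epoch, "epoch_record"))
  if (length(bands) < 1L) stop("at least one band required")
  sos_list <- lapply(bands, function(b)
    butter_bandpass_sos(b$low, b$high, epoch$sampling_rate))
  n_ch <- nrow(epoch$signal)
  out <- numeric(length(bands) * n_ch)
  names_out <- character(length(out))
  idx <- 1L
  for (ch in seq_len(n_ch)) {
    x <- epoch$signal[ch, ]
    if (!all(is.finite(x))) stop("epoch signal contains non-finite samples")
    for (bi in seq_along(bands)) {
      y <- sos_apply(sos_list[[bi]], x)
      if (zero_phase) y <- rev(sos_apply(sos_list[[bi]], rev(y)))
      out[idx] <- band_power(y)
      names_out[idx] <- sprintf("ch%03d_%s", ch - 1L, bands[[bi]]$name)
      idx <- idx + 1L
    }
  }
  names(out) <- names_out
  out
}

#' Split an epoch into equal contiguous segments
#'
#' @param epoch An [epoch_record()].
#' @param parts Number of equal non-overlapping segments (sample count must
#'   be divisible by `parts`).
#' @return List of `parts` epoch records; ids gain a `_sN` suffix.
#' @export
split_epoch <- function(epoch, parts = 2L) {
  stopifnot(inherits(epoch, "epoch_record"))
  n <- ncol(epoch$signal)
  if (n %% parts != 0L) {
    stop("epoch length ", n, " not divisible into ", parts, " parts")
  }
  if (parts == 1L) return(list(epoch))
  len <- n %/% parts
  lapply(seq_len(parts), function(p) {
    cols <- ((p - 1L) * len + 1L):(p * len)
    epoch_record(epoch$signal[, cols, drop = FALSE], epoch$sampling_rate,
                 paste0(epoch$epoch_id, "_s", p - 1L), epoch$participant_id)
  })
}
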