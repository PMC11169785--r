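#' Preprocessing configuration
#'
#' Defaults follow standard ECoG practice: 1-200 Hz bandpass, 60 Hz notch and
#' harmonics, downsample to 500 Hz, order-4 Butterworth applied zero-phase
#' (forward-backward; effective order 8).
#'
#' @param bp_low,bp_high Bandpass edges in Hz.
#' @param notch_base Line frequency in Hz.
#' @param notch_harmonics How many multiples of `notch_base` to notch
#'   (harmonics at or above Nyquist are skipped).
#' @param notch_q Notch quality factor (center frequency / -3 dB width).
#' @param target_fs Sampling rate after downsampling (must divide the input
#'   rate).
#' @param filter_order Butterworth order for the bandpass.
#' @param zero_phase Apply filters forward-backward (default); avoids
#'   band-dependent envelope lags that would misalign the 10-s bins.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(bp_low = 1, bp_high = 200, notch_base = 60,
                              notch_harmonics = 3, notch_q = 30,
                              target_fs = 500, filter_order = 4,
                              zero_phase = TRUE) {
  if (bp_low <= 0 || bp_low >= bp_high) stop_config("need 0 < bp_low < bp_high")
  structure(list(bp_low = bp_low, bp_high = bp_high, notch_base = notch_base,
                 notch_harmonics = notch_harmonics, notch_q = notch_q,
                 target_fs = target_fs, filter_order = filter_order,
                 zero_phase = zero_phase),
            class = "preprocess_config")
}

# Biquad notch (RBJ audio-EQ cookbook).
notch_coefs <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1), a = c(1 + alpha, -2 * cos(w0), 1 - alpha))
}

butter_coefs <- function(order, low, high, fs, type = "pass") {
  bf <- if (type == "pass") {
    signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  } else {
    signal::butter(order, high / (fs / 2), type = "low")
  }
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# Apply one IIR filter to every channel (rows), optionally zero-phase.
apply_iir <- function(X, coefs, zero_phase = TRUE, pad = NULL) {
  if (is.null(pad)) pad <- 3 * (max(length(coefs$b), length(coefs$a)) - 1)
  pad <- min(pad, ncol(X) - 1L)
  if (zero_phase) {
    cpp_filtfilt_rows(coefs$b, coefs$a, X, as.integer(pad))
  } else {
    t(apply(X, 1, function(x) cpp_iir_filter(coefs$b, coefs$a, x)))
  }
}

#' Remove per-channel DC by median subtraction
#'
#' @param rec An [ecog_recording()].
#' @return A new recording with per-channel median 0.
#' @export
remove_dc <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (n_samples(rec) < 1L) stop_input("empty recording")
  med <- apply(rec$data, 1, median)
  rec$data <- rec$data - med
  rec
}

#' Bandpass and notch filter a recording
#'
#' Bandpass between `bp_low` and `bp_high` (Butterworth) and notch at the line
#' frequency and its harmonics below Nyquist; zero-phase by default.
#'
#' @param rec An [ecog_recording()].
#' @param cfg A [preprocess_config()].
#' @return A filtered recording at the same sampling rate.
#' @export
filter_raw <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "ecog_recording"))
  nyq <- rec$fs / 2
  if (cfg$bp_high >= nyq) stop_config("bp_high must be below Nyquist (", nyq, " Hz)")
  bp <- butter_coefs(cfg$filter_order, cfg$bp_low, cfg$bp_high, rec$fs)
  pad <- min(ncol(rec$data) - 1L, max(24L, round(3 * rec$fs / cfg$bp_low)))
  X <- apply_iir(rec$data, bp, cfg$zero_phase, pad = pad)
  freqs <- cfg$notch_base * seq_len(cfg$notch_harmonics)
  for (f0 in freqs[freqs < 0.98 * nyq]) {
    nc <- notch_coefs(f0, rec$fs, cfg$notch_q)
    X <- apply_iir(X, nc, cfg$zero_phase, pad = min(ncol(X) - 1L, round(2 * rec$fs)))
  }
  rec$data <- X
  rec
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias lowpass (Butterworth order 6 at 0.45 x
#' target rate) before decimation, even when the content is already
#' band-limited, as a defensive-correctness measure for arbitrary inputs.
#'
#' @param rec An [ecog_recording()].
#' @param target_fs Target rate in Hz; must divide `rec$fs`.
#' @return A recording at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (target_fs > rec$fs) stop_config("target_fs exceeds recording rate")
  if (target_fs == rec$fs) return(rec)
  fac <- rec$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) stop_config("target_fs must divide the recording rate")
  fac <- round(fac)
  aa <- butter_coefs(6, NA, 0.45 * target_fs, rec$fs, type = "low")
  X <- apply_iir(rec$data, aa, zero_phase = TRUE,
                 pad = min(ncol(rec$data) - 1L, round(rec$fs / 2)))
  rec$data <- X[, seq(1, ncol(X), by = fac), drop = FALSE]
  rec$fs <- target_fs
  rec
}

#' Re-reference to the common median
#'
#' Subtracts, at every sample, the median across good channels from all
#' channels. Bad channels are excluded from the median but still
#' re-referenced.
#'
#' @param rec An [ecog_recording()].
#' @return The re-referenced recording.
#' @export
common_median_reference <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  good <- which(rec$good)
  if (length(good) < 2L) stop_input("common median reference needs >= 2 good channels")
  med <- cpp_col_medians(rec$data, as.integer(good))
  rec$data <- sweep(rec$data, 2, med)
  rec
}

#' Full preprocessing chain
#'
#' `remove_dc` -> `filter_raw` -> `downsample` -> `common_median_reference`,
#' in that fixed order. All stages are pure; the input is never modified.
#'
#' @param rec An [ecog_recording()].
#' @param cfg A [preprocess_config()].
#' @return The cleaned recording at `cfg$target_fs`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  rec <- remove_dc(rec)
  rec <- filter_raw(rec, cfg)
  rec <- downsample(rec, min(cfg$target_fs, rec$fs))
  common_median_reference(rec)
}
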