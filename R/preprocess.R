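# Acquisition-equivalent filtering, EMG envelope / onset detection, epoching.
# All offline filters are applied zero-phase: the squared Butterworth
# magnitude response (the transfer function forward-backward filtering
# realises) is applied in the frequency domain, which keeps the printed
# cutoffs, doubles the effective order, and filters all channels of a long
# record in two FFTs each.

# |H(f)|^2 of a digital IIR filter (or cascade, given a list) on the
# n-point FFT grid
iir_mag_sq <- function(coef, n) {
  if (!is.null(coef$b)) coef <- list(coef)
  w <- 2 * pi * (0:(n - 1)) / n
  h2 <- rep(1, n)
  for (cf in coef) {
    e <- exp(-1i * outer(w, seq_along(cf$b) - 1))
    h <- as.vector(e %*% cf$b) / as.vector(e %*% cf$a)
    h2 <- h2 * Mod(h)^2
  }
  h2
}

# zero-phase filtering of a matrix of channels (columns); `coef` may be a
# single b/a filter or a list of them (applied as a cascade)
filtfilt_mat <- function(x, coef) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  m <- stats::nextn(n, c(2, 3, 5))
  h2 <- iir_mag_sq(coef, m)
  xp <- rbind(x, matrix(0, m - n, ncol(x)))
  y <- Re(stats::mvfft(stats::mvfft(xp) * h2, inverse = TRUE))[seq_len(n), , drop = FALSE] / m
  if (single) as.numeric(y) else y
}

butter_filtfilt <- function(x, coef) {
  filtfilt_mat(x, coef)
}

# per-channel application (sample-domain filters)
apply_to_channels <- function(rec, labels, fun) {
  out <- rec
  for (ch in labels) out$data[, ch] <- fun(rec$data[, ch])
  out
}

# matrix-wise zero-phase IIR application (frequency-domain filters)
apply_filter_channels <- function(rec, labels, coef) {
  out <- rec
  out$data[, labels] <- filtfilt_mat(rec$data[, labels, drop = FALSE], coef)
  out
}

#' EEG band-pass filter
#'
#' Zero-phase Butterworth band-pass, default 3-50 Hz, 3rd order, applied to
#' all EEG channels (EMG channels are left untouched).
#'
#' @param rec A [recording()].
#' @param low,high Cutoff frequencies, Hz.
#' @param order Butterworth order.
#' @return Filtered [recording()], same length.
#' @export
eeg_bandpass <- function(rec, low = 3, high = 50, order = 3) {
  stopifnot(inherits(rec, "recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("eeg_bandpass: need 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  apply_filter_channels(rec, eeg_channel_labels(rec), bf)
}

#' Powerline notch filter
#'
#' Zero-phase Butterworth band-stop of +-1 Hz around `freq` on all EEG
#' channels: at least 20 dB attenuation at `freq`, under 1 dB at
#' `freq +- 5` Hz.
#'
#' @param rec A [recording()].
#' @param freq Powerline frequency, Hz.
#' @return Filtered [recording()].
#' @export
powerline_notch <- function(rec, freq = 50) {
  stopifnot(inherits(rec, "recording"))
  if (freq >= rec$fs / 2) stop("powerline_notch: freq must be below fs/2")
  bf <- signal::butter(2, c(freq - 1, freq + 1) / (rec$fs / 2), type = "stop")
  apply_filter_channels(rec, eeg_channel_labels(rec), bf)
}

#' EMG envelope
#'
#' 20-500 Hz band-pass, full-wave rectification, then 10 Hz low-pass, on
#' the EMG channels only. Rectification is required for the onset threshold
#' rule to operate on a non-negative-trending envelope.
#'
#' @param rec A [recording()] containing EMG channels.
#' @return A [recording()] holding only the EMG envelope channels.
#' @export
emg_envelope <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  emg <- rec_channels(rec)[is_emg_label(rec_channels(rec))]
  if (length(emg) == 0) stop("emg_envelope: no EMG channels present")
  if (rec$fs <= 1000) stop("emg_envelope: sampling rate must exceed 1000 Hz")
  bp <- signal::butter(4, c(20, 500) / (rec$fs / 2), type = "pass")
  lp <- signal::butter(4, 10 / (rec$fs / 2), type = "low")
  env <- filtfilt_mat(abs(filtfilt_mat(rec$data[, emg, drop = FALSE], bp)), lp)
  colnames(env) <- emg
  recording(env, fs = rec$fs, condition = rec$condition, task = rec$task,
            events = rec$events)
}

#' Movement-onset detection parameters
#'
#' @param k_sd Threshold multiplier of the resting standard deviation.
#' @param min_hold Seconds the threshold must be continuously exceeded.
#' @param rest_window Seconds of baseline used for the resting mean/SD.
#' @return A list of class `"onset_params"`.
#' @export
onset_params <- function(k_sd = 2, min_hold = 0.1, rest_window = 1.5) {
  stopifnot(k_sd > 0, min_hold > 0, rest_window > 0)
  structure(list(k_sd = k_sd, min_hold = min_hold, rest_window = rest_window),
            class = "onset_params")
}

#' Detect movement onset from an EMG envelope
#'
#' Returns the first sample at which the envelope exceeds the resting mean
#' plus `k_sd` resting standard deviations continuously for at least
#' `min_hold` seconds, searching from `search_from` onward; the baseline is
#' the `rest_window` seconds immediately preceding `search_from`.
#'
#' @param env Numeric envelope vector (one channel).
#' @param fs Sampling rate, Hz.
#' @param params An [onset_params()].
#' @param search_from 1-based sample index where the search starts.
#' @param search_to Optional last sample of the search span.
#' @return Sample index of onset, or `NA` if no qualifying span exists.
#' @export
detect_movement_onset <- function(env, fs, params = onset_params(),
                                  search_from = NULL, search_to = length(env)) {
  stopifnot(inherits(params, "onset_params"))
  rest_n <- round(params$rest_window * fs)
  if (is.null(search_from)) search_from <- rest_n + 1L
  if (search_from - rest_n < 1 || search_from > length(env)) {
    stop("detect_movement_onset: rest window extends before the signal")
  }
  base <- env[(search_from - rest_n):(search_from - 1L)]
  thr <- mean(base) + params$k_sd * stats::sd(base)
  hold_n <- max(1L, round(params$min_hold * fs))
  above <- env[search_from:search_to] > thr
  if (!any(above)) return(NA_integer_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= hold_n)
  if (length(ok) == 0) return(NA_integer_)
  as.integer(search_from + starts[ok[1]] - 1L)
}

#' Epoch a recording around movement onsets
#'
#' Cuts `[t_start, t_end]` second windows around each onset sample. Trials
#' whose window exceeds the recording bounds are dropped (a message reports
#' the count).
#'
#' @param rec A [recording()].
#' @param onsets Sorted vector of onset sample indices.
#' @param t_start,t_end Window relative to onset, seconds.
#' @param labels Class label per onset (`"right_hand"`/`"bimanual"`).
#' @return An [epoch_set()].
#' @export
epoch_around <- function(rec, onsets, t_start = -2, t_end = 6, labels) {
  stopifnot(inherits(rec, "recording"), t_end > t_start)
  if (length(labels) != length(onsets)) {
    stop("epoch_around: labels must align with onsets")
  }
  n_len <- round((t_end - t_start) * rec$fs)
  first <- onsets + round(t_start * rec$fs)
  ok <- first >= 1 & (first + n_len - 1) <= nrow(rec$data) & !is.na(onsets)
  if (sum(!ok) > 0) {
    message("epoch_around: dropped ", sum(!ok), " trial(s) out of bounds")
  }
  if (!any(ok)) stop("epoch_around: no surviving trials")
  keep <- which(ok)
  chs <- rec_channels(rec)
  all_idx <- as.vector(vapply(keep, function(k) first[k]:(first[k] + n_len - 1L),
                              integer(n_len)))
  block <- rec$data[all_idx, , drop = FALSE]        # (n_len * n_keep) x nch
  trials <- aperm(array(block, c(n_len, length(keep), length(chs))), c(2, 3, 1))
  dimnames(trials) <- list(NULL, chs, NULL)
  epoch_set(trials, fs = rec$fs, t0_offset = t_start, labels = labels[keep])
}

#' Standard acquisition-equivalent preprocessing
#'
#' EEG band-pass (3-50 Hz) plus optional powerline notch; EMG channels pass
#' through untouched (their envelope is computed separately).
#'
#' @param rec A [recording()].
#' @param notch Apply the 50 Hz powerline notch.
#' @return Preprocessed [recording()].
#' @export
preprocess_recording <- function(rec, notch = TRUE) {
  if (!notch) return(eeg_bandpass(rec))
  # single-pass cascade of the band-pass and the powerline notch
  nyq <- rec$fs / 2
  cascade <- list(signal::butter(3, c(3, 50) / nyq, type = "pass"),
                  signal::butter(2, c(49, 51) / nyq, type = "stop"))
  apply_filter_channels(rec, eeg_channel_labels(rec), cascade)
}
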