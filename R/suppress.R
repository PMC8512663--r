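# The four artifact-suppression techniques, each per-channel and
# implementable in a streaming fashion (the centred SMA template implies an
# explicit look-ahead of ceiling(M/2) stimulation periods).

#' Superposition-of-moving-averages parameters
#'
#' @param window_len Samples per stimulation period (`fs / burst_rate`;
#'   40 at 1200 Hz and 30 Hz).
#' @param m_windows Number of neighbouring windows `M` averaged into the
#'   template (the template divides by `M + 1`, including the current
#'   window).
#' @return A list of class `"sma_params"`.
#' @export
sma_params <- function(window_len = 40, m_windows = 5) {
  stopifnot(window_len >= 2, m_windows >= 1)
  structure(list(window_len = as.integer(window_len),
                 m_windows = as.integer(m_windows)),
            class = "sma_params")
}

#' Self-referenced adaptive filter parameters
#'
#' @param frame_len Samples per stimulation period `N` (40 at 1200 Hz /
#'   30 Hz), which aligns the artifact across frames.
#' @param m_frames Number of past frames `M` in the least-squares predictor.
#' @return A list of class `"adaptive_params"`.
#' @export
adaptive_params <- function(frame_len = 40, m_frames = 6) {
  stopifnot(frame_len >= 2, m_frames >= 1)
  structure(list(frame_len = as.integer(frame_len),
                 m_frames = as.integer(m_frames)),
            class = "adaptive_params")
}

#' Median filter parameters
#'
#' @param window Odd window length in samples (7 samples is about 6 ms at
#'   1200 Hz).
#' @return A list of class `"median_params"`.
#' @export
median_params <- function(window = 7) {
  stopifnot(window >= 3, window %% 2 == 1)
  structure(list(window = as.integer(window)), class = "median_params")
}

#' Stimulation-frequency notch parameters
#'
#' @param low,high Band-stop edges, Hz (29-31 around the 30 Hz burst rate).
#' @param order Butterworth order.
#' @return A list of class `"notch_params"`.
#' @export
notch_params <- function(low = 29, high = 31, order = 3) {
  stopifnot(low < high)
  structure(list(low = low, high = high, order = as.integer(order)),
            class = "notch_params")
}

#' Superposition of moving averages (SMA) filter
#'
#' Splits the channel into consecutive non-overlapping windows of one
#' stimulation period and subtracts from each window the mean of the
#' `M + 1` windows centred on it (for `M = 5`: three before, the current,
#' and two after). The template is recomputed for every window, so it
#' tracks slow changes in artifact shape; near the record edges the window
#' set is clamped to the nearest `M + 1` valid windows. A trailing partial
#' window has the last full template subtracted.
#'
#' @param x Single-channel numeric series.
#' @param p An [sma_params()].
#' @return Filtered series, same length.
#' @export
sma_filter <- function(x, p = sma_params()) {
  L <- p$window_len
  m <- p$m_windows
  if (length(x) < (m + 1) * L) {
    stop("sma_filter: series shorter than (m_windows + 1) * window_len")
  }
  nw <- length(x) %/% L
  w <- matrix(x[seq_len(nw * L)], nrow = L)
  cs <- cbind(0, t(apply(w, 1, cumsum)))
  before <- ceiling(m / 2)
  after <- floor(m / 2)
  lo <- pmax(1L, pmin(seq_len(nw) - before, nw - m))
  hi <- lo + m
  templ <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) / (m + 1)
  out <- as.numeric(w - templ)
  rem <- length(x) - nw * L
  if (rem > 0) out <- c(out, x[(nw * L + 1):length(x)] - templ[seq_len(rem), nw])
  out
}

#' Self-referenced adaptive filter
#'
#' For each frame of `N` samples the artifact is predicted as a linear
#' combination of the `M` previous frames, with weights chosen per frame by
#' least squares to minimise the energy of the residual; the prediction is
#' then subtracted. The first `M` frames (and any trailing partial frame)
#' pass through unmodified. Because the filter uses only the corrupted
#' signal itself, anything predictable one stimulation period ahead --
#' including genuine narrowband EEG rhythms -- is attenuated along with the
#' artifact.
#'
#' @param x Single-channel numeric series.
#' @param p An [adaptive_params()].
#' @return Filtered series, same length.
#' @export
adaptive_filter <- function(x, p = adaptive_params()) {
  L <- p$frame_len
  m <- p$m_frames
  if (length(x) < (m + 1) * L) {
    stop("adaptive_filter: series shorter than (m_frames + 1) * frame_len")
  }
  nf <- length(x) %/% L
  fr <- matrix(x[seq_len(nf * L)], nrow = L)
  out <- fr
  # fast path assumes well-conditioned normal equations; on any singular
  # frame the whole channel is redone with the pseudo-inverse fallback
  run <- function(solver) {
    for (j in (m + 1):nf) {
      a <- fr[, (j - 1):(j - m), drop = FALSE]
      f <- fr[, j]
      b <- solver(crossprod(a), crossprod(a, f))
      out[, j] <- f - a %*% b
    }
    out
  }
  out <- tryCatch(run(solve), error = function(e) {
    message("adaptive_filter: singular normal equations; used pseudo-inverse")
    run(function(g, rhs) MASS::ginv(g) %*% rhs)
  })
  res <- as.numeric(out)
  if (length(x) > nf * L) res <- c(res, x[(nf * L + 1):length(x)])
  res
}

#' Sliding-median spike suppression
#'
#' Centred running median; record edges are handled with shrinking windows
#' rather than padding, so no data are invented at the boundaries. Removes
#' isolated spikes narrower than half the window.
#'
#' @param x Single-channel numeric series.
#' @param p A [median_params()].
#' @return Filtered series, same length.
#' @export
median_suppress <- function(x, p = median_params()) {
  if (length(x) < p$window) stop("median_suppress: series shorter than window")
  as.numeric(stats::runmed(x, p$window, endrule = "median"))
}

#' Stimulation-frequency notch filter
#'
#' Zero-phase Butterworth band-stop around the burst rate (29-31 Hz by
#' default). Attenuates the 30 Hz fundamental only; burst harmonics are
#' untouched.
#'
#' @param x Single-channel numeric series.
#' @param p A [notch_params()].
#' @param fs Sampling rate, Hz.
#' @return Filtered series, same length.
#' @export
stim_notch <- function(x, p = notch_params(), fs) {
  if (p$high >= fs / 2) stop("stim_notch: band must lie below fs/2")
  bf <- signal::butter(p$order, c(p$low, p$high) / (fs / 2), type = "stop")
  butter_filtfilt(x, bf)
}

#' Apply a suppression method to all EEG channels of a recording
#'
#' EMG channels are untouched. The method name is recorded in the
#' `"suppression"` attribute of the result.
#'
#' @param rec A [recording()].
#' @param method One of `"sma"`, `"adaptive"`, `"median"`, `"notch"`.
#' @param params Optional method parameter object; defaults are derived
#'   from `rec$fs` and `burst_rate`.
#' @param burst_rate Stimulation burst rate used for default window/frame
#'   lengths, Hz.
#' @return Filtered [recording()].
#' @export
apply_suppression <- function(rec, method, params = NULL, burst_rate = 30) {
  stopifnot(inherits(rec, "recording"))
  if (!method %in% c("sma", "adaptive", "median", "notch")) {
    stop("apply_suppression: unknown method '", method, "'")
  }
  period <- round(rec$fs / burst_rate)
  if (method == "notch") {
    p <- if (is.null(params)) notch_params() else params
    if (p$high >= rec$fs / 2) stop("stim_notch: band must lie below fs/2")
    bf <- signal::butter(p$order, c(p$low, p$high) / (rec$fs / 2), type = "stop")
    out <- apply_filter_channels(rec, eeg_channel_labels(rec), bf)
    attr(out, "suppression") <- method
    return(out)
  }
  fun <- switch(method,
    sma = {
      p <- if (is.null(params)) sma_params(window_len = period) else params
      function(x) sma_filter(x, p)
    },
    adaptive = {
      p <- if (is.null(params)) adaptive_params(frame_len = period) else params
      function(x) adaptive_filter(x, p)
    },
    median = {
      p <- if (is.null(params)) median_params() else params
      function(x) median_suppress(x, p)
    },
    notch = {
      p <- if (is.null(params)) notch_params() else params
      function(x) stim_notch(x, p, rec$fs)
    }
  )
  out <- apply_to_channels(rec, eeg_channel_labels(rec), fun)
  attr(out, "suppression") <- method
  out
}
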