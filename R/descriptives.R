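# Time-domain characterisation: kurtosis, RMS, Higuchi fractal dimension,
# zero crossings, computed on 10 s non-overlapping segments and averaged.

#' Split a channel into 10 s non-overlapping segments
#'
#' @param x Single-channel numeric series.
#' @param fs Sampling rate, Hz.
#' @param seg_s Segment length in seconds.
#' @return List of numeric segments; the trailing remainder is discarded.
#' @export
segment_10s <- function(x, fs, seg_s = 10) {
  n_seg <- floor(length(x) / (seg_s * fs))
  if (n_seg < 1) stop("segment_10s: series shorter than one segment")
  L <- round(seg_s * fs)
  lapply(seq_len(n_seg), function(i) x[((i - 1) * L + 1):(i * L)])
}

#' Pearson (non-excess) kurtosis
#'
#' `m4 / m2^2`; the Gaussian reference value is 3.
#'
#' @param seg Numeric segment with positive variance.
#' @return Kurtosis (unitless).
#' @export
kurtosis_stat <- function(seg) {
  m <- mean(seg)
  m2 <- mean((seg - m)^2)
  if (m2 == 0) stop("kurtosis_stat: undefined for zero-variance segment")
  mean((seg - m)^4) / m2^2
}

#' Root mean square
#'
#' Computed without mean removal (input EEG is already high-passed).
#'
#' @param seg Numeric segment.
#' @return RMS in the units of `seg` (uV for EEG).
#' @export
rms_stat <- function(seg) {
  if (length(seg) == 0) stop("rms_stat: empty segment")
  sqrt(mean(seg^2))
}

#' Higuchi fractal dimension
#'
#' Curve-length scaling estimate of signal complexity: for each lag
#' `k = 1..k_max` the mean normalised curve length `L(k)` over all offsets
#' is computed and the slope of `log L(k)` versus `log(1/k)` is returned.
#' Values lie between 1 (smooth) and 2 (noise-like).
#'
#' @param seg Numeric segment.
#' @param k_max Largest decimation lag.
#' @return Fractal dimension (unitless).
#' @export
higuchi_fd <- function(seg, k_max = 10) {
  n <- length(seg)
  if (n < 2 * k_max) stop("higuchi_fd: segment shorter than 2 * k_max")
  lk <- vapply(seq_len(k_max), function(k) {
    lm_vals <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1
      if (ni < 1) return(NA_real_)
      sum(abs(diff(seg[idx]))) * (n - 1) / (ni * k) / k
    }, numeric(1))
    mean(lm_vals, na.rm = TRUE)
  }, numeric(1))
  if (any(lk <= 0)) stop("higuchi_fd: degenerate (constant) segment")
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(k_max))), log(lk))
  unname(fit$coefficients[2])
}

#' Zero crossings per 10 seconds
#'
#' Strict sign changes between consecutive samples (exact zeros inherit the
#' previous sign, so a touch of zero is not double-counted), rescaled to a
#' 10 s basis.
#'
#' @param seg Numeric segment.
#' @param fs Sampling rate, Hz.
#' @return Crossings per 10 s.
#' @export
zero_crossings <- function(seg, fs) {
  if (length(seg) == 0) stop("zero_crossings: empty segment")
  s <- sign(seg)
  # zeros inherit the previous sign, which is equivalent to dropping them
  # from the sign sequence before counting changes
  filled <- s[s != 0]
  if (length(filled) < 2) return(0)
  count <- sum(diff(filled) != 0)
  count * (10 * fs) / length(seg)
}

segment_stats <- function(x, fs, k_max = 10) {
  segs <- segment_10s(x, fs)
  c(kurtosis = mean(vapply(segs, kurtosis_stat, numeric(1))),
    rms = mean(vapply(segs, rms_stat, numeric(1))),
    hfd = mean(vapply(segs, higuchi_fd, numeric(1), k_max = k_max)),
    zero_crossings = mean(vapply(segs, zero_crossings, numeric(1), fs = fs)))
}

#' Descriptive statistics per channel and condition
#'
#' Each channel is split into 10 s segments; the four statistics are
#' computed per segment, averaged within each recording and then across
#' recordings (subjects) supplied for a condition.
#'
#' @param recs Named list: condition label -> a [recording()] or a list of
#'   recordings (one per subject). All recordings must share the montage.
#' @param k_max `k_max` for [higuchi_fd()].
#' @return Data frame with columns `condition`, `channel`, `kurtosis`,
#'   `rms`, `hfd`, `zero_crossings`.
#' @export
describe_conditions <- function(recs, k_max = 10) {
  stopifnot(is.list(recs), !is.null(names(recs)))
  as_list <- lapply(recs, function(r) if (inherits(r, "recording")) list(r) else r)
  ch0 <- sort(rec_channels(as_list[[1]][[1]]))
  rows <- list()
  for (cond in names(as_list)) {
    per_rec <- lapply(as_list[[cond]], function(r) {
      if (!identical(sort(rec_channels(r)), ch0)) {
        stop("describe_conditions: montage mismatch across conditions")
      }
      t(vapply(rec_channels(r), function(ch) segment_stats(r$data[, ch], r$fs, k_max),
               numeric(4)))
    })
    avg <- Reduce(`+`, per_rec) / length(per_rec)
    rows[[cond]] <- data.frame(condition = cond,
                               channel = rownames(avg), avg,
                               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
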