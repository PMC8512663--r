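# Multitaper spectral estimation and the derived contamination measures.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the DPSS. For long series (`n > interp_base`) the tapers
#' are computed at `interp_base` points, spline-interpolated to length `n`
#' and re-orthonormalised; the approximation error of this classical device
#' is negligible for the smooth low-order tapers used in spectral
#' estimation.
#'
#' @param n Series length.
#' @param nw Time-bandwidth product (half bandwidth in Rayleigh units).
#' @param k Number of tapers (typically `2 * nw - 1`).
#' @param interp_base Length above which interpolation is used (1024 keeps
#'   the one-off eigendecomposition under a couple of seconds).
#' @return An `n` x `k` matrix; columns are unit-energy tapers ordered by
#'   decreasing spectral concentration.
#' @export
dpss_tapers <- function(n, nw, k, interp_base = 1024) {
  key <- paste(n, round(nw, 6), k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  stopifnot(n >= 8, nw >= 1, k >= 1, k < n)
  if (n <= interp_base) {
    w <- nw / n
    t_idx <- 0:(n - 1)
    diag_el <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
    off_el <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
    m <- matrix(0, n, n)
    m[cbind(t_idx + 1, t_idx + 1)] <- diag_el
    m[cbind(1:(n - 1), 2:n)] <- off_el
    m[cbind(2:n, 1:(n - 1))] <- off_el
    ev <- eigen(m, symmetric = TRUE)
    tp <- ev$vectors[, seq_len(k), drop = FALSE]
  } else {
    base <- dpss_tapers(interp_base, nw, k)
    x0 <- seq(0, 1, length.out = interp_base)
    x1 <- seq(0, 1, length.out = n)
    tp <- apply(base, 2, function(v) stats::spline(x0, v, xout = x1)$y)
    tp <- qr.Q(qr(tp))
  }
  # unit energy, deterministic polarity (positive lobe first)
  tp <- apply(tp, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    i <- which(abs(v) > max(abs(v)) / 2)[1]
    if (v[i] < 0) -v else v
  })
  .taper_cache[[key]] <- tp
  tp
}

#' Multitaper power spectral density
#'
#' Slepian-taper PSD per channel. The number of tapers is
#' `floor(2 * NW) - 1` with `NW = half_bandwidth * duration`, the standard
#' choice retaining only well-concentrated tapers. Channels are demeaned
#' before tapering. The estimate is one-sided, in uV^2/Hz.
#'
#' @param rec A [recording()] (all channels are analysed).
#' @param half_bandwidth Spectral half bandwidth in Hz (default 0.1 Hz, i.e.
#'   NW = 9 for a 90 s record).
#' @return A list of class `"spectral_result"` with `freqs` (Hz) and `power`
#'   (channel x frequency matrix).
#' @export
multitaper_psd <- function(rec, half_bandwidth = 0.1) {
  stopifnot(inherits(rec, "recording"))
  n <- nrow(rec$data)
  dur <- n / rec$fs
  if (dur < 2) stop("multitaper_psd: record must be at least 2 s long")
  nw <- half_bandwidth * dur
  if (nw < 1) {
    stop("multitaper_psd: half_bandwidth too small for this duration (NW < 1)")
  }
  k <- max(1L, floor(2 * nw) - 1L)
  tp <- dpss_tapers(n, nw, k)
  nfreq <- floor(n / 2) + 1L
  freqs <- (seq_len(nfreq) - 1) * rec$fs / n
  power <- matrix(0, ncol(rec$data), nfreq,
                  dimnames = list(rec_channels(rec), NULL))
  for (ch in seq_len(ncol(rec$data))) {
    x <- rec$data[, ch] - mean(rec$data[, ch])
    tapered <- tp * x
    spec <- Mod(stats::mvfft(tapered))^2 / rec$fs
    s <- rowMeans(spec)[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist when n is even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (n %% 2 == 0) dbl[nfreq] <- 1
    power[ch, ] <- s * dbl
  }
  structure(list(freqs = freqs, power = power, fs = rec$fs),
            class = "spectral_result")
}

#' Integrated band power
#'
#' Trapezoidal integral of the PSD over `[lo, hi]` per channel.
#'
#' @param res A [multitaper_psd()] result.
#' @param lo,hi Band edges in Hz (`lo <= hi`, inside the frequency grid).
#' @return Named numeric vector, one value per channel (uV^2).
#' @export
band_power <- function(res, lo, hi) {
  stopifnot(inherits(res, "spectral_result"), lo <= hi)
  if (lo < min(res$freqs) || hi > max(res$freqs)) {
    stop("band_power: band outside the frequency grid")
  }
  sel <- which(res$freqs >= lo & res$freqs <= hi)
  if (length(sel) < 2) return(stats::setNames(rep(0, nrow(res$power)), rownames(res$power)))
  f <- res$freqs[sel]
  apply(res$power[, sel, drop = FALSE], 1, function(p) {
    sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  })
}

#' Relative band-power change versus a reference condition
#'
#' @param on,off Named per-channel power vectors (same channels).
#' @return Data frame with `channel` and `change_pct`
#'   (`100 * (on - off) / off`).
#' @export
relative_power_change <- function(on, off) {
  stopifnot(length(on) == length(off))
  if (any(off <= 0)) stop("relative_power_change: reference power must be positive")
  data.frame(channel = names(off), change_pct = 100 * (on - off) / off,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Individual alpha frequency
#'
#' Frequency of maximal PSD within the alpha band (8-12 Hz) for one channel.
#'
#' @param res A [multitaper_psd()] result.
#' @param channel Channel label.
#' @param band Alpha search band in Hz.
#' @return Peak frequency in Hz. If the in-band spectrum is essentially flat
#'   the argmax is still returned, with a message flagging low contrast.
#' @export
individual_alpha_frequency <- function(res, channel, band = c(8, 12)) {
  stopifnot(inherits(res, "spectral_result"), channel %in% rownames(res$power))
  sel <- which(res$freqs >= band[1] & res$freqs <= band[2])
  if (length(sel) < 3) stop("individual_alpha_frequency: grid does not cover the alpha band")
  p <- res$power[channel, sel]
  if (max(p) < 1.5 * stats::median(p)) {
    message("individual_alpha_frequency: flat alpha band at ", channel,
            "; peak poorly defined")
  }
  res$freqs[sel[which.max(p)]]
}

#' 30 Hz contamination profile along the midline
#'
#' For the raw stimulation-on recording and each requested suppression
#' method, the relative change of 28-32 Hz band power versus the
#' stimulation-off recording, at the seven midline channels ordered from Fz
#' (most distal from the stimulation site) to Oz (most proximal).
#'
#' @param on,off Paired [recording()]s sharing the montage.
#' @param filters Character vector of suppression methods (subset of
#'   `"sma"`, `"adaptive"`, `"median"`, `"notch"`); may be empty.
#' @param band Band defining "30 Hz power" (default 28-32 Hz).
#' @param half_bandwidth Multitaper half bandwidth (Hz).
#' @return Data frame with columns `method`, `channel`, `rank`, `change_pct`.
#' @export
midline_30hz_profile <- function(on, off, filters = character(0),
                                 band = c(28, 32), half_bandwidth = 0.1) {
  stopifnot(inherits(on, "recording"), inherits(off, "recording"))
  if (!setequal(rec_channels(on), rec_channels(off))) {
    stop("midline_30hz_profile: paired recordings must share the montage")
  }
  mid <- midline_order()
  off_m <- slice_channels(off, mid$channel)
  on_m <- slice_channels(on, mid$channel)
  p_off <- band_power(multitaper_psd(off_m, half_bandwidth), band[1], band[2])
  rows <- list()
  variants <- c(list(raw = on_m),
                stats::setNames(lapply(filters, function(m) {
                  slice_channels(apply_suppression(on, m), mid$channel)
                }), filters))
  for (nm in names(variants)) {
    p_on <- band_power(multitaper_psd(variants[[nm]], half_bandwidth), band[1], band[2])
    ch <- relative_power_change(p_on, p_off)
    rows[[nm]] <- data.frame(method = nm, channel = ch$channel, rank = mid$rank,
                             change_pct = ch$change_pct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
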