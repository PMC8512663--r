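# Small fixture builders shared across the suite. Everything is generated
# in code; no stored data.

fix_recording <- function(n = 1200, fs = 1200, channels = c("Fz", "Cz", "Oz"),
                          seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n * length(channels)), ncol = length(channels),
                   dimnames = list(NULL, channels)), fs = fs)
}

# single-channel band power from a plain periodogram (independent of the
# package's multitaper path)
fix_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- fs * (0:(n - 1)) / n
  sum(p[f >= lo & f <= hi])
}

# period-40 artifact-like waveform: sine plus a sharp biphasic spike
fix_periodic <- function(n_periods = 60, period = 40) {
  w <- sin(2 * pi * seq_len(period) / period)
  w[period - 4] <- 6
  w[period - 3] <- -6
  rep(w, n_periods)
}

# toy epoch set: two classes differing in the variance of selected channels
fix_epochs <- function(n_per_class = 20, n_ch = 4, n_samp = 200,
                       var_ratio = 4, disc_ch = 1, seed = 7) {
  set.seed(seed)
  labels <- rep(c("right_hand", "bimanual"), each = n_per_class)
  trials <- array(rnorm(2 * n_per_class * n_ch * n_samp),
                  dim = c(2 * n_per_class, n_ch, n_samp),
                  dimnames = list(NULL, paste0("ch", seq_len(n_ch)), NULL))
  scale <- sqrt(var_ratio)
  trials[labels == "right_hand", disc_ch, ] <-
    trials[labels == "right_hand", disc_ch, ] * scale
  epoch_set(trials, fs = 100, t0_offset = 0, labels = labels)
}
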