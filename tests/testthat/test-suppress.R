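# independent brute-force evaluation of the template-subtraction equation:
# explicit loops, clamped centred window set {n-3, ..., n+2} for M = 5
sma_oracle <- function(x, L = 40, m = 5) {
  nw <- length(x) %/% L
  out <- x
  before <- ceiling(m / 2)
  templ <- numeric(L)
  for (j in seq_len(nw)) {
    lo <- j - before
    if (lo < 1) lo <- 1
    if (lo + m > nw) lo <- nw - m
    for (t in seq_len(L)) {
      templ[t] <- mean(x[((lo:(lo + m)) - 1) * L + t])
      out[(j - 1) * L + t] <- x[(j - 1) * L + t] - templ[t]
    }
  }
  rem <- length(x) - nw * L
  if (rem > 0) {
    idx <- (nw * L + 1):length(x)
    out[idx] <- x[idx] - templ[seq_len(rem)]
  }
  out
}

test_that("SMA filter matches a direct evaluation of the template equation", {
  set.seed(11)
  x <- fix_periodic(50) + sin(2 * pi * 10 * (0:1999) / 1200) + rnorm(2000, 0, 0.3)
  expect_equal(sma_filter(x), sma_oracle(x), tolerance = 1e-12)
  # and with a trailing partial window
  x2 <- x[1:1990]
  expect_equal(sma_filter(x2), sma_oracle(x2), tolerance = 1e-12)
})

test_that("SMA nulls a periodic artifact and spares off-comb content", {
  per <- fix_periodic(50)
  out <- sma_filter(per)
  expect_lt(sum(out^2) / sum(per^2), 1e-20)
  # 30 Hz bin power reduced > 95 %, 10 Hz retained
  mix <- fix_periodic(60) + sin(2 * pi * 10 * (0:2399) / 1200)
  y <- sma_filter(mix)
  expect_lt(fix_band_power(y, 1200, 29, 31) / fix_band_power(mix, 1200, 29, 31),
            0.05)
  expect_gt(fix_band_power(y, 1200, 9, 11) / fix_band_power(mix, 1200, 9, 11),
            0.8)
  expect_error(sma_filter(rnorm(100)), "shorter")
})

test_that("SMA distortion of artifact-free noise matches the analytic value", {
  # subtracting the mean of the 6 windows centred on the current one maps
  # white noise of unit variance to variance (5/6)^2 + 5 (1/6)^2 = 30/36
  set.seed(21)
  ratios <- replicate(10, {
    x <- rnorm(4000)
    var(sma_filter(x)) / var(x)
  })
  expect_true(all(ratios > 0.75 & ratios < 0.95))
  expect_equal(mean(ratios), 30 / 36, tolerance = 0.05)
})

test_that("empirical SMA response matches the analytic comb", {
  fs <- 1200
  for (f in c(10, 28, 30, 32, 45)) {
    x <- sin(2 * pi * f * (0:11999) / fs)
    gain2 <- sum(sma_filter(x)[2001:10000]^2) / sum(x[2001:10000]^2)
    h <- 1 - mean(exp(1i * 2 * pi * f * 40 / fs * (-3:2)))
    expect_equal(gain2, Mod(h)^2, tolerance = 0.02)
  }
})

test_that("adaptive filter is the per-frame least-squares minimiser", {
  per <- fix_periodic(60)
  out <- adaptive_filter(per)
  warm <- 6 * 40
  expect_lt(sum(out[(warm + 1):length(out)]^2) /
              sum(per[(warm + 1):length(per)]^2), 1e-6)
  expect_equal(out[1:warm], per[1:warm])  # first M frames pass through
  # output frame energy never exceeds input frame energy (optimality)
  set.seed(5)
  x <- rnorm(4000)
  y <- adaptive_filter(x)
  ein <- colSums(matrix(x[1:4000], nrow = 40)^2)
  eout <- colSums(matrix(y[1:4000], nrow = 40)^2)
  expect_true(all(eout <= ein + 1e-9))
  expect_error(adaptive_filter(rnorm(200)), "shorter")
})

test_that("adaptive output equals brute-force normal-equation prediction", {
  set.seed(6)
  # artifact repeating with slow AR-style amplitude evolution
  amp <- filter(rnorm(80), 0.9, method = "recursive")
  x <- as.numeric(t(outer(as.numeric(amp), sin(2 * pi * (1:40) / 40)))) +
    rnorm(3200, 0, 0.1)
  y <- adaptive_filter(x)
  fr <- matrix(x, nrow = 40)
  for (j in c(10, 40, 79)) {
    a <- fr[, (j - 1):(j - 6)]
    b <- solve(t(a) %*% a, t(a) %*% fr[, j])
    expect_equal(y[((j - 1) * 40 + 1):(j * 40)],
                 as.numeric(fr[, j] - a %*% b), tolerance = 1e-8)
  }
})

test_that("median filter removes narrow spikes and respects monotone input", {
  x <- rep(1, 100)
  x[50] <- 100
  expect_equal(median_suppress(x), rep(1, 100))
  ramp <- seq_len(200) / 10
  expect_equal(median_suppress(ramp)[4:197], ramp[4:197])
  pulse <- rep(0, 100)
  pulse[40:42] <- 50  # 3-sample pulse, window 7
  expect_equal(median_suppress(pulse), rep(0, 100))
  # idempotent on piecewise-constant signals
  pc <- rep(c(0, 5, -2, 3), each = 25)
  once <- median_suppress(pc)
  expect_equal(median_suppress(once), once)
  expect_error(median_suppress(rnorm(3)), "shorter")
})

test_that("stimulation notch meets its attenuation and passband contract", {
  fs <- 1200
  t <- (0:11999) / fs
  att_db <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- stim_notch(x, notch_params(), fs)
    -20 * log10(sqrt(mean(y[2001:10000]^2)) / sqrt(mean(x[2001:10000]^2)))
  }
  expect_gt(att_db(30), 30)
  expect_lt(att_db(20), 1)
  expect_lt(att_db(40), 1)
  x30 <- sin(2 * pi * 30 * t)
  expect_lt(sqrt(mean(stim_notch(x30, fs = fs)^2)), 0.03)
  x10 <- sin(2 * pi * 10 * t)
  expect_equal(sqrt(mean(stim_notch(x10, fs = fs)[2001:10000]^2)),
               sqrt(mean(x10[2001:10000]^2)), tolerance = 0.02)
  expect_true(all(abs(stim_notch(rep(0, 1000), fs = fs)) < 1e-12))
})

test_that("apply_suppression touches EEG only and validates the method", {
  pair <- compose_paired_sessions(background_spec(), erd_spec(), stim_profile(),
                                  seed = 14, task = "rest_eyes_open",
                                  duration = 20)
  on <- pair$on
  expect_error(apply_suppression(on, "wavelet"), "unknown method")
  for (m in c("sma", "adaptive", "median", "notch")) {
    out <- apply_suppression(on, m)
    expect_identical(attr(out, "suppression"), m)
    drop <- vapply(eeg_montage(), function(ch) {
      fix_band_power(out$data[, ch], 1200, 29, 31) /
        fix_band_power(on$data[, ch], 1200, 29, 31)
    }, numeric(1))
    expect_true(all(drop < 0.8))  # 30 Hz power falls in every channel
  }
})

test_that("SMA and notch shrink the RMS gap between the paired sessions", {
  pair <- compose_paired_sessions(background_spec(), erd_spec(), stim_profile(),
                                  seed = 15, task = "rest_eyes_open",
                                  duration = 20, shared_noise = TRUE)
  rms <- function(m) apply(m, 2, function(v) sqrt(mean(v^2)))
  gap_raw <- abs(rms(pair$on$data) - rms(pair$off$data))
  for (m in c("sma", "notch")) {
    filt <- apply_suppression(pair$on, m)
    gap <- abs(rms(filt$data) - rms(pair$off$data))
    expect_true(all(gap[c("POz", "Oz")] < gap_raw[c("POz", "Oz")]))
    expect_lt(mean(gap), mean(gap_raw))
  }
})
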