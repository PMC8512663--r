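test_that("Slepian tapers are orthonormal in both computation paths", {
  tp <- dpss_tapers(512, 4, 7)            # direct tridiagonal path
  expect_equal(crossprod(tp), diag(7), tolerance = 1e-10)
  tp2 <- dpss_tapers(6000, 4, 7)          # interpolated path
  expect_equal(crossprod(tp2), diag(7), tolerance = 1e-8)
  expect_equal(dim(tp2), c(6000, 7))
})

test_that("multitaper PSD locates tones and conserves power", {
  fs <- 600
  n <- 30 * fs
  x <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  res <- multitaper_psd(recording(cbind(Cz = x), fs = fs), 0.1)
  expect_equal(res$freqs[which.max(res$power["Cz", ])], 10, tolerance = 0.1)
  set.seed(51)
  wn <- recording(cbind(Cz = rnorm(n)), fs = fs)
  pw <- multitaper_psd(wn, 0.2)
  integ <- sum(diff(pw$freqs) *
                 (head(pw$power[1, ], -1) + tail(pw$power[1, ], -1)) / 2)
  expect_equal(integ, var(wn$data[, 1]), tolerance = 0.05)
  z <- multitaper_psd(recording(cbind(Cz = rep(0, n)), fs = fs), 0.1)
  expect_true(all(z$power == 0))
  expect_error(multitaper_psd(recording(cbind(Cz = rnorm(300)), fs = 600), 0.1),
               "2 s")
  expect_error(multitaper_psd(recording(cbind(Cz = rnorm(3 * 600)), fs = 600),
                              half_bandwidth = 0.1), "NW < 1")
})

test_that("PSD power scales quadratically with amplitude", {
  set.seed(52)
  x <- rnorm(6000)
  r1 <- multitaper_psd(recording(cbind(Cz = x), fs = 600), 0.5)
  r2 <- multitaper_psd(recording(cbind(Cz = 2 * x), fs = 600), 0.5)
  expect_equal(r2$power, 4 * r1$power, tolerance = 1e-10)
})

test_that("band power integrates the grid and adds over disjoint bands", {
  res <- structure(list(freqs = seq(0, 100, by = 0.5),
                        power = matrix(1, 1, 201,
                                       dimnames = list("Cz", NULL))),
                   class = "spectral_result")
  expect_equal(unname(band_power(res, 20, 24)), 4)
  expect_equal(unname(band_power(res, 30, 30)), 0)
  expect_error(band_power(res, 90, 110), "outside")
  set.seed(53)
  rnd <- multitaper_psd(recording(cbind(Cz = rnorm(6000)), fs = 600), 0.5)
  total <- band_power(rnd, 0, 300)
  expect_equal(unname(band_power(rnd, 0, 100) + band_power(rnd, 100, 300)),
               unname(total), tolerance = 0.02)
})

test_that("relative power change is the percentage against the reference", {
  off <- c(Fz = 2, Oz = 4)
  expect_equal(relative_power_change(off, off)$change_pct, c(0, 0))
  expect_equal(relative_power_change(2 * off, off)$change_pct, c(100, 100))
  expect_error(relative_power_change(off, c(Fz = 0, Oz = 1)), "positive")
})

test_that("alpha peak extraction is band-restricted and accurate", {
  fs <- 600
  n <- 60 * fs
  set.seed(54)
  noise <- tscseeg:::one_over_f_noise(n, fs, 1)
  x <- 5 * sin(2 * pi * 10.5 * (0:(n - 1)) / fs) + noise
  res <- multitaper_psd(recording(cbind(Oz = x), fs = fs), 0.1)
  expect_equal(individual_alpha_frequency(res, "Oz"), 10.5,
               tolerance = diff(res$freqs)[1] + 1e-9)
  # strong 6 Hz theta must not capture the alpha search
  y <- 20 * sin(2 * pi * 6 * (0:(n - 1)) / fs) +
    2 * sin(2 * pi * 9 * (0:(n - 1)) / fs) + noise
  res2 <- multitaper_psd(recording(cbind(Oz = y), fs = fs), 0.1)
  expect_equal(individual_alpha_frequency(res2, "Oz"), 9, tolerance = 0.05)
})

test_that("the artifact leaves the alpha peak in place (isolated pair)", {
  pair <- compose_paired_sessions(background_spec(), erd_spec(), stim_profile(),
                                  seed = 55, task = "rest_eyes_closed",
                                  duration = 30, shared_noise = TRUE)
  po <- multitaper_psd(slice_channels(preprocess_recording(pair$off), "Fz"), 0.1)
  pn <- multitaper_psd(slice_channels(preprocess_recording(pair$on), "Fz"), 0.1)
  expect_equal(individual_alpha_frequency(pn, "Fz"),
               individual_alpha_frequency(po, "Fz"),
               tolerance = diff(po$freqs)[1] + 1e-9)
})

test_that("eyes-closed alpha power exceeds eyes-open at default settings", {
  b <- background_spec()
  ro <- gen_background(b, 30, 1200, "open", seed = 56)
  rc <- gen_background(b, 30, 1200, "closed", seed = 56)
  p_open <- band_power(multitaper_psd(slice_channels(ro, "Oz"), 0.2), 8, 12)
  p_closed <- band_power(multitaper_psd(slice_channels(rc, "Oz"), 0.2), 8, 12)
  expect_gt(unname(p_closed), unname(p_open))
})

test_that("midline 30 Hz profile reflects gain monotonicity and suppression", {
  # identical recordings, no filters: all-zero profile
  rec <- fix_recording(n = 30 * 1200, fs = 1200,
                       channels = midline_order()$channel, seed = 57)
  prof0 <- midline_30hz_profile(rec, rec, half_bandwidth = 0.2)
  expect_equal(prof0$change_pct, rep(0, 7))
  # raw synthetic pair: contamination grows toward Oz; filters cut it
  pair <- compose_paired_sessions(background_spec(), erd_spec(),
                                  stim_profile(intensity = 60), seed = 58,
                                  task = "rest_eyes_closed", duration = 30)
  prof <- midline_30hz_profile(preprocess_recording(pair$on),
                               preprocess_recording(pair$off),
                               filters = c("sma", "notch"),
                               half_bandwidth = 0.2)
  raw <- prof[prof$method == "raw", ]
  raw <- raw[order(raw$rank, decreasing = TRUE), ]  # Fz ... Oz
  expect_false(is.unsorted(raw$change_pct))
  for (m in c("sma", "notch")) {
    fm <- prof[prof$method == m, ]
    expect_true(all(abs(fm$change_pct) <
                      abs(raw$change_pct[match(fm$channel, raw$channel)])))
  }
})
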