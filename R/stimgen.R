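# Synthetic-data generator: background EEG, sensorimotor movement sessions,
# and the tSCS pulse-train artifact with its spatial gradient and
# undersampling (aliasing) behaviour.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic derived seeds, kept inside 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483629)
}

#' Stimulation artifact parameterisation
#'
#' Defaults match cervical tSCS as used in upper-limb rehabilitation:
#' 30 Hz trains ("bursts") of ten 100 us biphasic rectangular pulses packed
#' back-to-back (10 kHz intra-burst rate, 1 ms burst), at a tolerable
#' intensity of about 40 mA. `channel_gain` maps each EEG channel to the
#' artifact peak amplitude it picks up, in uV per mA; the default decays
#' exponentially with anterior-posterior distance from the neck-posterior
#' stimulation site so that Oz receives about 3x the amplitude of Fz.
#'
#' `clock_drift` is the relative offset between the stimulator clock and the
#' EEG sampling clock. With a 1200 Hz sampling rate and a 30 Hz burst rate
#' the artifact period is exactly 40 samples, so with zero drift every burst
#' is sampled at identical phases; any non-zero drift makes the sampling
#' phase slide slowly through the 1 ms burst, which is what produces the
#' slow amplitude modulation (aliasing) seen on real recordings.
#'
#' @param burst_rate Burst (train) repetition rate, Hz.
#' @param pulses_per_burst Pulses per train.
#' @param pulse_width Duration of one biphasic pulse, seconds (both phases).
#' @param biphasic If `TRUE`, each pulse is a symmetric positive-negative
#'   rectangle with zero net charge.
#' @param intensity Stimulation current, mA.
#' @param clock_drift Relative stimulator clock offset (dimensionless).
#' @param channel_gain Named vector, uV of artifact peak per mA per channel.
#' @return A list of class `"stim_profile"`.
#' @export
stim_profile <- function(burst_rate = 30, pulses_per_burst = 10,
                         pulse_width = 100e-6, biphasic = TRUE,
                         intensity = 40, clock_drift = 1e-4,
                         channel_gain = default_channel_gain()) {
  stopifnot(burst_rate > 0, pulses_per_burst >= 1, pulse_width > 0)
  if (pulse_width * 2 * pulses_per_burst >= 1 / burst_rate) {
    stop("stim_profile: burst does not fit inside one stimulation period")
  }
  if (any(channel_gain < 0)) stop("stim_profile: channel_gain must be non-negative")
  mid <- midline_order()
  g <- channel_gain[mid$channel[order(mid$rank, decreasing = TRUE)]]  # Fz ... Oz
  g <- g[!is.na(g)]
  if (length(g) > 1 && any(diff(g) < 0)) {
    stop("stim_profile: channel_gain must be non-decreasing toward Oz")
  }
  structure(list(burst_rate = burst_rate, pulses_per_burst = pulses_per_burst,
                 pulse_width = pulse_width, biphasic = biphasic,
                 intensity = intensity, clock_drift = clock_drift,
                 channel_gain = channel_gain),
            class = "stim_profile")
}

#' Default artifact gain profile
#'
#' Exponential decay with anterior-posterior distance rank from the
#' stimulation site, calibrated so that the Oz/Fz amplitude ratio is
#' `fz_oz_ratio` and the gain at Oz is `gain_oz` uV per mA.
#'
#' @param gain_oz Artifact peak amplitude at Oz, uV per mA.
#' @param fz_oz_ratio Amplitude ratio Oz / Fz.
#' @param channels Channel labels.
#' @return Named numeric vector of gains (uV/mA).
#' @export
default_channel_gain <- function(gain_oz = 1.6, fz_oz_ratio = 3,
                                 channels = eeg_montage()) {
  r <- ap_rank(channels)
  g <- gain_oz * fz_oz_ratio^(-r / max(r))
  g[is_emg_label(channels)] <- 0
  stats::setNames(g, channels)
}

#' Background EEG parameterisation
#'
#' A 1/f ("pink") broadband floor plus a shared-phase narrowband alpha
#' oscillation whose amplitude depends on the eyes state (closed > open,
#' the classical Berger effect).
#'
#' @param alpha_freq Alpha centre frequency, Hz (8-12).
#' @param alpha_amp_open,alpha_amp_closed Equivalent alpha sine amplitude,
#'   uV, for eyes open / closed.
#' @param alpha_bandwidth Spectral half-width (Gaussian sigma) of the alpha
#'   process in Hz. The default 0 gives a stable spectral line (random
#'   phase), which keeps the individual alpha frequency of a session pair
#'   identical to sub-bin precision; real alpha is about 1 Hz wide.
#' @param one_over_f_exponent Spectral slope of the broadband floor.
#' @param noise_rms RMS of the broadband floor per channel, uV.
#' @return A list of class `"background_spec"`.
#' @export
background_spec <- function(alpha_freq = 10, alpha_amp_open = 3,
                            alpha_amp_closed = 10, alpha_bandwidth = 0,
                            one_over_f_exponent = 1, noise_rms = 5) {
  stopifnot(alpha_freq >= 8, alpha_freq <= 12,
            alpha_amp_open >= 0, alpha_amp_closed >= alpha_amp_open,
            alpha_bandwidth >= 0, noise_rms >= 0)
  structure(list(alpha_freq = alpha_freq, alpha_amp_open = alpha_amp_open,
                 alpha_amp_closed = alpha_amp_closed,
                 alpha_bandwidth = alpha_bandwidth,
                 one_over_f_exponent = one_over_f_exponent,
                 noise_rms = noise_rms),
            class = "background_spec")
}

#' Event-related desynchronisation parameterisation
#'
#' Sensorimotor mu and beta rhythms over the hand areas whose band power
#' drops by `erd_depth` during movement: contralaterally (left hemisphere)
#' for right-hand movement, bilaterally for bimanual movement.
#'
#' @param mu_band,beta_band Band limits, Hz.
#' @param erd_depth Fractional band-power reduction during movement (0-1).
#' @param mu_amp,beta_amp Resting equivalent sine amplitude of the rhythms,
#'   uV.
#' @return A list of class `"erd_spec"`.
#' @export
erd_spec <- function(mu_band = c(8, 13), beta_band = c(14, 30),
                     erd_depth = 0.5, mu_amp = 12, beta_amp = 5) {
  stopifnot(erd_depth >= 0, erd_depth <= 1, mu_amp >= 0, beta_amp >= 0)
  structure(list(mu_band = mu_band, beta_band = beta_band,
                 erd_depth = erd_depth, mu_amp = mu_amp, beta_amp = beta_amp),
            class = "erd_spec")
}

# Gaussian process with a prescribed spectral amplitude shape, unit variance.
# Synthesis length is padded to a 2-3-5-smooth integer so the FFT never
# degenerates to the O(n * p) mixed-radix worst case, then truncated.
shaped_noise <- function(n, fs, shape_fun) {
  m <- stats::nextn(n, c(2, 3, 5))
  f <- fs * (0:(m - 1)) / m
  f_fold <- pmin(f, fs - f)
  amp <- shape_fun(f_fold)
  amp[1] <- 0
  x <- stats::rnorm(m)
  y <- Re(stats::fft(stats::fft(x) * amp, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(y)
  if (s == 0) rep(0, n) else y / s
}

one_over_f_noise <- function(n, fs, expo) {
  shaped_noise(n, fs, function(f) pmax(f, 1)^(-expo / 2))
}

# Shared narrowband alpha waveform with equivalent sine amplitude `amp`
# (RMS = amp / sqrt(2)).
alpha_wave <- function(n, fs, freq, amp, bandwidth) {
  if (amp == 0) return(rep(0, n))
  if (bandwidth == 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    return(amp * sin(2 * pi * freq * (0:(n - 1)) / fs + phase))
  }
  w <- shaped_noise(n, fs, function(f) exp(-(f - freq)^2 / (2 * bandwidth^2)))
  w * amp / sqrt(2)
}

#' Generate resting-state background EEG
#'
#' Per-channel independent 1/f noise plus a shared-phase alpha oscillation
#' whose amplitude follows the eyes state. Deterministic given `seed`.
#'
#' @param spec A [background_spec()].
#' @param duration Length in seconds.
#' @param fs Sampling rate, Hz.
#' @param eyes `"open"` or `"closed"`.
#' @param seed Integer seed.
#' @param channels Channel labels (default: the 19-channel montage).
#' @param noise_seed Optional separate seed for the broadband floor, so a
#'   paired session can share its alpha draws but not its noise.
#' @return A [recording()] in the `tscs_off` condition.
#' @export
gen_background <- function(spec, duration, fs, eyes = c("open", "closed"),
                           seed, channels = eeg_montage(), noise_seed = NULL) {
  eyes <- match.arg(eyes)
  stopifnot(inherits(spec, "background_spec"))
  n <- round(duration * fs)
  if (n < 1) stop("gen_background: duration * fs must be at least 1")
  if (is.null(noise_seed)) noise_seed <- child_seed(seed, 1)
  amp <- if (eyes == "open") spec$alpha_amp_open else spec$alpha_amp_closed
  alpha <- with_seed(child_seed(seed, 2),
                     alpha_wave(n, fs, spec$alpha_freq, amp, spec$alpha_bandwidth))
  noise <- with_seed(noise_seed, {
    vapply(seq_along(channels), function(i) {
      spec$noise_rms * one_over_f_noise(n, fs, spec$one_over_f_exponent)
    }, numeric(n))
  })
  dat <- noise + alpha
  colnames(dat) <- channels
  recording(dat, fs = fs, condition = "tscs_off",
            task = paste0("rest_eyes_", eyes))
}

# Evaluate the continuous pulse-train waveform (unit peak) at times `t`
# (seconds), quantised to the oversampled grid of `fs * oversample_factor`.
# Identical to synthesising the train at the oversampled rate and taking
# every oversample_factor-th sample, without materialising the long vector.
pulse_train_at <- function(t, profile, fs, oversample_factor) {
  grid <- fs * oversample_factor
  # sample-centre convention: avoids floating-point ties when pulse-phase
  # boundaries coincide exactly with grid points
  tq <- (floor(t * grid) + 0.5) / grid
  t_burst <- 1 / (profile$burst_rate * (1 + profile$clock_drift))
  u <- tq %% t_burst
  burst_len <- profile$pulses_per_burst * profile$pulse_width
  inside <- u < burst_len
  v <- numeric(length(t))
  pos <- u[inside] %% profile$pulse_width
  if (profile$biphasic) {
    v[inside] <- ifelse(pos < profile$pulse_width / 2, 1, -1)
  } else {
    v[inside] <- 1
  }
  v
}

#' Generate the tSCS artifact as seen by the EEG amplifier
#'
#' The continuous-time burst train runs on the stimulator clock
#' (`burst_rate * (1 + clock_drift)`), is synthesised on an oversampled grid
#' and point-decimated (no anti-alias filter) to `fs` -- the mechanism that
#' produces both the narrow ~30 Hz peaks and, when `clock_drift != 0`, the
#' slow envelope modulation of their sampled amplitude. Per-channel
#' amplitude is `intensity * channel_gain`. The stimulator start phase is
#' randomised by `seed`.
#'
#' @param profile A [stim_profile()].
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param oversample_factor Integer oversampling factor; the oversampled
#'   rate must resolve one pulse with at least two samples.
#' @param seed Integer seed (stimulator start phase).
#' @param channels Channel labels (default montage).
#' @return A [recording()] holding the artifact alone (`tscs_on`).
#' @export
gen_tscs_artifact <- function(profile, duration, fs, oversample_factor = 100,
                              seed = 1, channels = eeg_montage()) {
  stopifnot(inherits(profile, "stim_profile"))
  min_ovs <- ceiling(2 / (profile$pulse_width * fs))
  if (oversample_factor < min_ovs) {
    stop("gen_tscs_artifact: oversample_factor too small; need at least ", min_ovs)
  }
  n <- round(duration * fs)
  phase0 <- with_seed(seed, stats::runif(1, 0, 1 / profile$burst_rate))
  t <- (0:(n - 1)) / fs + phase0
  w <- pulse_train_at(t, profile, fs, oversample_factor)
  gains <- profile$channel_gain[channels]
  gains[is.na(gains)] <- 0
  dat <- outer(w, as.numeric(gains) * profile$intensity)
  colnames(dat) <- channels
  recording(dat, fs = fs, condition = "tscs_on", task = "rest_eyes_open")
}

# channel sets for the sensorimotor rhythm model
sensorimotor_sets <- function() {
  list(left = c("FC3", "FC1", "C3", "C1", "CP3", "CP1"),
       right = c("FC2", "FC4", "C2", "C4", "CP2", "CP4"),
       midline = c("FCz", "Cz", "CPz"))
}

#' Generate a cued movement session
#'
#' Interleaved right-hand and bimanual trials: each trial is a 4 s movement
#' cued on screen, separated by a randomised 1.5-2.5 s inter-trial
#' interval. Sensorimotor mu and beta rhythms over the hand areas lose
#' `erd_depth` of their band power during movement -- in the left hemisphere
#' for right-hand trials and bilaterally for bimanual trials -- and two
#' forearm EMG channels (`EMG_L`, `EMG_R`) carry a burst starting 0-300 ms
#' after the cue on the moving side(s). Event codes: 1 = right-hand cue,
#' 2 = bimanual cue.
#'
#' @param bspec A [background_spec()].
#' @param espec An [erd_spec()].
#' @param n_trials_per_class Trials per class.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param noise_seed Optional separate seed for the broadband EEG noise.
#' @return A [recording()] with 19 EEG + 2 EMG channels, `task = "movement"`.
#' @export
gen_movement_session <- function(bspec, espec, n_trials_per_class = 30,
                                 fs = 1200, seed = 1, noise_seed = NULL) {
  stopifnot(inherits(bspec, "background_spec"), inherits(espec, "erd_spec"),
            n_trials_per_class >= 1)
  if (is.null(noise_seed)) noise_seed <- child_seed(seed, 1)
  n_tr <- 2L * n_trials_per_class

  sched <- with_seed(child_seed(seed, 2), {
    labels <- sample(rep(c("right_hand", "bimanual"), n_trials_per_class))
    iti <- stats::runif(n_tr, 1.5, 2.5)
    cues <- 5 + cumsum(c(0, 4 + iti[-n_tr]))
    list(labels = labels, cues = cues,
         emg_delay = stats::runif(n_tr, 0, 0.3))
  })
  duration <- sched$cues[n_tr] + 4 + 2
  n <- round(duration * fs)
  eeg_ch <- eeg_montage()

  # background floor + posterior-style alpha (not class-dependent)
  bg <- gen_background(bspec, duration, fs, eyes = "open",
                       seed = child_seed(seed, 3), channels = eeg_ch,
                       noise_seed = noise_seed)
  dat <- bg$data[seq_len(n), , drop = FALSE]

  # fast mask of [start, end) second intervals via a cumulated delta train
  interval_mask <- function(starts, ends) {
    d <- integer(n + 1L)
    i0 <- pmin(pmax(round(starts * fs) + 1L, 1L), n)
    i1 <- pmin(pmax(round(ends * fs) + 1L, 1L), n + 1L)
    for (k in seq_along(i0)) {
      d[i0[k]] <- d[i0[k]] + 1L
      d[i1[k]] <- d[i1[k]] - 1L
    }
    cumsum(d[seq_len(n)]) > 0
  }

  # per-hemisphere rhythm waveforms with ERD gain modulation
  sets <- sensorimotor_sets()
  gain_for <- function(side) {
    moves <- sched$labels == "bimanual" |
      (sched$labels == "right_hand" & side == "left") | side == "midline"
    if (!any(moves)) return(rep(1, n))
    m <- interval_mask(sched$cues[moves] + 0.2, sched$cues[moves] + 4)
    1 - m * (1 - sqrt(1 - espec$erd_depth))
  }
  # rhythm bandwidths matter for single-trial discriminability: a 2 s
  # classification window sees ~2 * bandwidth * T independent amplitude
  # draws, so unrealistically narrow rhythms make log-variance features
  # fade-limited regardless of amplitude
  rhythms <- with_seed(child_seed(seed, 4), {
    lapply(stats::setNames(names(sets), names(sets)), function(side) {
      mu <- alpha_wave(n, fs, mean(espec$mu_band), espec$mu_amp, 2)
      beta <- alpha_wave(n, fs, mean(espec$beta_band), espec$beta_amp, 4)
      (mu + beta) * gain_for(side)
    })
  })
  for (side in names(sets)) {
    dat[, sets[[side]]] <- dat[, sets[[side]]] + rhythms[[side]]
  }

  # forearm EMG: rest-level 20-500 Hz noise plus movement bursts
  emg <- with_seed(child_seed(seed, 5), {
    band <- function(f) as.numeric(f >= 20 & f <= 500)
    mk <- function(side) {
      rest <- 2 * shaped_noise(n, fs, band)
      burst <- 60 * shaped_noise(n, fs, band)
      active <- sched$labels == "bimanual" |
        (sched$labels == "right_hand" & side == "R")
      t0 <- sched$cues[active] + sched$emg_delay[active]
      rest + burst * interval_mask(t0, t0 + 4)
    }
    cbind(EMG_L = mk("L"), EMG_R = mk("R"))
  })

  events <- data.frame(
    sample = round(sched$cues * fs) + 1L,
    code = ifelse(sched$labels == "right_hand", 1L, 2L)
  )
  recording(cbind(dat, emg), fs = fs, condition = "tscs_off",
            task = "movement", events = events)
}

# day-to-day physiological variation between the two sessions of the
# crossover: log-normal amplitude moves of ~20% and a slight drift of the
# broadband spectral slope, the order of published test-retest variability
# of resting EEG band measures
jitter_specs <- function(bspec, espec, seed, sd_amp = 0.2, sd_rms = 0.15,
                         sd_expo = 0.08) {
  with_seed(seed, {
    b <- bspec
    a_jit <- exp(stats::rnorm(1, 0, sd_amp))
    b$alpha_amp_open <- b$alpha_amp_open * a_jit
    b$alpha_amp_closed <- b$alpha_amp_closed * a_jit
    b$noise_rms <- b$noise_rms * exp(stats::rnorm(1, 0, sd_rms))
    b$one_over_f_exponent <- b$one_over_f_exponent + stats::rnorm(1, 0, sd_expo)
    e <- espec
    r_jit <- exp(stats::rnorm(1, 0, sd_amp))
    e$mu_amp <- e$mu_amp * r_jit
    e$beta_amp <- e$beta_amp * r_jit
    list(bspec = b, espec = e)
  })
}

#' Compose a paired stimulation-off / stimulation-on session
#'
#' The neural content (alpha draws, cue schedule, rhythms, EMG) comes from
#' identical generator draws across the pair, but -- emulating a two-day
#' crossover -- each session redraws its broadband noise and receives a
#' small independent physiological jitter (alpha/rhythm amplitudes ~15%,
#' noise RMS ~10%, spectral slope ~0.05), unless `shared_noise = TRUE`, in
#' which case the two recordings share every draw and differ exactly by the
#' artifact. The `tscs_on` member adds a [gen_tscs_artifact()] realisation
#' to the EEG channels.
#'
#' @param bspec A [background_spec()].
#' @param espec An [erd_spec()] (used when `task = "movement"`).
#' @param profile A [stim_profile()].
#' @param seed Integer seed.
#' @param task `"rest_eyes_open"`, `"rest_eyes_closed"` or `"movement"`.
#' @param duration Rest duration in seconds (ignored for movement).
#' @param n_trials_per_class Movement trials per class.
#' @param fs Sampling rate, Hz.
#' @param oversample_factor Artifact synthesis oversampling.
#' @param shared_noise If `TRUE`, both sessions share the same noise draws.
#' @return List with elements `off` and `on` ([recording()]s).
#' @export
compose_paired_sessions <- function(bspec, espec = erd_spec(), profile,
                                    seed,
                                    task = c("rest_eyes_open",
                                             "rest_eyes_closed", "movement"),
                                    duration = 90, n_trials_per_class = 30,
                                    fs = 1200, oversample_factor = 100,
                                    shared_noise = FALSE) {
  task <- match.arg(task)
  noise_off <- child_seed(seed, 11)
  noise_on <- if (shared_noise) noise_off else child_seed(seed, 12)
  jit_off <- jitter_specs(bspec, espec, child_seed(seed, 21))
  jit_on <- if (shared_noise) jit_off else {
    jitter_specs(bspec, espec, child_seed(seed, 22))
  }
  if (task == "movement") {
    off <- gen_movement_session(jit_off$bspec, jit_off$espec,
                                n_trials_per_class, fs,
                                seed = seed, noise_seed = noise_off)
    on <- gen_movement_session(jit_on$bspec, jit_on$espec,
                               n_trials_per_class, fs,
                               seed = seed, noise_seed = noise_on)
  } else {
    eyes <- if (task == "rest_eyes_closed") "closed" else "open"
    off <- gen_background(jit_off$bspec, duration, fs, eyes, seed = seed,
                          noise_seed = noise_off)
    on <- gen_background(jit_on$bspec, duration, fs, eyes, seed = seed,
                         noise_seed = noise_on)
  }
  art <- gen_tscs_artifact(profile, duration = nrow(on$data) / fs, fs = fs,
                           oversample_factor = oversample_factor,
                           seed = child_seed(seed, 13),
                           channels = eeg_montage())
  eeg <- intersect(rec_channels(on), eeg_montage())
  on$data[, eeg] <- on$data[, eeg] + art$data[seq_len(nrow(on$data)), eeg]
  on$condition <- "tscs_on"
  list(off = off, on = on)
}
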