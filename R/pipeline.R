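# Config-driven end-to-end runs that regenerate the analysis surfaces
# (descriptive-statistics, 30 Hz topography, alpha-frequency and
# classification tables) on a synthetic cohort.

#' Pipeline configuration
#'
#' Bundles the generator specifications, cohort size and seeds that drive
#' [run_resting_analysis()] and [run_movement_analysis()]. The defaults are
#' the study conditions the generator emulates: 21 subjects, 1200 Hz, 90 s
#' resting records, 30 movement trials per class, stimulation at
#' 40 +- 10 mA (truncated to the tolerated 10-60 mA range).
#'
#' @param n_subjects Cohort size.
#' @param base_seed Master seed; every subject-level seed derives from it.
#' @param fs Sampling rate, Hz.
#' @param rest_duration Resting-record length, seconds.
#' @param n_trials_per_class Movement trials per class.
#' @param intensity_mean,intensity_sd Stimulation intensity distribution,
#'   mA.
#' @param bspec,espec,profile Generator specifications; per-subject alpha
#'   frequency and intensity are redrawn around these.
#' @param filters Suppression methods evaluated against the raw conditions.
#' @param half_bandwidth Multitaper half bandwidth, Hz.
#' @param out_dir Optional output directory for CSV/JSON result files.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_subjects = 21, base_seed = 1, fs = 1200,
                            rest_duration = 90, n_trials_per_class = 30,
                            intensity_mean = 40, intensity_sd = 10,
                            bspec = background_spec(), espec = erd_spec(),
                            profile = stim_profile(),
                            filters = c("sma", "adaptive", "median", "notch"),
                            half_bandwidth = 0.1, out_dir = NULL) {
  stopifnot(n_subjects >= 1, base_seed == round(base_seed))
  structure(list(n_subjects = n_subjects, base_seed = as.integer(base_seed),
                 fs = fs, rest_duration = rest_duration,
                 n_trials_per_class = n_trials_per_class,
                 intensity_mean = intensity_mean, intensity_sd = intensity_sd,
                 bspec = bspec, espec = espec, profile = profile,
                 filters = filters, half_bandwidth = half_bandwidth,
                 out_dir = out_dir),
            class = "pipeline_config")
}

subject_params <- function(cfg, s) {
  seed_s <- child_seed(cfg$base_seed, 1000 + s)
  with_seed(seed_s, {
    list(seed = seed_s,
         alpha_freq = stats::runif(1, 8.5, 11.5),
         intensity = min(60, max(10, stats::rnorm(1, cfg$intensity_mean,
                                                  cfg$intensity_sd))),
         # inter-subject sensorimotor-rhythm expression varies widely
         rhythm_scale = exp(stats::rnorm(1, 0, 0.25)))
  })
}

subject_specs <- function(cfg, par) {
  b <- cfg$bspec
  b$alpha_freq <- par$alpha_freq
  p <- cfg$profile
  p$intensity <- par$intensity
  e <- cfg$espec
  e$mu_amp <- e$mu_amp * par$rhythm_scale
  e$beta_amp <- e$beta_amp * par$rhythm_scale
  list(bspec = b, profile = p, espec = e)
}

condition_names <- function(filters) {
  c("tscs_off", "tscs_on", paste0("tscs_on_", filters))
}

# off/on preprocessed variants for one paired session
session_variants <- function(pair, filters) {
  off <- preprocess_recording(pair$off)
  on <- preprocess_recording(pair$on)
  v <- c(list(tscs_off = off, tscs_on = on),
         stats::setNames(lapply(filters, function(m) apply_suppression(on, m)),
                         paste0("tscs_on_", filters)))
  v
}

write_result_csv <- function(out_dir, name, df) {
  if (!is.null(out_dir) && !is.null(df)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
}

#' Resting-state analysis on a synthetic cohort
#'
#' For every simulated subject: paired eyes-open and eyes-closed sessions
#' are generated, preprocessed, and the stimulation-on session is run
#' through each suppression method. Descriptive statistics (eyes open) feed
#' a Scheirer-Ray-Hare condition x electrode test and gated pairwise
#' comparisons at Fz/Oz; 28-32 Hz band power (eyes closed) yields the
#' midline contamination profile with per-channel paired tests; and the
#' individual alpha frequency at Fz/Oz (both eyes states) is compared
#' across conditions with one-way ANOVAs and gated pairwise tests.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of result tables (`descriptives`, `desc_tests`, `srh`,
#'   `profile30`, `profile_tests`, `iaf`, `iaf_tests`, `log`); also written
#'   as CSV under `cfg$out_dir` when set.
#' @export
run_resting_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  conds <- condition_names(cfg$filters)
  mid <- midline_order()$channel
  n_s <- cfg$n_subjects

  stat_names <- c("kurtosis", "rms", "hfd", "zero_crossings")
  desc <- array(NA_real_, c(n_s, length(conds), length(mid), 4),
                dimnames = list(NULL, conds, mid, stat_names))
  pow30 <- array(NA_real_, c(n_s, length(conds), length(mid)),
                 dimnames = list(NULL, conds, mid))
  iaf <- array(NA_real_, c(n_s, length(conds), 2, 2),
               dimnames = list(NULL, conds, c("Fz", "Oz"), c("open", "closed")))
  log <- data.frame()

  for (s in seq_len(n_s)) {
    par <- subject_params(cfg, s)
    sp <- subject_specs(cfg, par)
    log <- rbind(log, data.frame(subject = s, seed = par$seed,
                                 alpha_freq = par$alpha_freq,
                                 intensity = par$intensity))
    for (eyes in c("open", "closed")) {
      task <- paste0("rest_eyes_", eyes)
      pair <- compose_paired_sessions(sp$bspec, sp$espec, sp$profile,
                                      seed = child_seed(par$seed,
                                                        if (eyes == "open") 1 else 2),
                                      task = task,
                                      duration = cfg$rest_duration, fs = cfg$fs)
      # only the midline channels enter the resting analyses
      pair <- list(off = slice_channels(pair$off, mid),
                   on = slice_channels(pair$on, mid))
      vars <- session_variants(pair, cfg$filters)
      for (cond in conds) {
        rec_m <- vars[[cond]]
        if (eyes == "open") {
          for (ch in mid) {
            desc[s, cond, ch, ] <- segment_stats(rec_m$data[, ch], cfg$fs)
          }
          psd2 <- multitaper_psd(slice_channels(rec_m, c("Fz", "Oz")),
                                 cfg$half_bandwidth)
          iaf[s, cond, "Fz", "open"] <- individual_alpha_frequency(psd2, "Fz")
          iaf[s, cond, "Oz", "open"] <- individual_alpha_frequency(psd2, "Oz")
        } else {
          psd <- multitaper_psd(rec_m, cfg$half_bandwidth)
          pow30[s, cond, ] <- band_power(psd, 28, 32)[mid]
          iaf[s, cond, "Fz", "closed"] <- individual_alpha_frequency(psd, "Fz")
          iaf[s, cond, "Oz", "closed"] <- individual_alpha_frequency(psd, "Oz")
        }
      }
    }
  }

  # ---- group tables ----
  desc_mean <- apply(desc, c(2, 3, 4), mean)
  descriptives <- do.call(rbind, lapply(conds, function(cond) {
    data.frame(condition = cond, channel = mid,
               matrix(desc_mean[cond, , ], ncol = 4,
                      dimnames = list(NULL, stat_names)),
               stringsAsFactors = FALSE)
  }))

  # group inference needs at least 3 subjects (normality gate); smaller
  # cohorts (ablation runs) get the tables without tests
  run_tests <- n_s >= 3
  desc_tests <- if (!run_tests) NULL else
    do.call(rbind, lapply(stat_names, function(st) {
    do.call(rbind, lapply(c("Fz", "Oz"), function(ch) {
      cbind(statistic_name = st, channel = ch,
            gated_pairwise(desc[, , ch, st], reference = "tscs_off"))
    }))
  }))

  srh <- if (!run_tests) NULL else
    do.call(rbind, lapply(stat_names, function(st) {
    v <- as.vector(desc[, , , st])
    fa <- rep(rep(conds, each = n_s), times = length(mid))
    fb <- rep(mid, each = n_s * length(conds))
    cbind(statistic_name = st, scheirer_ray_hare(v, fa, fb))
  }))

  off_pow <- matrix(pow30[, "tscs_off", ], nrow = n_s)
  profile30 <- do.call(rbind, lapply(setdiff(conds, "tscs_off"), function(cond) {
    chg <- 100 * (matrix(pow30[, cond, ], nrow = n_s) - off_pow) / off_pow
    data.frame(condition = cond, channel = mid,
               rank = midline_order()$rank,
               change_pct = colMeans(chg), stringsAsFactors = FALSE)
  }))
  profile_tests <- if (!run_tests) NULL else
    do.call(rbind, lapply(mid, function(ch) {
    cbind(channel = ch, gated_pairwise(pow30[, , ch], reference = "tscs_off"))
  }))

  iaf_rows <- list()
  iaf_tests <- list()
  for (ch in c("Fz", "Oz")) {
    for (eyes in c("open", "closed")) {
      m <- matrix(iaf[, , ch, eyes], nrow = n_s, dimnames = list(NULL, conds))
      iaf_rows[[paste(ch, eyes)]] <- data.frame(
        channel = ch, eyes = eyes, condition = conds,
        mean_iaf = colMeans(m), stringsAsFactors = FALSE)
      if (!run_tests) next
      aov_res <- one_way_anova(lapply(conds, function(c2) m[, c2]))
      pw <- gated_pairwise(m, reference = "tscs_off")
      iaf_tests[[paste(ch, eyes)]] <- cbind(channel = ch, eyes = eyes,
                                            rbind(cbind(comparison = "omnibus",
                                                        aov_res[c("test_name", "statistic",
                                                                  "df", "p_value")],
                                                        p_adjusted = NA),
                                                  pw[c("comparison", "test_name",
                                                       "statistic", "df", "p_value",
                                                       "p_adjusted")]))
    }
  }
  iaf_tbl <- do.call(rbind, iaf_rows)
  iaf_tests <- if (run_tests) do.call(rbind, iaf_tests) else NULL
  for (nm in c("descriptives", "desc_tests", "srh", "profile30",
               "profile_tests", "iaf_tbl", "iaf_tests")) {
    v <- get(nm)
    if (!is.null(v)) row.names(v) <- NULL
    assign(nm, v)
  }

  out <- list(descriptives = descriptives, desc_tests = desc_tests, srh = srh,
              profile30 = profile30, profile_tests = profile_tests,
              iaf = iaf_tbl, iaf_tests = iaf_tests, log = log,
              desc_subject = desc, pow30_subject = pow30, iaf_subject = iaf)
  write_result_csv(cfg$out_dir, "resting_descriptives.csv", descriptives)
  write_result_csv(cfg$out_dir, "resting_descriptive_tests.csv", desc_tests)
  write_result_csv(cfg$out_dir, "resting_srh.csv", srh)
  write_result_csv(cfg$out_dir, "midline_30hz.csv", profile30)
  write_result_csv(cfg$out_dir, "midline_30hz_tests.csv", profile_tests)
  write_result_csv(cfg$out_dir, "iaf.csv", iaf_tbl)
  write_result_csv(cfg$out_dir, "iaf_tests.csv", iaf_tests)
  write_result_csv(cfg$out_dir, "resting_run_log.csv", log)
  out
}

#' Movement-classification analysis on a synthetic cohort
#'
#' For every simulated subject: a paired movement session is generated,
#' movement onsets are detected from the EMG envelope, epochs (-2 to 6 s)
#' are cut and cropped to the 0.5-2.5 s classification window, and the
#' CSP-LDA cross-validated accuracy is computed for the stimulation-off,
#' raw stimulation-on, and each filtered variant. Group accuracies are
#' compared against stimulation-off with paired t-tests (BH-adjusted), and
#' the binomial chance level is reported.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `accuracy` (subject x condition matrix), `table`
#'   (summary with p-values), `chance_level_pct`, `log`.
#' @export
run_movement_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  conds <- condition_names(cfg$filters)
  n_s <- cfg$n_subjects
  acc <- matrix(NA_real_, n_s, length(conds), dimnames = list(NULL, conds))
  log <- data.frame()

  for (s in seq_len(n_s)) {
    par <- subject_params(cfg, s)
    sp <- subject_specs(cfg, par)
    pair <- compose_paired_sessions(sp$bspec, sp$espec, sp$profile,
                                    seed = child_seed(par$seed, 3),
                                    task = "movement",
                                    n_trials_per_class = cfg$n_trials_per_class,
                                    fs = cfg$fs)
    # EMG onsets and preprocessing once per session; filters reuse them
    prep <- lapply(pair, function(src) {
      env <- emg_envelope(src)
      env_max <- pmax(env$data[, "EMG_L"], env$data[, "EMG_R"])
      onsets <- vapply(src$events$sample, function(cue) {
        detect_movement_onset(env_max, cfg$fs, onset_params(),
                              search_from = cue,
                              search_to = min(length(env_max),
                                              cue + round(1.5 * cfg$fs)))
      }, integer(1))
      list(eeg = slice_channels(preprocess_recording(src), eeg_montage()),
           onsets = onsets,
           labels = ifelse(src$events$code == 1L, "right_hand", "bimanual"))
    })
    for (cond in conds) {
      side <- if (cond == "tscs_off") prep$off else prep$on
      eeg <- side$eeg
      if (cond != "tscs_off" && cond != "tscs_on") {
        eeg <- apply_suppression(eeg, sub("tscs_on_", "", cond))
      }
      ep <- suppressMessages(epoch_around(eeg, side$onsets, labels = side$labels))
      ep <- classification_window(ep)
      cv <- crossval_accuracy(ep, seed = child_seed(par$seed, 4))
      acc[s, cond] <- cv$mean_acc
    }
    log <- rbind(log, data.frame(subject = s, seed = par$seed,
                                 intensity = par$intensity,
                                 n_trials = 2 * cfg$n_trials_per_class))
  }

  tests <- do.call(rbind, lapply(setdiff(conds, "tscs_off"), function(cond) {
    cbind(comparison = paste(cond, "vs tscs_off"),
          paired_t(acc[, cond], acc[, "tscs_off"]))
  }))
  tests$p_adjusted <- bh_fdr(tests$p_value)
  chance <- binomial_chance_level(cfg$n_trials_per_class)
  tbl <- data.frame(condition = conds,
                    mean_acc = colMeans(acc),
                    sd_acc = apply(acc, 2, stats::sd),
                    p_vs_off = c(NA, tests$p_value),
                    p_adjusted = c(NA, tests$p_adjusted),
                    chance_level_pct = chance,
                    stringsAsFactors = FALSE)
  row.names(tbl) <- row.names(tests) <- NULL
  out <- list(accuracy = acc, table = tbl, tests = tests,
              chance_level_pct = chance, log = log)
  write_result_csv(cfg$out_dir, "movement_accuracy.csv",
                   data.frame(subject = seq_len(n_s), acc))
  write_result_csv(cfg$out_dir, "movement_table.csv", tbl)
  write_result_csv(cfg$out_dir, "movement_run_log.csv", log)
  out
}
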