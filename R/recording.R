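#' Multi-channel recording container
#'
#' The unit of data every pipeline stage consumes and produces: a matrix of
#' samples (rows) by channels (columns) in microvolts, with sampling rate,
#' condition/task metadata and an event list.
#'
#' @param data Numeric matrix, samples x channels, in uV. Column names are
#'   channel labels; if absent, `channels` must be supplied.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Optional character vector of channel labels overriding the
#'   column names of `data`.
#' @param condition `"tscs_off"` or `"tscs_on"`.
#' @param task `"rest_eyes_open"`, `"rest_eyes_closed"` or `"movement"`.
#' @param events Data frame with integer column `sample` (1-based sample
#'   index) and column `code` (integer event code: 1 = right-hand cue,
#'   2 = bimanual cue, 3 = EMG-derived movement onset).
#'
#' @return An object of class `"recording"`: a list with elements `data`,
#'   `fs`, `condition`, `task`, `events`.
#' @export
recording <- function(data, fs, channels = NULL,
                      condition = c("tscs_off", "tscs_on"),
                      task = c("rest_eyes_open", "rest_eyes_closed", "movement"),
                      events = NULL) {
  condition <- match.arg(condition)
  task <- match.arg(task)
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.null(channels)) {
    stopifnot(length(channels) == ncol(data))
    colnames(data) <- channels
  }
  if (is.null(colnames(data)) || ncol(data) == 0) {
    stop("recording: channel labels are required (named columns or `channels`)")
  }
  if (anyDuplicated(colnames(data))) stop("recording: channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("recording: fs must be a positive scalar")
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), code = integer(0))
  }
  stopifnot(is.data.frame(events), all(c("sample", "code") %in% names(events)))
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > nrow(data)))) {
    stop("recording: event sample indices must lie within the signal")
  }
  structure(
    list(data = data, fs = fs, condition = condition, task = task,
         events = events[order(events$sample), , drop = FALSE]),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat(sprintf("  condition: %s  task: %s  events: %d\n",
              x$condition, x$task, nrow(x$events)))
  invisible(x)
}

rec_channels <- function(rec) colnames(rec$data)
rec_duration <- function(rec) nrow(rec$data) / rec$fs

#' Select channels from a recording
#'
#' @param rec A [recording()].
#' @param labels Channel labels to keep; output channel order follows
#'   `labels`. Events and metadata are preserved.
#' @return A [recording()] with the requested channels.
#' @export
slice_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "recording"))
  missing_ch <- setdiff(labels, rec_channels(rec))
  if (length(missing_ch) > 0) {
    stop("slice_channels: unknown channel label(s): ", paste(missing_ch, collapse = ", "))
  }
  recording(rec$data[, labels, drop = FALSE], fs = rec$fs,
            condition = rec$condition, task = rec$task, events = rec$events)
}

# Reorder channels so canonical montage channels come first in montage order,
# followed by any remaining channels (e.g. EMG) in their current order.
canonical_order <- function(labels) {
  canon <- intersect(eeg_montage(), labels)
  c(canon, setdiff(labels, canon))
}

eeg_channel_labels <- function(rec) {
  setdiff(rec_channels(rec), rec_channels(rec)[is_emg_label(rec_channels(rec))])
}

#' Epoched trials container
#'
#' Trials time-locked to movement onset: a trial x channel x sample array
#' with per-trial class labels.
#'
#' @param trials Numeric array, trials x channels x samples (uV). The channel
#'   dimension must carry dimnames.
#' @param fs Sampling rate (Hz).
#' @param t0_offset Time of the first sample of each trial relative to the
#'   alignment event, in seconds (negative = before onset).
#' @param labels Character vector, one of `"right_hand"`/`"bimanual"` per trial.
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(trials, fs, t0_offset, labels) {
  stopifnot(is.array(trials), length(dim(trials)) == 3)
  if (is.null(dimnames(trials)[[2]])) stop("epoch_set: channel dimnames required")
  if (dim(trials)[1] != length(labels)) {
    stop("epoch_set: labels length must equal trial count")
  }
  stopifnot(all(labels %in% c("right_hand", "bimanual")))
  structure(
    list(trials = trials, fs = fs, t0_offset = t0_offset,
         labels = as.character(labels)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (t0 = %+.2f s)\n",
              d[1], d[2], d[3], x$fs, x$t0_offset))
  print(table(x$labels))
  invisible(x)
}

n_trials <- function(ep) dim(ep$trials)[1]
ep_channels <- function(ep) dimnames(ep$trials)[[2]]
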