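# EDF/EDF+ input and output.
#
# Minimal but standard-conformant subset: continuous recordings ("EDF+C"),
# one data record per second, 16-bit samples, and a single "EDF Annotations"
# signal carrying event markers as time-stamped annotation lists (TALs).
# Physical units are normalised to microvolts on read.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# numeric header field: densest representation that survives the 8-char
# ASCII budget without silent truncation (falls back to scientific form)
edf_num <- function(x, width) {
  for (digits in 8:1) {
    s <- formatC(x, format = "fg", digits = digits, width = 1)
    if (nchar(s) <= width && abs(as.numeric(s) - x) <= abs(x) * 1e-6) {
      return(edf_pad(s, width))
    }
  }
  for (digits in 6:1) {
    s <- formatC(x, format = "g", digits = digits, width = 1)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop("write_edf: cannot represent ", x, " in ", width, " characters")
}

#' Write a recording to an EDF+ file
#'
#' Samples are stored as 16-bit integers with a per-channel symmetric
#' physical range covering the data, so the quantisation error is bounded by
#' (physical range) / 2^15 per sample. Events are written as EDF+
#' annotations whose text is the integer event code. The condition/task
#' metadata are stored in the recording-identification header field and
#' recovered by [read_edf()].
#'
#' @param rec A [recording()]; `fs` must be a whole number of Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (ncol(rec$data) == 0) stop("write_edf: recording has no channels")
  if (rec$fs != round(rec$fs)) stop("write_edf: integer sampling rate required")
  if (!all(is.finite(rec$data))) stop("write_edf: non-finite samples are not representable")
  fs <- as.integer(rec$fs)
  n <- nrow(rec$data)
  nch <- ncol(rec$data)
  nrec <- as.integer(ceiling(n / fs))
  # zero-pad the trailing partial record
  dat <- rec$data
  if (nrec * fs > n) dat <- rbind(dat, matrix(0, nrec * fs - n, nch))

  pm <- pmax(apply(abs(dat), 2, max), 1e-6)
  dig <- sweep(dat, 2, pm / 32767, "/")
  dig <- round(dig)
  if (any(abs(dig) > 32767)) stop("write_edf: scaled data exceeds 16-bit range")

  # annotation payload per record: timestamp TAL plus event TALs
  onset_s <- (rec$events$sample - 1) / fs
  ev_rec <- pmin(floor(onset_s), nrec - 1)
  ann <- vapply(seq_len(nrec) - 1L, function(r) {
    tal <- sprintf("+%d\x14\x14", r)
    sel <- which(ev_rec == r)
    for (i in sel) {
      tal <- paste0(tal, sprintf("+%.6f\x14%d\x14", onset_s[i], rec$events$code[i]))
    }
    tal
  }, character(1))
  ann_bytes <- max(60L, max(nchar(ann, type = "bytes")) + 2L)
  if (ann_bytes %% 2L == 1L) ann_bytes <- ann_bytes + 1L
  ann_spr <- ann_bytes %/% 2L

  ns <- nch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad(sprintf("Startdate 01-JAN-2000 cond=%s task=%s", rec$condition, rec$task), 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(header_bytes, 8))
  wr(edf_pad("EDF+C", 44))
  wr(edf_pad(nrec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))

  labels <- c(colnames(dat), "EDF Annotations")
  for (lab in labels) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  wr(paste(vapply(seq_len(nch), function(i) edf_pad("uV", 8), character(1)), collapse = ""))
  wr(edf_pad("", 8))
  for (i in seq_len(nch)) wr(edf_num(-pm[i], 8))
  wr(edf_pad("-1", 8))
  for (i in seq_len(nch)) wr(edf_num(pm[i], 8))
  wr(edf_pad("1", 8))
  # symmetric digital range so a physical zero maps to digital zero exactly
  for (i in seq_len(ns)) wr(edf_pad("-32767", 8))
  for (i in seq_len(ns)) wr(edf_pad("32767", 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(nch)) wr(edf_pad(fs, 8))
  wr(edf_pad(ann_spr, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, , drop = FALSE]), con, size = 2, endian = "little")
    payload <- charToRaw(ann[r])
    writeBin(c(payload, raw(ann_bytes - length(payload))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Channel units are converted to microvolts, channels are reordered to the
#' canonical montage order where their labels match [eeg_montage()], and
#' EDF+ annotations with integer text become event codes.
#'
#' @param path Path to an EDF/EDF+ file.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("read_edf: file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) rawToChar(readBin(con, raw(), width))
  version <- trimws(rd(8))
  if (version != "0") stop("read_edf: not an EDF file (bad version field)")
  rd(80)
  recid <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(trimws(rd(8)))
  rd(44)
  nrec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1) stop("read_edf: malformed header")

  fields <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), character(1))
  labels <- fields(16)
  fields(80)
  units <- fields(8)
  pmin_ <- as.numeric(fields(8))
  pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8))
  dmax_ <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr))) stop("read_edf: malformed signal headers")

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  if (length(sig_idx) == 0) stop("read_edf: no data signals")
  if (length(unique(spr[sig_idx])) != 1) {
    stop("read_edf: unsupported layout - channels with mismatched sampling rates")
  }
  fs <- spr[sig_idx[1]] / rec_dur

  tot <- sum(spr)
  raw_all <- readBin(con, raw(), nrec * tot * 2L)
  if (length(raw_all) < nrec * tot * 2L) stop("read_edf: truncated data section")

  starts <- c(0L, cumsum(spr))  # sample offsets within a record
  rec_off <- (seq_len(nrec) - 1L) * tot
  get_samples <- function(j) {
    idx <- as.vector(outer((starts[j] + seq_len(spr[j])) - 1L, rec_off, "+")) * 2L
    b <- raw_all[as.vector(rbind(idx + 1L, idx + 2L))]
    readBin(b, integer(), n = length(idx), size = 2, endian = "little")
  }

  dat <- matrix(0, nrow = nrec * spr[sig_idx[1]], ncol = length(sig_idx))
  for (k in seq_along(sig_idx)) {
    j <- sig_idx[k]
    d <- get_samples(j)
    # centred form: symmetric ranges map digital zero to physical zero exactly
    scale_j <- (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
    phys <- (d - (dmin_[j] + dmax_[j]) / 2) * scale_j + (pmin_[j] + pmax_[j]) / 2
    scale <- switch(tolower(units[j]), "mv" = 1e3, "v" = 1e6, 1)
    dat[, k] <- phys * scale
  }
  colnames(dat) <- labels[sig_idx]
  dat <- dat[, canonical_order(colnames(dat)), drop = FALSE]

  events <- data.frame(sample = integer(0), code = integer(0))
  if (any(is_ann)) {
    j <- which(is_ann)[1]
    idx <- as.vector(outer((starts[j] + seq_len(spr[j])) - 1L, rec_off, "+")) * 2L
    b <- raw_all[as.vector(rbind(idx + 1L, idx + 2L))]
    txt <- rawToChar(b[b != as.raw(0)])
    tals <- strsplit(txt, "\x14\\+", fixed = FALSE)[[1]]
    for (tal in strsplit(txt, "(?<=\x14)(?=\\+)", perl = TRUE)[[1]]) {
      parts <- strsplit(tal, "\x14")[[1]]
      if (length(parts) < 2) next
      onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[1])))
      code <- suppressWarnings(as.integer(parts[2]))
      if (!is.na(onset) && !is.na(code)) {
        events <- rbind(events, data.frame(sample = round(onset * fs) + 1L, code = code))
      }
    }
  }

  cond <- if (grepl("cond=tscs_on", recid)) "tscs_on" else "tscs_off"
  task <- regmatches(recid, regexpr("task=[a-z_]+", recid))
  task <- if (length(task) == 1) sub("task=", "", task) else "rest_eyes_open"
  if (!task %in% c("rest_eyes_open", "rest_eyes_closed", "movement")) task <- "rest_eyes_open"
  events <- events[events$sample >= 1 & events$sample <= nrow(dat), , drop = FALSE]
  recording(dat, fs = fs, condition = cond, task = task, events = events)
}
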