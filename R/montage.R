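#' Canonical EEG montage
#'
#' The 19-channel subset of the international 10-20 system used throughout
#' this package, in canonical (anterior-to-posterior, left-to-right) order.
#' Every function that produces topographic output orders its channels this
#' way so that tables are directly comparable across runs.
#'
#' @return Character vector of 19 channel labels.
#' @export
eeg_montage <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
    "C3", "C1", "Cz", "C2", "C4",
    "CP3", "CP1", "CPz", "CP2", "CP4",
    "Pz", "POz", "Oz")
}

#' Midline channels ordered by distance from the stimulation site
#'
#' Stimulation is delivered over the posterior cervical spine, so the
#' occipital midline channel Oz is closest to the current source and the
#' frontal channel Fz is farthest. Artifact amplitude decays with this
#' distance, which is the spatial structure all midline analyses exploit.
#'
#' @return Data frame with columns `channel` (Fz ... Oz in montage order) and
#'   `rank` (integer distance rank from the stimulation site; Oz = 0 is most
#'   proximal, Fz = 6 most distal).
#' @export
midline_order <- function() {
  data.frame(
    channel = c("Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz"),
    rank = c(6L, 5L, 4L, 3L, 2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}

# Anterior-posterior distance rank from the stimulation site for every montage
# channel (lateral channels share the rank of their midline row).
ap_rank <- function(channels = eeg_montage()) {
  row_rank <- c(Fz = 6, FC = 5, C = 4, CP = 3, Pz = 2, POz = 1, Oz = 0)
  rank_of <- function(ch) {
    if (ch %in% c("Fz", "Pz", "POz", "Oz")) return(row_rank[[ch]])
    if (grepl("^FC", ch)) return(row_rank[["FC"]])
    if (grepl("^CP", ch)) return(row_rank[["CP"]])
    if (grepl("^C", ch)) return(row_rank[["C"]])
    NA_real_
  }
  vapply(channels, rank_of, numeric(1))
}

is_emg_label <- function(labels) grepl("^EMG", labels)
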