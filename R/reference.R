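#' Reference values from the human-recording study the generator emulates
#'
#' A small table of descriptive values reported for the real 21-subject
#' dataset that this package's synthetic cohort stands in for: Oz
#' peak-to-peak amplitudes with and without stimulation at 10 mA, the Fz
#' zero-crossing rates with and without SMA filtering, and related
#' quantities. These are used for worked-arithmetic checks and generator
#' calibration targets, never as ground truth for the synthetic data.
#'
#' @return Named numeric vector.
#' @export
reference_study_values <- function() {
  path <- system.file("extdata", "reference_study_values.csv",
                      package = "tscseeg", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}
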