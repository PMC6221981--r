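#' Published group-mean ERP peak amplitudes
#'
#' The group-level N2, P3 and N2P3 peak-to-peak mean amplitudes (with SDs,
#' in uV) reported by the study this pipeline models, for each cue condition
#' (Go/NoGo), group (Control/OFC lesion), distractor valence and electrode
#' (F3, F4, C3, C4, P3, P4). Used for arithmetic consistency checks: for
#' rows with self-consistent rounding, \code{p3 - n2} reproduces the printed
#' \code{n2p3} to one decimal.
#'
#' @return Data frame with columns \code{cue}, \code{group},
#'   \code{distractor}, \code{channel}, \code{n2}, \code{n2_sd}, \code{p3},
#'   \code{p3_sd}, \code{n2p3}, \code{n2p3_sd}.
#' @examples
#' tab <- reference_peak_table()
#' with(subset(tab, cue == "Go" & group == "Control" &
#'             distractor == "Emotional" & channel == "F3"),
#'      n2p3_amplitude(n2, p3))  # 6.8
#' @export
reference_peak_table <- function() {
  path <- system.file("extdata", "reference_peak_table.tsv",
                      package = "execrt", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Published behavioural error rates
#'
#' Overall error proportions per group reported by the modelled study
#' (errors of any type, as fractions of all trials), together with the trial
#' counts of the published design. The marginal odds ratio of these rates is
#' the reference value 0.43 (Control vs OFC lesion group).
#'
#' @return Named list with \code{control_rate} (0.021), \code{ofc_rate}
#'   (0.047), \code{trials_per_subject} (1024), \code{n_control} (11
#'   analysed) and \code{n_ofc} (12).
#' @export
reference_error_rates <- function() {
  list(control_rate = 0.021, ofc_rate = 0.047, trials_per_subject = 1024L,
       n_control = 11L, n_ofc = 12L)
}
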