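# End-to-end orchestration: synthetic study -> preprocessing -> ERP features
# -> behavioural scoring -> statistics, under one master seed with a
# checksummed output manifest.

#' Study configuration
#'
#' Collects every tunable of an end-to-end synthetic study run; defaults
#' reproduce the published design (12 patients vs 11 analysed controls, 16
#' blocks of 64 trials, 500 Hz acquisition, the canonical preprocessing
#' parameters and measurement windows).
#'
#' @param n_control,n_ofc Subjects per group. Defaults 11 and 12.
#' @param n_blocks,trials_per_block Schedule size. Defaults 16 and 64.
#' @param fs Acquisition sampling rate, Hz. Default 500.
#' @param noise A \code{noise_model}.
#' @param control_profile,ofc_profile \code{subject_profile}s for the two
#'   groups.
#' @param preprocess A list from \code{\link{preprocess_params}}.
#' @param master_seed Master seed; per-subject, per-stage substreams derive
#'   deterministically from it.
#' @param out_dir Output directory, or \code{NULL} to keep results in
#'   memory only.
#' @return A \code{study_config} list.
#' @export
study_config <- function(n_control = 11L, n_ofc = 12L, n_blocks = 16L,
                         trials_per_block = 64L, fs = 500,
                         noise = noise_model(),
                         control_profile = subject_profile("control_like"),
                         ofc_profile = subject_profile("ofc_like"),
                         preprocess = preprocess_params(),
                         master_seed = 1L, out_dir = NULL) {
  cfg <- list(n_control = as.integer(n_control), n_ofc = as.integer(n_ofc),
              n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block), fs = fs,
              noise = noise, control_profile = control_profile,
              ofc_profile = ofc_profile, preprocess = preprocess,
              master_seed = as.integer(master_seed), out_dir = out_dir)
  class(cfg) <- "study_config"
  cfg
}

# Deterministic substream: subject i, stage s. Kept < 2^31.
substream_seed <- function(master_seed, subject_idx, stage) {
  stage_id <- match(stage, c("schedule", "behavior", "eeg"))
  (as.numeric(master_seed) * 7919 + subject_idx * 104729 + stage_id * 13) %%
    2147483647
}

#' Run a full synthetic study
#'
#' For each simulated subject: generate a schedule, simulate behaviour and
#' EEG, preprocess, apply the minimum-segments rule and extract ERP
#' features. Then pool the cohort: behavioural QC and trial-level error
#' models, the Go and NoGo N2P3 mixed ANOVAs (Group x Emotion x Laterality x
#' Region) and the difference-wave window-mean ANOVAs (Group x Laterality x
#' Region per window). Identical configurations reproduce all numeric
#' outputs exactly.
#'
#' @param config A \code{study_config}.
#' @param verbose Print per-subject progress. Default \code{FALSE}.
#' @return A list with elements \code{behavior} (pooled log),
#'   \code{qc}, \code{error_models} (per dichotomization scheme),
#'   \code{peaks} and \code{window_means} (pooled feature tables),
#'   \code{anova_go}, \code{anova_nogo} (N2P3 peak-to-peak),
#'   \code{anova_windows} (difference-wave window means), \code{erp_pass}
#'   (minimum-segment outcomes) and, when \code{out_dir} is set,
#'   \code{manifest} (file list with checksums).
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  groups <- c(rep("control", cfg$n_control), rep("ofc", cfg$n_ofc))
  profiles <- list(control = cfg$control_profile, ofc = cfg$ofc_profile)
  behavior <- list(); peaks <- list(); wmeans <- list(); erp_pass <- list()

  for (i in seq_along(groups)) {
    sid <- sprintf("%s%02d", substr(groups[i], 1, 1), i)
    if (verbose) message("subject ", sid, " (", groups[i], ")")
    sched <- generate_schedule(cfg$n_blocks, cfg$trials_per_block,
                               seed = substream_seed(cfg$master_seed, i,
                                                     "schedule"))
    beh <- simulate_behavior(sched, profiles[[groups[i]]],
                             seed = substream_seed(cfg$master_seed, i,
                                                   "behavior"))
    beh$subject <- sid
    beh$group <- groups[i]
    behavior[[i]] <- beh
    rec <- simulate_eeg(sched, profiles[[groups[i]]], cfg$noise,
                        fs = cfg$fs,
                        seed = substream_seed(cfg$master_seed, i, "eeg"))
    pp <- tryCatch(preprocess_recording(rec, cfg$preprocess),
                   error = function(e)
                     stop("stage preprocessing failed for subject ", sid,
                          ": ", conditionMessage(e)))
    ms <- enforce_min_segments(pp$epochs, cfg$preprocess$min_segments)
    erp_pass[[sid]] <- ms
    if (!ms$pass) next
    ft <- tryCatch(erp_feature_table(pp$epochs, subject = sid,
                                     group = groups[i],
                                     min_epochs = cfg$preprocess$min_segments),
                   error = function(e)
                     stop("stage erp_features failed for subject ", sid,
                          ": ", conditionMessage(e)))
    peaks[[sid]] <- ft$peaks
    wmeans[[sid]] <- ft$window_means
  }
  behavior <- do.call(rbind, behavior)
  if (!length(peaks))
    stop("stage erp_features: no subject passed the minimum-segment ",
         "criterion (", cfg$preprocess$min_segments, " per condition); ",
         "larger schedules or a lower min_segments are needed")
  peaks <- do.call(rbind, peaks)
  wmeans <- do.call(rbind, wmeans)

  qc <- qc_screen(behavior)
  error_models <- lapply(
    stats::setNames(nm = c("error_vs_correct", "miss_vs_other",
                           "incorrect_vs_other", "commission_vs_correct")),
    function(sch) fit_trial_level_error_model(dichotomize(behavior, sch),
                                              ref_group = "ofc"))

  anova_of_cue <- function(cue) {
    d <- peaks[peaks$cue == cue, ]
    mixed_anova(d, "n2p3", "subject", between = "group",
                within = c("valence", "laterality", "region"))
  }
  anova_go <- anova_of_cue("go")
  anova_nogo <- anova_of_cue("nogo")
  anova_windows <- lapply(split(wmeans, list(wmeans$cue, wmeans$window),
                                sep = " "),
                          function(d)
                            mixed_anova(d, "value", "subject",
                                        between = "group",
                                        within = c("laterality", "region")))

  results <- list(behavior = behavior, qc = qc, error_models = error_models,
                  peaks = peaks, window_means = wmeans,
                  anova_go = anova_go, anova_nogo = anova_nogo,
                  anova_windows = anova_windows, erp_pass = erp_pass,
                  config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      behavior = file.path(cfg$out_dir, "behavior.tsv"),
      peaks = file.path(cfg$out_dir, "erp_peaks.tsv"),
      window_means = file.path(cfg$out_dir, "window_means.tsv"),
      anova_go = file.path(cfg$out_dir, "anova_go.tsv"),
      anova_nogo = file.path(cfg$out_dir, "anova_nogo.tsv"))
    write_feature_table(behavior, paths[["behavior"]])
    write_feature_table(peaks, paths[["peaks"]])
    write_feature_table(wmeans, paths[["window_means"]])
    write_feature_table(as.data.frame(anova_go), paths[["anova_go"]])
    write_feature_table(as.data.frame(anova_nogo), paths[["anova_nogo"]])
    manifest <- data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
    manifest_meta <- list(package_version =
                            as.character(utils::packageVersion("execrt")),
                          master_seed = cfg$master_seed,
                          n_control = cfg$n_control, n_ofc = cfg$n_ofc,
                          files = manifest)
    jsonlite::write_json(manifest_meta,
                         file.path(cfg$out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    results$manifest <- manifest
  }
  results
}
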