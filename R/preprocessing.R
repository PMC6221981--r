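# Continuous-recording container and the preprocessing chain, applied in the
# fixed order: downsample -> 0.01-70 Hz band-pass -> blink removal -> jump
# rejection -> linked-earlobe re-reference -> 0.01-30 Hz band-pass ->
# segmentation with baseline correction.

#' Construct a continuous EEG recording
#'
#' @param samples Numeric matrix, channels x time, in uV; rownames are the
#'   channel labels (10-20 names plus \code{A1}, \code{A2} earlobes and an
#'   \code{EOG} proxy channel).
#' @param fs Sampling rate, Hz.
#' @param markers Data frame with integer \code{sample} (1-based index,
#'   strictly increasing, in range) and integer \code{code} (see
#'   \code{\link{condition_codes}}).
#' @param history Character vector of processing stages already applied.
#' @return An object of class \code{eeg_recording} with elements
#'   \code{samples}, \code{fs}, \code{channel_names}, \code{markers},
#'   \code{bad_intervals} (data frame of annotated bad sample ranges) and
#'   \code{history}.
#' @export
eeg_recording <- function(samples, fs, markers = NULL, history = character()) {
  stopifnot(is.matrix(samples), fs > 0, !is.null(rownames(samples)))
  if (is.null(markers))
    markers <- data.frame(sample = integer(), code = integer())
  stopifnot(all(diff(markers$sample) > 0),
            all(markers$sample >= 1), all(markers$sample <= ncol(samples)))
  structure(list(samples = samples, fs = fs,
                 channel_names = rownames(samples), markers = markers,
                 bad_intervals = data.frame(start = integer(),
                                            end = integer(),
                                            reason = character()),
                 history = history),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("  markers: %d, bad intervals: %d\n", nrow(x$markers),
              nrow(x$bad_intervals)))
  if (length(x$history)) cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase 8th-order Butterworth low-pass at 80\% of the target
#' Nyquist frequency, then decimates by the integer ratio. Markers are
#' remapped to the nearest retained sample.
#'
#' @param rec An \code{eeg_recording}.
#' @param target_fs Target sampling rate, Hz (must divide \code{rec$fs}).
#'   Default 250.
#' @return The downsampled \code{eeg_recording}.
#' @export
downsample <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs == target_fs) return(rec)
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fs = ", rec$fs, " is not an integer multiple of target_fs = ",
         target_fs, "; resampling by rational ratios is not supported")
  ratio <- as.integer(round(ratio))
  filtered <- apply_channelwise(rec$samples, function(x)
    zero_phase_butter(x, 0.8 * target_fs / 2, rec$fs, "low", order = 8L))
  keep <- seq(1L, ncol(filtered), by = ratio)
  out <- rec
  out$samples <- filtered[, keep, drop = FALSE]
  out$fs <- target_fs
  out$markers$sample <- (rec$markers$sample - 1L) %/% ratio + 1L
  out$history <- c(rec$history, sprintf("downsample(%g)", target_fs))
  out
}

#' Zero-phase IIR band-pass filter
#'
#' Cascades a high-pass at \code{low} Hz and a low-pass at \code{high} Hz
#' (Butterworth, \code{order}th order each), both applied forward-backward so
#' the net phase shift is zero. Channels are de-meaned first so the extreme
#' 0.01 Hz high-pass edge does not ring on a DC offset.
#'
#' @param rec An \code{eeg_recording}.
#' @param low,high Corner frequencies, Hz; \code{0 < low < high < fs/2}.
#' @param order Butterworth order per edge (even). Default 4.
#' @return The filtered \code{eeg_recording}.
#' @export
bandpass <- function(rec, low, high, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("invalid corner frequencies: need 0 < low < high < fs/2")
  out <- rec
  out$samples <- apply_channelwise(rec$samples, function(x) {
    x <- x - mean(x)
    zero_phase_butter(zero_phase_butter(x, low, rec$fs, "high", order),
                      high, rec$fs, "low", order)
  })
  out$history <- c(rec$history, sprintf("bandpass(%g-%g)", low, high))
  out
}

#' Remove blink artifacts by EOG regression
#'
#' Default stand-in for ICA-based ocular correction: each EEG channel has its
#' least-squares projection onto the EOG-proxy channel subtracted
#' (\code{beta = cov(channel, EOG) / var(EOG)}). \code{method =
#' "passthrough"} returns the input unchanged (hook for plugging in other
#' removal schemes).
#'
#' @param rec An \code{eeg_recording}.
#' @param method \code{"regression"} or \code{"passthrough"}.
#' @param eog_channel Name of the EOG proxy channel. Default \code{"EOG"}.
#' @return The corrected \code{eeg_recording}.
#' @export
remove_blinks <- function(rec, method = c("regression", "passthrough"),
                          eog_channel = "EOG") {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  out <- rec
  if (method == "regression") {
    if (!eog_channel %in% rec$channel_names)
      stop("EOG-proxy channel '", eog_channel,
           "' not present; cannot regress out blinks")
    eog <- rec$samples[eog_channel, ] - mean(rec$samples[eog_channel, ])
    v <- sum(eog^2)
    if (v > 0) {
      for (ch in setdiff(rec$channel_names, eog_channel)) {
        x <- rec$samples[ch, ]
        beta <- sum((x - mean(x)) * eog) / v
        out$samples[ch, ] <- x - beta * eog
      }
    }
  }
  out$history <- c(rec$history, sprintf("remove_blinks(%s)", method))
  out
}

# Rolling max over a trailing window of k samples (doubling trick, O(n log k))
rolling_max <- function(x, k) {
  trail <- function(m, s) pmax(m, c(rep(-Inf, s), m[seq_len(length(m) - s)]))
  m <- x
  span <- 1L
  while (2L * span <= k) {
    m <- trail(m, span)
    span <- 2L * span
  }
  if (span < k) m <- trail(m, k - span)
  m
}

#' Annotate voltage-jump artifacts (> 100 uV rule)
#'
#' Flags intervals in which the signal differs from its surroundings by more
#' than \code{threshold} on any channel (earlobe and EOG channels excluded).
#' The criterion is the peak-to-peak voltage difference (max minus min)
#' within a sliding 200 ms window — the "maximal difference of values in
#' intervals" check of standard ERP software, which catches step artifacts
#' of any duration at their transitions. Flagged windows are expanded by a
#' +/-200 ms guard band and merged into bad intervals; epochs overlapping a
#' bad interval are dropped at segmentation.
#'
#' @param rec An \code{eeg_recording}.
#' @param threshold Rejection threshold, uV. Default 100.
#' @param exclude Channels not scanned (reference/EOG). Default
#'   \code{c("A1", "A2", "EOG")}.
#' @return The \code{eeg_recording} with \code{bad_intervals} filled in
#'   (columns \code{start}, \code{end} in samples, \code{reason}).
#' @export
reject_jump_artifacts <- function(rec, threshold = 100,
                                  exclude = c("A1", "A2", "EOG")) {
  stopifnot(inherits(rec, "eeg_recording"), threshold > 0)
  k <- as.integer(round(0.2 * rec$fs))  # 200 ms window
  guard <- as.integer(round(0.2 * rec$fs))
  n <- ncol(rec$samples)
  bad_end <- logical(n)  # window end positions whose range exceeds threshold
  for (ch in setdiff(rec$channel_names, exclude)) {
    x <- rec$samples[ch, ]
    rng <- rolling_max(x, k) + rolling_max(-x, k)
    bad_end <- bad_end | (rng > threshold)
  }
  out <- rec
  if (any(bad_end)) {
    idx <- which(bad_end)
    starts <- pmax(1L, idx - (k - 1L) - guard)  # cover the whole window
    ends <- pmin(n, idx + guard)
    # merge overlapping guard-banded intervals
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    merged_s <- starts[1]; merged_e <- ends[1]
    ms <- integer(); me <- integer()
    for (i in seq_along(starts)[-1]) {
      if (starts[i] <= merged_e + 1L) {
        merged_e <- max(merged_e, ends[i])
      } else {
        ms <- c(ms, merged_s); me <- c(me, merged_e)
        merged_s <- starts[i]; merged_e <- ends[i]
      }
    }
    ms <- c(ms, merged_s); me <- c(me, merged_e)
    out$bad_intervals <- data.frame(start = ms, end = me,
                                    reason = "jump>threshold",
                                    stringsAsFactors = FALSE)
  }
  out$history <- c(rec$history, sprintf("reject_jumps(%g)", threshold))
  out
}

#' Re-reference to linked earlobes
#'
#' Subtracts the mean of the two earlobe channels \code{A1} and \code{A2}
#' from every channel. After re-referencing, (A1 + A2)/2 is identically
#' zero, and the operation is idempotent.
#'
#' @param rec An \code{eeg_recording} containing channels \code{A1} and
#'   \code{A2}.
#' @return The re-referenced \code{eeg_recording}.
#' @export
rereference_linked_earlobes <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(c("A1", "A2") %in% rec$channel_names))
    stop("earlobe channels A1/A2 not present; cannot re-reference")
  ref <- (rec$samples["A1", ] + rec$samples["A2", ]) / 2
  out <- rec
  out$samples <- sweep(rec$samples, 2, ref, "-")
  out$history <- c(rec$history, "rereference_linked_earlobes")
  out
}

#' Segment a recording into baseline-corrected epochs
#'
#' Cuts one epoch per event marker on the closed window \code{window} ms
#' around trial onset (default -200..+1800 ms; 501 samples at 250 Hz) and
#' subtracts the per-channel mean of the baseline interval (default the
#' closed interval -200..0 ms). Epochs overlapping an annotated bad interval,
#' or without full window support inside the recording, are dropped (kept +
#' dropped = number of markers).
#'
#' @param rec An \code{eeg_recording} (markers and, if jump rejection ran,
#'   bad intervals present).
#' @param window Length-2 numeric, epoch window in ms relative to onset.
#' @param baseline Length-2 numeric, baseline interval in ms.
#' @return An object of class \code{epoch_set}: list with \code{data}
#'   (epochs x channels x time array, all markers), \code{time_ms} (time
#'   axis), \code{condition} (per-epoch label), \code{kept} (logical: epoch
#'   survived), \code{fs}, \code{channel_names}.
#' @export
segment_and_baseline <- function(rec, window = c(-200, 1800),
                                 baseline = c(-200, 0)) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[1] < 0, window[2] > 0)
  step <- 1000 / rec$fs
  rel <- seq(round(window[1] / step), round(window[2] / step))
  time_ms <- rel * step
  n_ep <- nrow(rec$markers)
  n_ch <- nrow(rec$samples)
  n_t <- length(rel)
  data <- array(NA_real_, c(n_ep, n_ch, n_t),
                dimnames = list(NULL, rec$channel_names, NULL))
  kept <- rep(TRUE, n_ep)
  bi <- rec$bad_intervals
  bsel <- time_ms >= baseline[1] & time_ms <= baseline[2]
  for (i in seq_len(n_ep)) {
    idx <- rec$markers$sample[i] + rel
    if (idx[1] < 1 || idx[n_t] > ncol(rec$samples)) {
      kept[i] <- FALSE
      next
    }
    if (nrow(bi) && any(bi$start <= idx[n_t] & bi$end >= idx[1])) {
      kept[i] <- FALSE
      next
    }
    ep <- rec$samples[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, bsel, drop = FALSE])
    data[i, , ] <- ep
  }
  codes <- condition_codes()
  cond <- codes$condition[match(rec$markers$code, codes$code)]
  structure(list(data = data, time_ms = time_ms, condition = cond,
                 kept = kept, fs = rec$fs,
                 channel_names = rec$channel_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d channels x %d samples @ %g Hz\n",
              length(x$kept), sum(x$kept), dim(x$data)[2], dim(x$data)[3],
              x$fs))
  print(table(condition = x$condition[x$kept]))
  invisible(x)
}

#' Minimum-segment criterion per condition
#'
#' A subject is excluded from ERP analysis if any of the four conditions has
#' fewer than \code{minimum} artifact-free epochs (boundary inclusive: a
#' count of exactly \code{minimum} passes).
#'
#' @param epochs An \code{epoch_set}.
#' @param minimum Minimum kept epochs per condition. Default 50.
#' @return List with \code{counts} (named kept-epoch counts over the four
#'   conditions) and logical \code{pass}.
#' @export
enforce_min_segments <- function(epochs, minimum = 50L) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- condition_codes()$condition
  counts <- vapply(conds, function(cc) sum(epochs$kept & epochs$condition == cc),
                   integer(1))
  list(counts = counts, pass = all(counts >= minimum))
}

#' Run the full preprocessing chain in the canonical order
#'
#' Fixed stage order: downsample to 250 Hz, 0.01--70 Hz band-pass, blink
#' removal, voltage-jump rejection (100 uV rule), linked-earlobe
#' re-reference, 0.01--30 Hz band-pass, segmentation (-200..+1800 ms) with
#' baseline correction over -200..0 ms.
#'
#' @param rec An \code{eeg_recording}.
#' @param params A list as produced by \code{\link{preprocess_params}}.
#' @return A list with \code{epochs} (the \code{epoch_set}),
#'   \code{recording} (the preprocessed continuous recording) and
#'   \code{bad_intervals}.
#' @export
preprocess_recording <- function(rec, params = preprocess_params()) {
  p <- params
  rec <- downsample(rec, p$target_fs)
  rec <- bandpass(rec, p$wide_band[1], p$wide_band[2], p$filter_order)
  rec <- remove_blinks(rec, p$blink_method)
  rec <- reject_jump_artifacts(rec, p$jump_threshold)
  rec <- rereference_linked_earlobes(rec)
  rec <- bandpass(rec, p$narrow_band[1], p$narrow_band[2], p$filter_order)
  expected <- c("downsample", "bandpass", "remove_blinks", "reject_jumps",
                "rereference_linked_earlobes", "bandpass")
  got <- sub("\\(.*", "", utils::tail(rec$history, length(expected)))
  stopifnot(identical(got, expected))  # stage-order invariant
  epochs <- segment_and_baseline(rec, p$epoch_window, p$baseline_window)
  list(epochs = epochs, recording = rec, bad_intervals = rec$bad_intervals)
}

#' Preprocessing parameters (defaults follow the published pipeline)
#'
#' @param target_fs Analysis sampling rate, Hz (250).
#' @param wide_band First band-pass, Hz (0.01--70).
#' @param narrow_band Pre-segmentation band-pass, Hz (0.01--30).
#' @param filter_order Butterworth order per edge (4).
#' @param blink_method \code{"regression"} or \code{"passthrough"}.
#' @param jump_threshold Voltage-difference rejection threshold, uV (100).
#' @param epoch_window Epoch window, ms (-200..1800).
#' @param baseline_window Baseline interval, ms (-200..0).
#' @param min_segments Minimum kept epochs per condition (50).
#' @return Named list of parameters.
#' @export
preprocess_params <- function(target_fs = 250, wide_band = c(0.01, 70),
                              narrow_band = c(0.01, 30), filter_order = 4L,
                              blink_method = "regression",
                              jump_threshold = 100,
                              epoch_window = c(-200, 1800),
                              baseline_window = c(-200, 0),
                              min_segments = 50L) {
  list(target_fs = target_fs, wide_band = wide_band,
       narrow_band = narrow_band, filter_order = filter_order,
       blink_method = blink_method, jump_threshold = jump_threshold,
       epoch_window = epoch_window, baseline_window = baseline_window,
       min_segments = min_segments)
}

#' Export bad-interval annotations as delimited text
#'
#' @param rec An \code{eeg_recording} with annotations.
#' @param path Output file (tab-separated: start_ms, end_ms, reason).
#' @export
write_bad_intervals <- function(rec, path) {
  bi <- rec$bad_intervals
  out <- data.frame(start_ms = (bi$start - 1) / rec$fs * 1000,
                    end_ms = (bi$end - 1) / rec$fs * 1000,
                    reason = bi$reason)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
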