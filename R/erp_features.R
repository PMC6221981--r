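# Condition ERPs and scalar features: windowed N2/P3 peaks (mean around the
# extremum +/-5 time points), N2P3 peak-to-peak amplitudes, emotional-minus-
# neutral difference waveforms and fixed 100-ms window means.

#' The fixed electrode set and its laterality x region mapping
#'
#' Six electrodes enter the statistics: one frontal, central and parietal
#' site over each hemisphere.
#'
#' @return Data frame with columns \code{channel}, \code{laterality}
#'   (\code{left}/\code{right}) and \code{region}
#'   (\code{frontal}/\code{central}/\code{parietal}).
#' @export
roi_channels <- function() {
  data.frame(
    channel = c("F3", "F4", "C3", "C4", "P3", "P4"),
    laterality = c("left", "right", "left", "right", "left", "right"),
    region = rep(c("frontal", "central", "parietal"), each = 2),
    stringsAsFactors = FALSE
  )
}

#' Measurement windows for the ERP components (ms from trial onset)
#'
#' N2: most negative peak in 450--670 ms; P3: most positive peak in
#' 600--900 ms (i.e. 150--370 and 300--600 ms from the response cue, which
#' appears 300 ms after trial onset).
#'
#' @param component \code{"N2"} or \code{"P3"}.
#' @return Length-2 numeric window in ms.
#' @export
component_window <- function(component = c("N2", "P3")) {
  switch(match.arg(component), N2 = c(450, 670), P3 = c(600, 900))
}

#' Average kept epochs of one condition into an ERP waveform
#'
#' @param epochs An \code{epoch_set}.
#' @param condition One of \code{"GoEmotional"}, \code{"GoNeutral"},
#'   \code{"NoGoEmotional"}, \code{"NoGoNeutral"}.
#' @param min_epochs Refuse (with an exclusion-flag error) if fewer kept
#'   epochs than this are available. Default 50, the published cut-off;
#'   lower it for small synthetic examples.
#' @return An \code{erp_waveform}: list with \code{values} (channels x time
#'   matrix, uV), \code{time_ms}, \code{condition}, \code{n_epochs},
#'   \code{channel_names}, \code{fs}.
#' @export
average_condition <- function(epochs, condition, min_epochs = 50L) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- which(epochs$kept & epochs$condition == condition)
  if (length(sel) < min_epochs)
    stop("excluded-for-ERP: condition ", condition, " has ", length(sel),
         " kept epochs (< ", min_epochs, ")")
  values <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(values) <- epochs$channel_names
  structure(list(values = values, time_ms = epochs$time_ms,
                 condition = condition, n_epochs = length(sel),
                 channel_names = epochs$channel_names, fs = epochs$fs),
            class = "erp_waveform")
}

#' Construct an ERP waveform directly from a matrix
#'
#' Mostly for tests and synthetic ground truth.
#' @param values Channels x time matrix (rownames = channels), uV.
#' @param time_ms Time axis, ms from trial onset.
#' @param condition Label.
#' @param n_epochs Number of epochs averaged. Default 1.
#' @return An \code{erp_waveform}.
#' @export
erp_waveform <- function(values, time_ms, condition = "", n_epochs = 1L) {
  stopifnot(is.matrix(values), ncol(values) == length(time_ms),
            !is.null(rownames(values)))
  fs <- 1000 / mean(diff(time_ms))
  structure(list(values = values, time_ms = time_ms, condition = condition,
                 n_epochs = n_epochs, channel_names = rownames(values),
                 fs = fs),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s: %d channels, %d samples (%g..%g ms), n = %d\n",
              x$condition, nrow(x$values), length(x$time_ms),
              min(x$time_ms), max(x$time_ms), x$n_epochs))
  invisible(x)
}

#' Detect a windowed ERP peak and its +/-5-sample mean amplitude
#'
#' Finds the most negative (N2) or most positive (P3) sample within the
#' component's search window; ties break toward the earlier latency. The
#' reported amplitude is the mean of the waveform over the detected extremum
#' +/-5 time points (+/-20 ms at 250 Hz), truncated at the epoch edges.
#'
#' @param erp An \code{erp_waveform}.
#' @param channel Channel label.
#' @param component \code{"N2"} or \code{"P3"}.
#' @param window Optional length-2 search window in ms; defaults to the
#'   component's canonical window (\code{\link{component_window}}).
#' @param halfwidth Samples averaged on each side of the peak. Default 5.
#' @return A \code{peak_measure}: list with \code{component}, \code{channel},
#'   \code{latency} (ms), \code{amplitude} (uV), \code{search_window}.
#' @export
detect_peak <- function(erp, channel, component = c("N2", "P3"),
                        window = NULL, halfwidth = 5L) {
  stopifnot(inherits(erp, "erp_waveform"))
  component <- match.arg(component)
  if (!channel %in% rownames(erp$values))
    stop("channel '", channel, "' absent from waveform")
  if (is.null(window)) window <- component_window(component)
  in_win <- which(erp$time_ms >= window[1] & erp$time_ms <= window[2])
  if (!length(in_win)) stop("search window outside time axis")
  x <- erp$values[channel, ]
  xw <- x[in_win]
  pick <- if (component == "N2") which.min(xw) else which.max(xw)
  # which.min/max already take the first (earliest) index on ties
  peak_idx <- in_win[pick]
  lo <- max(1L, peak_idx - halfwidth)
  hi <- min(length(x), peak_idx + halfwidth)
  structure(list(component = component, channel = channel,
                 latency = erp$time_ms[peak_idx],
                 amplitude = mean(x[lo:hi]),
                 search_window = window),
            class = "peak_measure")
}

#' N2P3 peak-to-peak amplitude
#'
#' The attention biomarker: P3 peak amplitude minus N2 peak amplitude for a
#' given electrode.
#'
#' @param n2,p3 \code{peak_measure} objects for the same channel (or bare
#'   numeric amplitudes in uV).
#' @return Peak-to-peak amplitude in uV.
#' @examples
#' n2p3_amplitude(-5.3, 1.5)   # 6.8
#' @export
n2p3_amplitude <- function(n2, p3) {
  if (inherits(n2, "peak_measure") && inherits(p3, "peak_measure")) {
    if (!identical(n2$channel, p3$channel))
      stop("channel mismatch: N2 at ", n2$channel, ", P3 at ", p3$channel)
    return(p3$amplitude - n2$amplitude)
  }
  stopifnot(is.numeric(n2), is.numeric(p3))
  p3 - n2
}

#' Emotional-minus-neutral difference waveform
#'
#' Pointwise subtraction isolating the effect of emotional valence with all
#' purely visual components cancelled (the two distractors share identical
#' line elements).
#'
#' @param emotional,neutral \code{erp_waveform}s of the same cue condition on
#'   the same time axis.
#' @return An \code{erp_waveform} of the difference.
#' @export
difference_wave <- function(emotional, neutral) {
  stopifnot(inherits(emotional, "erp_waveform"),
            inherits(neutral, "erp_waveform"))
  if (!isTRUE(all.equal(emotional$time_ms, neutral$time_ms)) ||
      !identical(rownames(emotional$values), rownames(neutral$values)))
    stop("mismatched time axes or channels")
  erp_waveform(emotional$values - neutral$values, emotional$time_ms,
               condition = paste0(emotional$condition, "-",
                                  neutral$condition),
               n_epochs = min(emotional$n_epochs, neutral$n_epochs))
}

#' Mean amplitude over a fixed time window
#'
#' Arithmetic mean over all samples whose time lies in the closed interval
#' \code{window}; a sample on a shared boundary (e.g. 700 ms) belongs to both
#' adjacent windows.
#'
#' @param wave An \code{erp_waveform} (typically a difference waveform).
#' @param channel Channel label.
#' @param window Length-2 numeric, ms (one of (600,700), (700,800),
#'   (800,900) in the published analysis).
#' @return Mean amplitude, uV.
#' @export
window_mean <- function(wave, channel, window) {
  stopifnot(inherits(wave, "erp_waveform"), length(window) == 2)
  if (!channel %in% rownames(wave$values))
    stop("channel '", channel, "' absent from waveform")
  sel <- wave$time_ms >= window[1] & wave$time_ms <= window[2]
  if (!any(sel)) stop("window outside time axis")
  mean(wave$values[channel, sel])
}

#' Tidy ERP feature table for one subject
#'
#' Computes, per condition and electrode, the N2 and P3 peak measures and
#' the N2P3 peak-to-peak amplitude, plus the emotional-minus-neutral
#' difference-wave means in the three 100-ms windows, keyed by laterality
#' and region. This is the direct input to the statistics engine.
#'
#' @param epochs An \code{epoch_set} for one subject.
#' @param subject Subject identifier.
#' @param group Group label.
#' @param min_epochs Passed to \code{\link{average_condition}}.
#' @return List with data frames \code{peaks} (subject, group, cue, valence,
#'   channel, laterality, region, n2, n2_latency, p3, p3_latency, n2p3) and
#'   \code{window_means} (subject, group, cue, channel, laterality, region,
#'   window, value).
#' @export
erp_feature_table <- function(epochs, subject = "s1", group = "control",
                              min_epochs = 50L) {
  roi <- roi_channels()
  codes <- condition_codes()
  erps <- lapply(stats::setNames(codes$condition, codes$condition),
                 function(cc) average_condition(epochs, cc, min_epochs))
  peaks <- do.call(rbind, lapply(seq_len(nrow(codes)), function(i) {
    cc <- codes$condition[i]
    do.call(rbind, lapply(seq_len(nrow(roi)), function(j) {
      n2 <- detect_peak(erps[[cc]], roi$channel[j], "N2")
      p3 <- detect_peak(erps[[cc]], roi$channel[j], "P3")
      data.frame(subject = subject, group = group, cue = codes$cue[i],
                 valence = codes$distractor[i], channel = roi$channel[j],
                 laterality = roi$laterality[j], region = roi$region[j],
                 n2 = n2$amplitude, n2_latency = n2$latency,
                 p3 = p3$amplitude, p3_latency = p3$latency,
                 n2p3 = n2p3_amplitude(n2, p3),
                 stringsAsFactors = FALSE)
    }))
  }))
  windows <- list(c(600, 700), c(700, 800), c(800, 900))
  wm <- do.call(rbind, lapply(c("go", "nogo"), function(cue) {
    emo <- erps[[codes$condition[codes$cue == cue &
                                   codes$distractor == "emotional"]]]
    neu <- erps[[codes$condition[codes$cue == cue &
                                   codes$distractor == "neutral"]]]
    dw <- difference_wave(emo, neu)
    do.call(rbind, lapply(windows, function(w) {
      do.call(rbind, lapply(seq_len(nrow(roi)), function(j) {
        data.frame(subject = subject, group = group, cue = cue,
                   channel = roi$channel[j], laterality = roi$laterality[j],
                   region = roi$region[j],
                   window = sprintf("%d-%d", w[1], w[2]),
                   value = window_mean(dw, roi$channel[j], w),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  list(peaks = peaks, window_means = wm)
}

#' Write a tidy feature table as delimited text
#' @param table A data frame.
#' @param path Output path (tab-separated).
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
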