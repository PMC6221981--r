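# Continuous-EEG generator with known ground truth: per-trial Gaussian ERP
# components under condition-dependent emotional modulation, 1/f + white
# background, blink and voltage-jump artifacts, near-silent earlobe
# reference channels and sample-exact event markers.

#' Default simulated montage
#'
#' The nine channels the analysis pipeline touches: the six statistical
#' electrodes, the two earlobe references and an EOG proxy. A fuller montage
#' can be passed to \code{\link{simulate_eeg}}; extra channels carry noise
#' only.
#' @return Character vector of channel labels.
#' @export
default_montage <- function()
  c("F3", "F4", "C3", "C4", "P3", "P4", "A1", "A2", "EOG")

gauss_pulse <- function(t_ms, lat, width) exp(-((t_ms - lat)^2) / (2 * width^2))

# Injected component amplitude for (component, channel, condition)
component_amplitude <- function(profile, comp_name, channel, cue, distractor) {
  co <- profile$components[[comp_name]]
  w <- co$topo[channel]
  amp <- co$amp * ifelse(is.na(w), 0, w)
  if (distractor == "emotional") {
    m <- profile$modulation
    hit <- m$cue == cue & m$component == comp_name & m$channel == channel
    if (any(hit)) amp <- amp + sum(m$delta[hit])
  }
  unname(amp)
}

# Clean (noiseless) epoch waveform for one condition on an arbitrary grid
clean_condition_waveform <- function(profile, cue, distractor, channels,
                                     time_ms) {
  vals <- matrix(0, length(channels), length(time_ms),
                 dimnames = list(channels, NULL))
  for (comp_name in names(profile$components)) {
    co <- profile$components[[comp_name]]
    pulse <- gauss_pulse(time_ms, co$lat, co$width)
    for (ch in channels) {
      a <- component_amplitude(profile, comp_name, ch, cue, distractor)
      if (a != 0) vals[ch, ] <- vals[ch, ] + a * pulse
    }
  }
  vals
}

# 1/f-shaped noise via spectral shaping of white Gaussian noise
pink_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  f <- c(1, seq_len(m - 1))  # avoid division by zero at DC
  shape <- 1 / sqrt(pmin(f, m - f + 1))
  y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y * sd / stats::sd(y)
}

#' Simulate a continuous EEG recording for one subject
#'
#' Renders the trial schedule into a multichannel recording: every trial
#' contributes the profile's ERP components (Gaussian in time, peaks placed
#' inside their measurement windows: N2 in 450--670 ms, P3 in 600--900 ms,
#' LPP sustained around 700--900 ms from trial onset), with the profile's
#' emotional modulation added at its effect sites on emotional trials.
#' Background is independent white + 1/f noise per channel; blinks
#' (frontally weighted half-sines, mirrored on the EOG proxy) and > 100 uV
#' voltage jumps occur at the modelled rates. Earlobe channels A1/A2 carry
#' attenuated noise only. Event markers align sample-exactly with trial
#' onsets.
#'
#' A ground-truth sidecar is attached as \code{attr(rec, "ground_truth")}:
#' injected amplitudes per condition/channel/component, the blink and jump
#' injection log, and the *expected* feature values (N2/P3 peak means, N2P3,
#' difference-wave window means) obtained by evaluating the clean parametric
#' waveform on the 250 Hz analysis grid — the reference for parameter-
#' recovery tests.
#'
#' @param schedule A \code{trial_schedule}.
#' @param profile A \code{subject_profile}.
#' @param noise A \code{noise_model}; use \code{noise_model_silent()} for
#'   noiseless ground-truth runs.
#' @param fs Sampling rate, Hz (>= 250). Default 500.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param channels Montage. Default \code{\link{default_montage}}.
#' @param start_offset_s Quiet lead-in/out, s. Default 2.
#' @return An \code{eeg_recording} with markers and ground-truth attribute.
#' @export
simulate_eeg <- function(schedule, profile, noise = noise_model(),
                         fs = 500, seed = 1L, channels = default_montage(),
                         start_offset_s = 2) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(profile, "subject_profile"),
            inherits(noise, "noise_model"), fs >= 250)
  iti_ms <- attr(schedule, "iti_ms")
  comp_end <- max(vapply(profile$components,
                         function(co) co$lat + 4 * co$width, numeric(1)))
  if (iti_ms < max(comp_end, 1800))
    stop("trials overlap: inter-trial interval ", iti_ms,
         " ms is shorter than the component support / epoch span")
  n_trials <- nrow(schedule)
  onset_samp <- as.integer(round(start_offset_s * fs)) + 1L +
    as.integer(round((seq_len(n_trials) - 1) * iti_ms / 1000 * fs))
  n_samp <- onset_samp[n_trials] +
    as.integer(round((iti_ms / 1000 + start_offset_s) * fs))
  n_ch <- length(channels)
  eeg_ch <- setdiff(channels, c("A1", "A2", "EOG"))

  codes <- condition_codes()
  code_of <- codes$code[match(paste(schedule$cue, schedule$distractor),
                              paste(codes$cue, codes$distractor))]

  # condition templates on the acquisition grid (0 .. 1600 ms covers all tails)
  tmpl_t <- seq(0, 1600, by = 1000 / fs)
  tmpl <- lapply(seq_len(4), function(i)
    clean_condition_waveform(profile, codes$cue[i], codes$distractor[i],
                             eeg_ch, tmpl_t))
  L <- length(tmpl_t)

  samples <- matrix(0, n_ch, n_samp, dimnames = list(channels, NULL))
  blink_log <- numeric(0)
  jump_log <- data.frame(sample = integer(), channel = character())
  local_seed(seed, {
    for (ch in channels) {
      w_sd <- if (ch %in% c("A1", "A2")) 0.3 * noise$white_sd else noise$white_sd
      p_sd <- if (ch %in% eeg_ch) noise$pink_sd else 0
      x <- numeric(n_samp)
      if (w_sd > 0) x <- x + stats::rnorm(n_samp, sd = w_sd)
      if (p_sd > 0) x <- x + pink_noise(n_samp, p_sd)
      samples[ch, ] <- x
    }
    minutes <- n_samp / fs / 60
    n_blinks <- stats::rpois(1, noise$blink_rate * minutes)
    if (n_blinks > 0 && noise$blink_amp > 0) {
      bl <- as.integer(round(noise$blink_dur_ms / 1000 * fs))
      shape <- sin(pi * seq(0, 1, length.out = bl))
      wts <- c(F3 = 0.5, F4 = 0.5, C3 = 0.2, C4 = 0.2, P3 = 0.05, P4 = 0.05,
               EOG = 1)
      blink_log <- sort(sample.int(n_samp - bl, n_blinks))
      for (s0 in blink_log) {
        idx <- s0 + seq_len(bl) - 1L
        for (ch in intersect(channels, names(wts)))
          samples[ch, idx] <- samples[ch, idx] +
            noise$blink_amp * wts[[ch]] * shape
      }
    }
    n_jumps <- stats::rpois(1, noise$jump_rate * minutes)
    if (n_jumps > 0 && noise$jump_amp > 0) {
      jl <- as.integer(round(noise$jump_dur_ms / 1000 * fs))
      js <- sort(sample.int(n_samp - jl, n_jumps))
      jch <- sample(eeg_ch, n_jumps, replace = TRUE)
      for (i in seq_len(n_jumps)) {
        idx <- js[i] + seq_len(jl) - 1L
        samples[jch[i], idx] <- samples[jch[i], idx] +
          noise$jump_amp * sample(c(-1, 1), 1)
      }
      jump_log <- data.frame(sample = js, channel = jch,
                             stringsAsFactors = FALSE)
    }
  })

  # inject per-trial ERP components
  for (i in seq_len(n_trials)) {
    idx <- onset_samp[i] + seq_len(L) - 1L
    samples[eeg_ch, idx] <- samples[eeg_ch, idx] + tmpl[[code_of[i]]]
  }

  rec <- eeg_recording(samples, fs,
                       markers = data.frame(sample = onset_samp,
                                            code = code_of),
                       history = "simulate_eeg")
  attr(rec, "ground_truth") <- ground_truth(profile, blink_log, jump_log,
                                            fs_analysis = 250)
  rec
}

#' Ground truth for a simulated subject
#'
#' Injected component amplitudes for every condition/channel and the
#' expected feature values on the analysis grid (what an ideal, noise-free
#' pipeline should measure, given the +/-5-sample peak-mean definition).
#'
#' @param profile A \code{subject_profile}.
#' @param blink_log,jump_log Artifact injection logs (internal).
#' @param fs_analysis Analysis rate the expectations are evaluated on.
#' @return List with \code{amplitudes} (condition x channel x component data
#'   frame), \code{expected_peaks}, \code{expected_window_means},
#'   \code{blink_samples}, \code{jumps}.
#' @export
ground_truth <- function(profile, blink_log = numeric(0),
                         jump_log = data.frame(), fs_analysis = 250) {
  codes <- condition_codes()
  roi <- roi_channels()
  step <- 1000 / fs_analysis
  time_ms <- seq(-200, 1800, by = step)
  waves <- lapply(seq_len(4), function(i) {
    vals <- clean_condition_waveform(profile, codes$cue[i],
                                     codes$distractor[i], roi$channel,
                                     time_ms)
    bsel <- time_ms >= -200 & time_ms <= 0
    vals <- vals - rowMeans(vals[, bsel, drop = FALSE])
    erp_waveform(vals, time_ms, codes$condition[i])
  })
  names(waves) <- codes$condition
  amplitudes <- do.call(rbind, lapply(seq_len(4), function(i)
    do.call(rbind, lapply(roi$channel, function(ch)
      do.call(rbind, lapply(names(profile$components), function(cn)
        data.frame(condition = codes$condition[i], channel = ch,
                   component = cn,
                   amplitude = component_amplitude(profile, cn, ch,
                                                   codes$cue[i],
                                                   codes$distractor[i]),
                   stringsAsFactors = FALSE)))))))
  expected_peaks <- do.call(rbind, lapply(codes$condition, function(cc)
    do.call(rbind, lapply(roi$channel, function(ch) {
      n2 <- detect_peak(waves[[cc]], ch, "N2")
      p3 <- detect_peak(waves[[cc]], ch, "P3")
      data.frame(condition = cc, channel = ch, n2 = n2$amplitude,
                 p3 = p3$amplitude, n2p3 = n2p3_amplitude(n2, p3),
                 stringsAsFactors = FALSE)
    }))))
  windows <- list(c(600, 700), c(700, 800), c(800, 900))
  expected_wm <- do.call(rbind, lapply(c("go", "nogo"), function(cue) {
    emo <- waves[[codes$condition[codes$cue == cue &
                                    codes$distractor == "emotional"]]]
    neu <- waves[[codes$condition[codes$cue == cue &
                                    codes$distractor == "neutral"]]]
    dw <- difference_wave(emo, neu)
    do.call(rbind, lapply(windows, function(w)
      do.call(rbind, lapply(roi$channel, function(ch)
        data.frame(cue = cue, channel = ch,
                   window = sprintf("%d-%d", w[1], w[2]),
                   value = window_mean(dw, ch, w),
                   stringsAsFactors = FALSE)))))
  }))
  list(amplitudes = amplitudes, expected_peaks = expected_peaks,
       expected_window_means = expected_wm,
       blink_samples = blink_log, jumps = jump_log)
}

#' Write the ground-truth sidecar as structured text (JSON)
#'
#' @param rec A simulated \code{eeg_recording}.
#' @param path Output path.
#' @export
write_ground_truth <- function(rec, path) {
  gt <- attr(rec, "ground_truth")
  if (is.null(gt)) stop("recording carries no ground-truth attribute")
  jsonlite::write_json(gt, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
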