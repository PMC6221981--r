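# Independent oracles used across the suite.

# Definitional mixed-ANOVA sums of squares by inclusion-exclusion over
# balanced margins (equal group sizes). Independent of the package's
# aov-based route: works purely from cell means.
anova_oracle <- function(d, dv, subject, between, within) {
  y <- d[[dv]]
  gm <- mean(y)
  avem <- function(cols) stats::ave(y, interaction(d[cols], drop = FALSE))
  subsets <- function(cols) {
    out <- list(character(0))
    for (m in seq_along(cols))
      out <- c(out, utils::combn(cols, m, simplify = FALSE))
    out
  }
  eff_ss <- function(cols) {  # crossed-effect SS via inclusion-exclusion
    tau <- rep(0, length(y))
    for (A in subsets(cols)) {
      mu <- if (!length(A)) gm else avem(A)
      tau <- tau + (-1)^(length(cols) - length(A)) * mu
    }
    sum(tau^2)
  }
  err_ss <- function(M) {     # subject x M interaction, subject nested in group
    tau <- rep(0, length(y))
    for (A in subsets(M)) {
      sgn <- (-1)^(length(M) - length(A))
      tau <- tau + sgn * (avem(c(subject, A)) - avem(c(between, A)))
    }
    sum(tau^2)
  }
  win_sets <- subsets(within)[-1]
  eff <- list()
  eff[[between]] <- eff_ss(between)
  for (W in win_sets) {
    eff[[paste(W, collapse = ":")]] <- eff_ss(W)
    eff[[paste(c(between, W), collapse = ":")]] <- eff_ss(c(between, W))
  }
  err <- list(subject = eff_ss(subject) - eff_ss(between))
  for (W in win_sets) err[[paste(W, collapse = ":")]] <- err_ss(W)

  n_subj <- length(unique(d[[subject]]))
  n_grp <- length(unique(d[[between]]))
  lev <- vapply(within, function(f) length(unique(d[[f]])), numeric(1))
  df_of <- function(effname) {
    parts <- strsplit(effname, ":", fixed = TRUE)[[1]]
    prod(vapply(parts, function(p)
      if (p == between) n_grp - 1 else lev[[p]] - 1, numeric(1)))
  }
  err_df <- c(subject = n_subj - n_grp)
  for (W in win_sets)
    err_df[[paste(W, collapse = ":")]] <- (n_subj - n_grp) *
      prod(lev[W] - 1)
  total_err <- sum(unlist(err))
  rows <- do.call(rbind, lapply(names(eff), function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    wpart <- setdiff(parts, between)
    stratum <- if (!length(wpart)) "subject" else paste(wpart, collapse = ":")
    dfn <- df_of(e)
    dfd <- err_df[[stratum]]
    Fv <- (eff[[e]] / dfn) / (err[[stratum]] / dfd)
    data.frame(effect = e, df_num = dfn, df_den = dfd, ss = eff[[e]],
               ss_error = err[[stratum]], F = Fv,
               p = stats::pf(Fv, dfn, dfd, lower.tail = FALSE),
               ges = eff[[e]] / (eff[[e]] + total_err),
               stringsAsFactors = FALSE)
  }))
  list(table = rows, err = err, total_err = total_err)
}

# Brute-force windowed peak scan (independent of detect_peak internals).
brute_force_peak <- function(values, time_ms, window, component,
                             halfwidth = 5L) {
  idx <- which(time_ms >= window[1] & time_ms <= window[2])
  best <- idx[1]
  for (i in idx) {
    if (component == "N2" && values[i] < values[best]) best <- i
    if (component == "P3" && values[i] > values[best]) best <- i
  }
  lo <- max(1L, best - halfwidth)
  hi <- min(length(values), best + halfwidth)
  list(latency = time_ms[best], amplitude = mean(values[lo:hi]))
}

# One-channel recording builder for preprocessing tests.
make_recording <- function(signals, fs = 250, markers = NULL) {
  stopifnot(is.list(signals))
  samples <- do.call(rbind, signals)
  rownames(samples) <- names(signals)
  eeg_recording(samples, fs, markers)
}

# Small fully-crossed long table for ANOVA tests.
make_anova_data <- function(n_per_group = 12, within_levels =
                              list(emotion = c("emo", "neu"),
                                   laterality = c("left", "right"),
                                   region = c("frontal", "central",
                                              "parietal")),
                            seed = 1, effects = NULL) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(2 * n_per_group))
  grp <- rep(c("control", "ofc"), each = n_per_group)
  d <- expand.grid(c(list(subject = subj), within_levels),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject, subj)]
  d$y <- stats::rnorm(nrow(d)) +
    stats::rnorm(length(subj))[match(d$subject, subj)]  # subject intercepts
  if (!is.null(effects)) d$y <- d$y + effects(d)
  d
}
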