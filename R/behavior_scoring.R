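# Behavioural scoring: RT transformation, error dichotomization, outlier and
# wrong-rule-block QC, rate summaries and odds-ratio estimation.

#' Log-transform reaction times
#'
#' RTs are right-skewed; the analysis uses natural-log RT, which is normal
#' under the log-normal generating model. Only correct Go responses carry
#' analysable RTs.
#'
#' @param rt_ms Positive RTs, ms.
#' @return \code{log(rt_ms)}.
#' @export
log_rt <- function(rt_ms) {
  if (any(!is.finite(rt_ms) | rt_ms <= 0))
    stop("reaction times must be positive and finite")
  log(rt_ms)
}

#' Dichotomize classified outcomes for logistic error models
#'
#' Each scheme maps eligible trials to a binary indicator:
#' \itemize{
#'   \item \code{incorrect_vs_other}: Go trials; 1 = incorrect button press.
#'   \item \code{miss_vs_other}: Go trials; 1 = miss.
#'   \item \code{commission_vs_correct}: NoGo trials; 1 = commission.
#'   \item \code{error_vs_correct}: all trials; 1 = any error.
#' }
#'
#' @param log A \code{behavior_log} (needs columns \code{cue},
#'   \code{outcome}; any others are carried through).
#' @param scheme One of the four scheme names.
#' @return The eligible rows of \code{log} with columns \code{scheme} and
#'   binary \code{y} appended; \code{sum(y) + sum(1 - y)} equals the number
#'   of eligible trials.
#' @export
dichotomize <- function(log, scheme = c("incorrect_vs_other",
                                        "miss_vs_other",
                                        "commission_vs_correct",
                                        "error_vs_correct")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("cue", "outcome") %in% names(log)))
  rows <- switch(scheme,
    incorrect_vs_other = log$cue == "go",
    miss_vs_other = log$cue == "go",
    commission_vs_correct = log$cue == "nogo",
    error_vs_correct = rep(TRUE, nrow(log)))
  out <- as.data.frame(log)[rows, , drop = FALSE]
  out$scheme <- scheme
  out$y <- as.integer(switch(scheme,
    incorrect_vs_other = out$outcome == "incorrect_button",
    miss_vs_other = out$outcome == "miss",
    commission_vs_correct = out$outcome == "commission",
    error_vs_correct = out$outcome != "correct"))
  rownames(out) <- NULL
  out
}

#' Quality-control screen: outlier subjects, wrong-rule and outlier blocks
#'
#' Implements the published QC rules on a multi-subject behavioural log:
#' \itemize{
#'   \item \emph{Outlier subject}: a subject whose error count in any error
#'     category exceeds the group mean for that category by strictly more
#'     than 2.5 group SDs.
#'   \item \emph{Wrong-rule block}: a block in which at least 75\% of the
#'     answers are commission errors and misses (the pattern produced by
#'     applying the reversed rule).
#'   \item \emph{Outlier block}: a block whose error rate is strictly more
#'     than 3 SDs above that subject's own mean block error rate.
#' }
#'
#' @param log A behavioural log with columns \code{subject}, \code{block},
#'   \code{cue}, \code{outcome}.
#' @param subject_sd Outlier-subject threshold in group SDs. Default 2.5.
#' @param block_sd Outlier-block threshold in subject SDs. Default 3.
#' @param wrong_rule_prop Wrong-rule proportion (inclusive). Default 0.75.
#' @return A \code{qc_report}: list of data frames \code{outlier_subjects}
#'   (subject, category, count, group mean/SD, exceedance in SD units),
#'   \code{wrong_rule_blocks} and \code{outlier_blocks}.
#' @export
qc_screen <- function(log, subject_sd = 2.5, block_sd = 3,
                      wrong_rule_prop = 0.75) {
  stopifnot(all(c("subject", "block", "cue", "outcome") %in% names(log)))
  subjects <- unique(log$subject)
  if (length(subjects) < 2)
    stop("QC needs at least 2 subjects (group SD undefined)")
  categories <- c("miss", "incorrect_button", "commission", "error")
  counts <- do.call(rbind, lapply(subjects, function(s) {
    oc <- log$outcome[log$subject == s]
    data.frame(subject = s, miss = sum(oc == "miss"),
               incorrect_button = sum(oc == "incorrect_button"),
               commission = sum(oc == "commission"),
               error = sum(oc != "correct"), stringsAsFactors = FALSE)
  }))
  outlier_subjects <- do.call(rbind, lapply(categories, function(cat) {
    x <- counts[[cat]]
    mu <- mean(x); sdev <- stats::sd(x)
    exceed <- if (sdev > 0) (x - mu) / sdev else rep(0, length(x))
    flag <- x > mu + subject_sd * sdev  # strict: "more than"
    if (!any(flag)) return(NULL)
    data.frame(subject = counts$subject[flag], category = cat,
               count = x[flag], group_mean = mu, group_sd = sdev,
               exceedance_sd = exceed[flag], stringsAsFactors = FALSE)
  }))
  if (is.null(outlier_subjects))
    outlier_subjects <- data.frame(subject = character(),
                                   category = character(), count = integer(),
                                   group_mean = numeric(),
                                   group_sd = numeric(),
                                   exceedance_sd = numeric())

  blocks <- unique(log[, c("subject", "block")])
  blk <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    sel <- log$subject == blocks$subject[i] & log$block == blocks$block[i]
    oc <- log$outcome[sel]
    data.frame(subject = blocks$subject[i], block = blocks$block[i],
               n = length(oc),
               comm_miss = sum(oc %in% c("commission", "miss")),
               errors = sum(oc != "correct"), stringsAsFactors = FALSE)
  }))
  blk$error_rate <- blk$errors / blk$n
  wrong_rule <- blk[blk$comm_miss / blk$n >= wrong_rule_prop,
                    c("subject", "block", "comm_miss", "n")]
  outlier_blocks <- do.call(rbind, lapply(subjects, function(s) {
    b <- blk[blk$subject == s, ]
    mu <- mean(b$error_rate); sdev <- stats::sd(b$error_rate)
    flag <- !is.na(sdev) & sdev > 0 & b$error_rate > mu + block_sd * sdev
    b[flag, c("subject", "block", "error_rate")]
  }))
  rownames(wrong_rule) <- rownames(outlier_blocks) <- NULL
  structure(list(outlier_subjects = outlier_subjects,
                 wrong_rule_blocks = wrong_rule,
                 outlier_blocks = outlier_blocks),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> outlier subjects: %d, wrong-rule blocks: %d, outlier blocks: %d\n",
              nrow(x$outlier_subjects), nrow(x$wrong_rule_blocks),
              nrow(x$outlier_blocks)))
  invisible(x)
}

#' Marginal odds ratio of two error rates
#'
#' \code{OR = (a / (1 - a)) / (b / (1 - b))}. With the four cell counts a
#' Wald 95\% confidence interval on the log odds ratio is added.
#'
#' @param rate_a,rate_b Proportions in (0, 1).
#' @param counts Optional named vector \code{c(a_event, a_total, b_event,
#'   b_total)} for the Wald CI.
#' @return List with \code{or} and, when counts are given, \code{ci}
#'   (length-2) and \code{se_log_or}.
#' @examples
#' marginal_odds_ratio(0.021, 0.047)$or   # 0.43
#' @export
marginal_odds_ratio <- function(rate_a, rate_b, counts = NULL) {
  if (!(rate_a > 0 && rate_a < 1 && rate_b > 0 && rate_b < 1))
    stop("degenerate rate (0 or 1): odds ratio undefined without ",
         "continuity correction")
  or <- (rate_a / (1 - rate_a)) / (rate_b / (1 - rate_b))
  out <- list(or = or)
  if (!is.null(counts)) {
    stopifnot(all(c("a_event", "a_total", "b_event", "b_total") %in%
                    names(counts)))
    cells <- c(counts[["a_event"]], counts[["a_total"]] - counts[["a_event"]],
               counts[["b_event"]], counts[["b_total"]] - counts[["b_event"]])
    if (any(cells <= 0)) stop("empty cell: Wald CI undefined")
    se <- sqrt(sum(1 / cells))
    out$se_log_or <- se
    out$ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  out
}

#' Trial-level mixed logistic error model
#'
#' Fits a binary logistic mixed model to dichotomized trials with Group and
#' Emotion (distractor valence) as fixed effects and Subject as a random
#' intercept, via \code{lme4::glmer}; reports fixed-effect odds ratios with
#' Wald 95\% CIs. If the mixed fit fails or does not converge, falls back to
#' the marginal odds ratio with a cluster-robust (subject-level jackknife)
#' CI.
#'
#' @param trials Output of \code{\link{dichotomize}} with columns
#'   \code{subject}, \code{group}, \code{distractor} (valence) and \code{y}.
#' @param ref_group Reference level of group (ORs are
#'   \code{other / reference}). Default the first sorted level.
#' @return Data frame with columns \code{term}, \code{estimate} (log odds),
#'   \code{or}, \code{ci_lo}, \code{ci_hi}, \code{p}, plus attributes
#'   \code{backend} (\code{"glmer"} or \code{"marginal"}) and
#'   \code{separation} (logical: a group x outcome cell had zero events).
#' @export
fit_trial_level_error_model <- function(trials, ref_group = NULL) {
  stopifnot(all(c("subject", "group", "distractor", "y") %in% names(trials)))
  if (length(unique(trials$subject[trials$group == unique(trials$group)[1]])) < 2)
    stop("need at least 2 subjects per group")
  trials$group <- factor(trials$group)
  if (!is.null(ref_group)) trials$group <- stats::relevel(trials$group,
                                                          ref_group)
  trials$emotion <- factor(trials$distractor,
                           levels = c("neutral", "emotional"))
  tab <- tapply(trials$y, trials$group, sum)
  separation <- any(tab == 0) || any(tapply(1 - trials$y, trials$group,
                                            sum) == 0)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(y ~ group + emotion + (1 | subject), data = trials,
                  family = stats::binomial()))),
    error = function(e) NULL)
  # a singular (zero-variance) random effect is a legitimate boundary fit;
  # fall back only on outright failure or non-convergence
  msgs <- if (is.null(fit)) "failed" else
    unlist(fit@optinfo$conv$lme4$messages)
  ok <- !is.null(fit) && !any(grepl("failed to converge", msgs))
  if (ok) {
    # tiny/sparse fits can fall back to the RX var-cov estimate with a
    # warning; the Wald CIs below are still well-defined
    co <- suppressWarnings(summary(fit))$coefficients
    terms <- rownames(co)[-1]
    res <- data.frame(
      term = terms, estimate = co[-1, "Estimate"],
      or = exp(co[-1, "Estimate"]),
      ci_lo = exp(co[-1, "Estimate"] -
                    stats::qnorm(0.975) * co[-1, "Std. Error"]),
      ci_hi = exp(co[-1, "Estimate"] +
                    stats::qnorm(0.975) * co[-1, "Std. Error"]),
      p = co[-1, "Pr(>|z|)"], stringsAsFactors = FALSE)
    attr(res, "backend") <- "glmer"
  } else {
    # marginal OR with leave-one-subject-out jackknife SE on the log OR
    lev <- levels(trials$group)
    rate <- function(d) c(mean(d$y[d$group == lev[2]]),
                          mean(d$y[d$group == lev[1]]))
    r <- rate(trials)
    or <- (r[1] / (1 - r[1])) / (r[2] / (1 - r[2]))
    subjects <- unique(trials$subject)
    lo <- vapply(subjects, function(s) {
      rr <- rate(trials[trials$subject != s, ])
      log((rr[1] / (1 - rr[1])) / (rr[2] / (1 - rr[2])))
    }, numeric(1))
    se <- sqrt((length(subjects) - 1) / length(subjects) *
                 sum((lo - mean(lo))^2))
    res <- data.frame(
      term = paste0("group", lev[2]), estimate = log(or), or = or,
      ci_lo = exp(log(or) - stats::qnorm(0.975) * se),
      ci_hi = exp(log(or) + stats::qnorm(0.975) * se),
      p = NA_real_, stringsAsFactors = FALSE)
    attr(res, "backend") <- "marginal"
  }
  attr(res, "separation") <- separation
  rownames(res) <- NULL
  res
}
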