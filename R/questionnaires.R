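# Questionnaire scoring and group comparison: BRIEF-A scale t-scores are
# consumed as provided (item-level scoring is proprietary), RPQ items split
# into somatic / emotional / cognitive subscales, BDI as a raw sum; group
# comparisons use Wilcoxon rank-sum tests.

#' Default RPQ item-to-category mapping (reconstruction)
#'
#' Assigns the 16 Rivermead Post-Concussion Symptoms Questionnaire items to
#' somatic, emotional and cognitive symptom categories. The published
#' analysis cites two category schemes without printing item lists; this
#' default is a reconstruction following the common three-factor split
#' (headaches, dizziness, nausea, sleep disturbance, fatigue, noise and
#' light sensitivity, blurred/double vision, restlessness as somatic;
#' irritability, depression, frustration as emotional; forgetfulness, poor
#' concentration, long thinking times as cognitive) and should be replaced
#' with the scheme of record when reproducing a specific analysis.
#'
#' @return Named character vector: names are item identifiers
#'   (\code{item01}..\code{item16}), values the category.
#' @export
rpq_default_mapping <- function() {
  c(item01 = "somatic",    # headaches
    item02 = "somatic",    # dizziness
    item03 = "somatic",    # nausea/vomiting
    item04 = "somatic",    # noise sensitivity
    item05 = "somatic",    # sleep disturbance
    item06 = "somatic",    # fatigue
    item07 = "emotional",  # irritability
    item08 = "emotional",  # depression/tearfulness
    item09 = "emotional",  # frustration/impatience
    item10 = "cognitive",  # forgetfulness
    item11 = "cognitive",  # poor concentration
    item12 = "cognitive",  # taking longer to think
    item13 = "somatic",    # blurred vision
    item14 = "somatic",    # light sensitivity
    item15 = "somatic",    # double vision
    item16 = "somatic")    # restlessness
}

#' RPQ subscale sums and total
#'
#' @param item_scores Named numeric vector of item scores (names must all be
#'   present in the mapping).
#' @param mapping Named character vector item -> category; default
#'   \code{\link{rpq_default_mapping}}.
#' @return Named numeric: \code{somatic}, \code{emotional},
#'   \code{cognitive}, \code{total}; the three subscales always sum to the
#'   total.
#' @export
rpq_subscales <- function(item_scores, mapping = rpq_default_mapping()) {
  stopifnot(!is.null(names(item_scores)))
  unmapped <- setdiff(names(item_scores), names(mapping))
  if (length(unmapped))
    stop("unmapped RPQ items: ", paste(unmapped, collapse = ", "))
  cat_of <- mapping[names(item_scores)]
  sums <- vapply(c("somatic", "emotional", "cognitive"),
                 function(cc) sum(item_scores[cat_of == cc]), numeric(1))
  c(sums, total = sum(item_scores))
}

#' BRIEF-A summary-index composition check
#'
#' Validates that the Behavioral Regulation Index (BRI), Metacognition Index
#' (MI) and Global Executive Composite (GEC) rows are consistent with the
#' instrument's structure when raw scale scores are supplied (BRI scales:
#' Inhibit, Shift, Emotional Control, Self-Monitor; MI scales: Initiate,
#' Working Memory, Plan/Organize, Task Monitor, Organization of Materials).
#' Normative t-scores do not sum, so the check applies to raw sums only.
#'
#' @return Named list of scale names per index.
#' @export
briefa_structure <- function() {
  list(BRI = c("Inhibit", "Shift", "Emotional Control", "Self-Monitor"),
       MI = c("Initiate", "Working Memory", "Plan/Organize", "Task-Monitor",
              "Organization of Materials"),
       GEC = c("Inhibit", "Shift", "Emotional Control", "Self-Monitor",
               "Initiate", "Working Memory", "Plan/Organize", "Task-Monitor",
               "Organization of Materials"))
}

#' Compare questionnaire scales between groups
#'
#' Per-scale two-sided Wilcoxon rank-sum test between the two groups
#' (questionnaire scores are typically non-normal, so the comparison is
#' rank-based and invariant under monotone rescaling).
#'
#' @param scores Data frame with columns \code{subject}, \code{group},
#'   \code{instrument}, \code{scale}, \code{score} (BRIEF-A as t-scores,
#'   RPQ/BDI as raw sums).
#' @return Data frame with one row per instrument x scale: group medians,
#'   the rank-sum statistic and p-value.
#' @export
compare_groups <- function(scores) {
  stopifnot(all(c("subject", "group", "instrument", "scale", "score") %in%
                  names(scores)))
  groups <- sort(unique(as.character(scores$group)))
  if (length(groups) != 2) stop("exactly two groups required")
  keys <- unique(scores[, c("instrument", "scale")])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- scores$instrument == keys$instrument[i] &
      scores$scale == keys$scale[i]
    x <- scores$score[sel & scores$group == groups[1]]
    y <- scores$score[sel & scores$group == groups[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("need at least 2 subjects per group for ", keys$scale[i])
    wt <- wilcoxon_rank_sum(x, y)
    data.frame(instrument = keys$instrument[i], scale = keys$scale[i],
               median_1 = stats::median(x), median_2 = stats::median(y),
               group_1 = groups[1], group_2 = groups[2],
               statistic = wt$statistic, p = wt$p, exact = wt$exact,
               stringsAsFactors = FALSE)
  }))
}
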