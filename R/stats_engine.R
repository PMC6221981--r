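# Mixed between/within repeated-measures ANOVA with Mauchly sphericity
# testing, Greenhouse-Geisser correction and generalized eta squared;
# interaction decomposition under Bonferroni control; Wilcoxon rank-sum and
# paired region contrasts.

check_long_table <- function(data, dv, subject, between, within) {
  stopifnot(all(c(dv, subject, within) %in% names(data)),
            is.null(between) || between %in% names(data))
  cells <- interaction(data[within], drop = FALSE)
  tab <- table(data[[subject]], cells)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("unbalanced design: expected exactly one value per subject per ",
         "within-cell; offending cells:\n",
         paste(utils::capture.output(print(tab[unique(bad[, 1]), ,
                                               drop = FALSE])),
               collapse = "\n"))
  }
  if (!is.null(between)) {
    g <- tapply(data[[between]], data[[subject]],
                function(x) length(unique(x)))
    if (any(g != 1)) stop("subjects must belong to exactly one ", between,
                          " level")
    n_per <- table(tapply(data[[between]], data[[subject]], `[`, 1))
    if (any(n_per < 2)) stop("need at least 2 subjects per ", between,
                             " level")
  }
  invisible(TRUE)
}

# Orthonormal contrast (Helmert) rows for a k-level factor
ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)           # k x (k-1)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  t(C)                                   # (k-1) x k
}

# Greenhouse-Geisser epsilon and Mauchly test for one within effect.
# Y: subjects x within-cells matrix (cells ordered as expand.grid(levels)),
# g: group factor per subject, effect: character vector of within factors in
# the effect, wlev: named list of factor levels (in cell order).
within_effect_sphericity <- function(Y, g, effect, wlev) {
  mats <- lapply(names(wlev), function(f) {
    k <- length(wlev[[f]])
    if (f %in% effect) ortho_contrasts(k) else matrix(1 / sqrt(k), 1, k)
  })
  # cells vary fastest in the FIRST factor (expand.grid order) -> kron in
  # reverse order so the Kronecker index matches the cell ordering
  C <- Reduce(`%x%`, rev(mats))
  d <- nrow(C)
  if (d < 2) return(list(epsilon = 1, mauchly_W = NA_real_,
                         mauchly_p = NA_real_, df = d))
  Z <- Y %*% t(C)
  resid <- Z - rowsum(Z, g)[g, , drop = FALSE] / as.vector(table(g))[g]
  nu <- nrow(Y) - nlevels(g)
  S <- crossprod(resid) / nu
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  ssd <- structure(list(SSD = crossprod(resid), call = quote(within_effect),
                        df = nu), class = "SSD")
  mt <- tryCatch(stats::mauchly.test(ssd),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  list(epsilon = eps, mauchly_W = unname(mt$statistic),
       mauchly_p = mt$p.value, df = d)
}

#' Mixed between/within repeated-measures ANOVA
#'
#' Univariate mixed-design ANOVA for one between-subject factor (optional)
#' and any number of crossed within-subject factors, on a balanced long
#' table (one value per subject per within-cell). Sums of squares and F
#' tests come from the standard multistratum decomposition
#' (\code{aov} with a \code{subject / (within factors)} error structure);
#' on top of that the function reports, per effect:
#' \itemize{
#'   \item generalized eta squared, \code{ges = SS_effect / (SS_effect +
#'     sum of all subject-level error SS)};
#'   \item Mauchly's sphericity test for every within effect with more than
#'     1 numerator df (pooled within-group covariance of the orthonormal
#'     effect contrasts);
#'   \item Greenhouse-Geisser epsilon and the corrected p-value; the
#'     \code{p_corrected} column applies the correction whenever Mauchly's
#'     test rejects at \code{sphericity_alpha} (both corrected and
#'     uncorrected p-values are always reported).
#' }
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject identifier column.
#' @param between Name of the between-subject factor, or \code{NULL}.
#' @param within Character vector of within-subject factor names.
#' @param sphericity_alpha Mauchly rejection level triggering the
#'   Greenhouse-Geisser correction. Default 0.05.
#' @return An \code{anova_table}: data frame with columns \code{effect},
#'   \code{df_num}, \code{df_den}, \code{ss}, \code{ss_error}, \code{F},
#'   \code{p}, \code{ges}, \code{epsilon}, \code{mauchly_W},
#'   \code{mauchly_p}, \code{p_gg}, \code{sphericity_corrected},
#'   \code{p_corrected}. Attribute \code{ss_total} carries the total sum of
#'   squares; \code{strata} the residual SS/df per error stratum.
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), emotion = c("emo", "neu"))
#' d$y <- rnorm(nrow(d))
#' mixed_anova(d, "y", "subject", between = NULL, within = "emotion")
#' @export
mixed_anova <- function(data, dv, subject, between = NULL, within,
                        sphericity_alpha = 0.05) {
  data <- as.data.frame(data)
  check_long_table(data, dv, subject, between, within)
  for (f in c(subject, between, within)) data[[f]] <- factor(data[[f]])

  rhs <- paste(c(between, within), collapse = " * ")
  err <- sprintf("Error(%s/(%s))", subject, paste(within, collapse = " * "))
  form <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(form, data = data)
  sm <- summary(fit)

  rows <- list(); strata <- list()
  for (stratum_name in names(sm)) {
    tab <- sm[[stratum_name]][[1]]
    terms <- trimws(rownames(tab))
    res_i <- which(terms == "Residuals")
    stratum_ss_err <- tab[res_i, "Sum Sq"]
    stratum_df_err <- tab[res_i, "Df"]
    strata[[stratum_name]] <- c(ss = stratum_ss_err, df = stratum_df_err)
    for (i in setdiff(seq_along(terms), res_i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], df_num = tab[i, "Df"],
        df_den = stratum_df_err, ss = tab[i, "Sum Sq"],
        ss_error = stratum_ss_err, F = tab[i, "F value"],
        p = tab[i, "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ss_error_all <- sum(vapply(strata, `[[`, numeric(1), "ss"))
  out$ges <- out$ss / (out$ss + ss_error_all)

  # sphericity diagnostics per within effect (shared by its interactions
  # with the between factor)
  wlev <- lapply(data[within], levels)
  grid <- expand.grid(wlev, KEEP.OUT.ATTRS = FALSE)
  cell_key <- interaction(grid, drop = FALSE)
  data_key <- interaction(data[within], drop = FALSE)
  subj_levels <- levels(data[[subject]])
  Y <- matrix(NA_real_, length(subj_levels), nrow(grid),
              dimnames = list(subj_levels, NULL))
  idx <- cbind(match(data[[subject]], subj_levels),
               match(data_key, levels(cell_key)))
  Y[idx] <- data[[dv]]
  g <- if (is.null(between)) factor(rep("all", length(subj_levels)))
       else factor(tapply(as.character(data[[between]]), data[[subject]],
                          `[`, 1)[subj_levels])

  out$epsilon <- 1; out$mauchly_W <- NA_real_; out$mauchly_p <- NA_real_
  for (i in seq_len(nrow(out))) {
    parts <- strsplit(out$effect[i], ":", fixed = TRUE)[[1]]
    weff <- intersect(parts, within)
    if (!length(weff)) next
    sph <- within_effect_sphericity(Y, g, weff, wlev)
    out$epsilon[i] <- sph$epsilon
    out$mauchly_W[i] <- sph$mauchly_W
    out$mauchly_p[i] <- sph$mauchly_p
  }
  out$p_gg <- stats::pf(out$F, out$epsilon * out$df_num,
                        out$epsilon * out$df_den, lower.tail = FALSE)
  out$sphericity_corrected <- !is.na(out$mauchly_p) &
    out$mauchly_p < sphericity_alpha & out$df_num > 1
  out$p_corrected <- ifelse(out$sphericity_corrected, out$p_gg, out$p)
  rownames(out) <- NULL
  attr(out, "ss_total") <- sum((data[[dv]] - mean(data[[dv]]))^2)
  attr(out, "strata") <- strata
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Decompose a significant interaction by stratified post-hoc ANOVAs
#'
#' Splits the data by the levels of one factor of a tested interaction and
#' re-runs the mixed ANOVA within each stratum, declaring significance only
#' at the Bonferroni-adjusted final level (default p < 0.017, the published
#' criterion for a three-way decomposition).
#'
#' @inheritParams mixed_anova
#' @param by Factor to stratify on (must be in \code{between} or
#'   \code{within}).
#' @param alpha_final Significance level applied to the stratum ANOVAs.
#'   Default 0.017.
#' @return Named list (one element per level of \code{by}) of
#'   \code{anova_table}s, each with an extra logical column
#'   \code{significant} (\code{p_corrected < alpha_final}).
#' @export
decompose_interaction <- function(data, by, dv, subject, between = NULL,
                                  within, alpha_final = 0.017,
                                  sphericity_alpha = 0.05) {
  if (!(by %in% c(between, within)))
    stop("factor '", by, "' is not part of the model being decomposed")
  data <- as.data.frame(data)
  new_between <- if (identical(by, between)) NULL else between
  new_within <- setdiff(within, by)
  if (!length(new_within))
    stop("decomposition would leave no within factor")
  lev <- unique(as.character(data[[by]]))
  res <- lapply(stats::setNames(lev, lev), function(lv) {
    sub <- data[as.character(data[[by]]) == lv, , drop = FALSE]
    tab <- mixed_anova(sub, dv, subject, new_between, new_within,
                       sphericity_alpha)
    tab$significant <- tab$p_corrected < alpha_final
    tab
  })
  attr(res, "alpha_final") <- alpha_final
  res
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum comparison: exact p-value by enumeration for small
#' untied samples (combined n <= 20), normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with \code{statistic} (Mann-Whitney U for \code{x}),
#'   \code{p}, and \code{exact} (logical).
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p   # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && (length(x) + length(y) <= 20)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Paired t-tests between all region pairs
#'
#' For each pair of region levels, a paired two-sided t-test on the
#' subject-aligned values (e.g. N2P3 amplitudes averaged over the other
#' within factors).
#'
#' @param data Data frame with one value per subject x region.
#' @param dv Name of the value column.
#' @param region Name of the region factor column.
#' @param subject Name of the subject column.
#' @return Data frame with columns \code{pair}, \code{t}, \code{df},
#'   \code{p}, \code{mean_diff}.
#' @export
region_pairwise_t <- function(data, dv, region, subject) {
  data <- as.data.frame(data)
  lev <- unique(as.character(data[[region]]))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- data[data[[region]] == pr[1], c(subject, dv)]
    b <- data[data[[region]] == pr[2], c(subject, dv)]
    m <- merge(a, b, by = subject)
    if (nrow(m) < 2) stop("fewer than 2 complete pairs for ",
                          paste(pr, collapse = " vs "))
    d <- m[[paste0(dv, ".x")]] - m[[paste0(dv, ".y")]]
    if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
      if (all(abs(d) < 1e-12))
        return(data.frame(pair = paste(pr, collapse = " vs "), t = 0,
                          df = length(d) - 1, p = 1, mean_diff = 0,
                          stringsAsFactors = FALSE))
      stop("degenerate paired contrast ", paste(pr, collapse = " vs "),
           ": differences are constant and non-zero (t undefined)")
    }
    tt <- stats::t.test(d)
    data.frame(pair = paste(pr, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_diff = mean(d),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
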