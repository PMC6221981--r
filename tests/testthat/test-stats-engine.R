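test_that("mixed ANOVA matches the definitional SS oracle to 1e-8", {
  for (seed in c(1, 2)) {
    d <- make_anova_data(n_per_group = 12, seed = seed,
                         effects = function(d)
                           0.4 * (d$group == "ofc") *
                           (d$emotion == "emo") +
                           0.3 * (d$region == "parietal"))
    tab <- mixed_anova(d, "y", "subject", "group",
                       c("emotion", "laterality", "region"))
    orc <- anova_oracle(d, "y", "subject", "group",
                        c("emotion", "laterality", "region"))$table
    m <- merge(as.data.frame(tab), orc, by = "effect",
               suffixes = c("", "_orc"))
    expect_equal(nrow(m), nrow(orc))
    expect_equal(m$F, m$F_orc, tolerance = 1e-8)
    expect_equal(m$df_num, m$df_num_orc)
    expect_equal(m$df_den, m$df_den_orc)
    expect_equal(m$ss, m$ss_orc, tolerance = 1e-8)
    expect_equal(m$ges, m$ges_orc, tolerance = 1e-8)
    # SS conservation: effects + error strata = total
    parts <- sum(tab$ss) +
      sum(vapply(attr(tab, "strata"), `[[`, numeric(1), "ss"))
    expect_equal(parts, attr(tab, "ss_total"), tolerance = 1e-8)
  }
})

test_that("one 2-level within factor reduces to the squared paired t", {
  set.seed(5)
  n <- 14
  d <- data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
                  emotion = rep(c("emo", "neu"), each = n),
                  y = rnorm(2 * n))
  tab <- mixed_anova(d, "y", "subject", NULL, "emotion")
  diffs <- d$y[d$emotion == "emo"] - d$y[d$emotion == "neu"]
  tt <- t.test(diffs)
  row <- tab[tab$effect == "emotion", ]
  expect_equal(row$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  # 2-level factors have epsilon 1 and corrected = uncorrected p
  expect_equal(row$epsilon, 1)
  expect_equal(row$p_corrected, row$p)
})

test_that("epsilon and Mauchly behave across covariance structures", {
  set.seed(6)
  n <- 30; k <- 4
  d0 <- expand.grid(subject = sprintf("s%02d", 1:n), w = letters[1:k],
                    stringsAsFactors = FALSE)
  # iid cells: epsilon near 1, Mauchly matches the mlm route
  Y <- matrix(rnorm(n * k), n, k)
  d0$y <- as.vector(Y)
  tab <- mixed_anova(d0, "y", "subject", NULL, "w")
  expect_gt(tab$epsilon[1], 0.7)  # GG epsilon is downward-biased at this n
  ml <- mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(tab$mauchly_p[1], ml$p.value, tolerance = 1e-4)
  # near-rank-1 covariance pushes epsilon to its 1/(k-1) floor
  Y2 <- rnorm(n) %o% seq_len(k) + matrix(rnorm(n * k, sd = 0.03), n, k)
  d0$y <- as.vector(Y2)
  tab2 <- mixed_anova(d0, "y", "subject", NULL, "w")
  expect_gte(tab2$epsilon[1], 1 / (k - 1) - 1e-9)
  expect_lt(tab2$epsilon[1], 0.45)
  expect_lt(tab2$mauchly_p[1], 0.05)
  expect_true(tab2$sphericity_corrected[1])
  expect_equal(tab2$p_corrected[1], tab2$p_gg[1])
  # GG correction weakens the evidence (larger p) for F > 1
  if (tab2$F[1] > 1) expect_gt(tab2$p_gg[1], tab2$p[1])
})

test_that("unbalanced or incomplete designs are refused with a report", {
  d <- make_anova_data(n_per_group = 3,
                       within_levels = list(emotion = c("emo", "neu")))
  expect_error(mixed_anova(d[-1, ], "y", "subject", "group", "emotion"),
               "unbalanced")
  d_one <- d[d$subject == "s01" | d$group == "ofc", ]
  expect_error(mixed_anova(d_one, "y", "subject", "group", "emotion"),
               "at least 2 subjects")
})

test_that("between-effect p is uniform under group-label permutation", {
  set.seed(9)
  d <- make_anova_data(n_per_group = 8,
                       within_levels = list(emotion = c("emo", "neu")))
  subj <- unique(d$subject)
  ps <- replicate(500, {
    perm <- sample(rep(c("control", "ofc"), each = 8))
    d$group <- perm[match(d$subject, subj)]
    tab <- mixed_anova(d, "y", "subject", "group", "emotion")
    tab$p[tab$effect == "group"]
  })
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.1)
})

test_that("generalized eta squared vanishes with the effect", {
  d <- make_anova_data(n_per_group = 6, seed = 3,
                       within_levels = list(emotion = c("emo", "neu")))
  deltas <- c(2, 0.5, 0.05, 0)
  ges <- vapply(deltas, function(delta) {
    d$y2 <- d$y - stats::ave(d$y, d$emotion) +
      delta * (d$emotion == "emo")
    tab <- mixed_anova(d, "y2", "subject", "group", "emotion")
    tab$ges[tab$effect == "emotion"]
  }, numeric(1))
  expect_true(all(diff(ges) < 1e-12))
  expect_equal(ges[4], 0, tolerance = 1e-20)
})

test_that("interaction decomposition stratifies and applies alpha 0.017", {
  set.seed(12)
  d <- make_anova_data(n_per_group = 10,
                       within_levels = list(emotion = c("emo", "neu"),
                                            laterality = c("left", "right")),
                       effects = function(d)
                         1.5 * (d$group == "ofc") * (d$emotion == "emo"))
  dec <- decompose_interaction(d, by = "group", dv = "y",
                               subject = "subject", between = "group",
                               within = c("emotion", "laterality"))
  expect_named(dec, c("control", "ofc"))
  expect_true(all(c("emotion", "laterality") %in% dec$ofc$effect))
  # a stratum p of 0.031 would not pass the 0.017 criterion
  for (tabs in dec)
    expect_identical(tabs$significant, tabs$p_corrected < 0.017)
  expect_error(decompose_interaction(d, by = "absent", dv = "y",
                                     subject = "subject",
                                     between = "group",
                                     within = c("emotion", "laterality")),
               "not part of the model")
})

test_that("decomposition controls familywise error under the null", {
  set.seed(14)
  n_rep <- 400
  fp <- 0
  d <- make_anova_data(n_per_group = 8,
                       within_levels = list(emotion = c("emo", "neu"),
                                            region = c("f", "c", "p")))
  for (i in seq_len(n_rep)) {
    d$y <- rnorm(nrow(d)) +
      rnorm(16)[match(d$subject, unique(d$subject))]
    dec <- decompose_interaction(d, by = "region", dv = "y",
                                 subject = "subject", between = "group",
                                 within = c("emotion", "region"))
    any_sig <- any(vapply(dec, function(tb)
      any(tb$significant[tb$effect == "emotion"]), logical(1)))
    fp <- fp + any_sig
  }
  # familywise rate across 3 strata at alpha 0.017 stays near 5%
  expect_lt(fp / n_rep, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("rank-sum test gives exact small-sample and tie-corrected p", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_equal(w$p, 1 / 3, tolerance = 1e-12)
  # identical multisets: p = 1 under the tie-corrected approximation
  x <- c(1, 2, 3)
  expect_equal(wilcoxon_rank_sum(x, x)$p, 1)
  # agreement with the reference implementation across random samples
  set.seed(18)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(9)
    expect_equal(wilcoxon_rank_sum(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("paired region contrasts handle identity and degeneracy", {
  d <- data.frame(subject = rep(sprintf("s%02d", 1:8), 2),
                  region = rep(c("frontal", "central"), each = 8),
                  y = rep(rnorm(8), 2))
  out <- region_pairwise_t(d, "y", "region", "subject")
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  d2 <- d
  d2$y[d2$region == "central"] <- d2$y[d2$region == "central"] + 1
  expect_error(region_pairwise_t(d2, "y", "region", "subject"),
               "degenerate")
})

test_that("paired t power matches the noncentral-t closed form", {
  set.seed(19)
  n <- 23; d_eff <- 0.6; n_rep <- 600
  rej <- 0
  for (i in seq_len(n_rep)) {
    diffs <- rnorm(n, mean = d_eff, sd = 1)
    dat <- data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
                      region = rep(c("frontal", "central"), each = n),
                      y = c(diffs, numeric(n)))
    out <- region_pairwise_t(dat, "y", "region", "subject")
    rej <- rej + (out$p < 0.05)
  }
  power <- stats::power.t.test(n = n, delta = d_eff, sd = 1,
                               type = "paired")$power
  se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(rej / n_rep - power), 4 * se)
})
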