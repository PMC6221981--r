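test_that("log_rt is the natural log and rejects nonpositive input", {
  expect_equal(log_rt(1), 0)
  expect_equal(log_rt(exp(1)), 1)
  expect_error(log_rt(0), "positive")
  expect_error(log_rt(c(100, -3)), "positive")
})

test_that("dichotomization conserves counts across all four schemes", {
  s <- generate_schedule(4, 16, seed = 3)
  p <- subject_profile("ofc_like")
  b <- simulate_behavior(s, p, seed = 17)
  n_go <- sum(b$cue == "go")
  n_nogo <- sum(b$cue == "nogo")
  d_inc <- dichotomize(b, "incorrect_vs_other")
  d_miss <- dichotomize(b, "miss_vs_other")
  d_comm <- dichotomize(b, "commission_vs_correct")
  d_err <- dichotomize(b, "error_vs_correct")
  expect_equal(nrow(d_inc), n_go)
  expect_equal(nrow(d_miss), n_go)
  expect_equal(nrow(d_comm), n_nogo)
  expect_equal(nrow(d_err), nrow(b))
  # scheme sums equal the generator's outcome counts
  expect_equal(sum(d_inc$y), sum(b$outcome == "incorrect_button"))
  expect_equal(sum(d_miss$y), sum(b$outcome == "miss"))
  expect_equal(sum(d_comm$y), sum(b$outcome == "commission"))
  expect_equal(sum(d_err$y), sum(b$outcome != "correct"))
  # miss_vs_other on a 10-trial toy: one miss -> y sums to 1
  toy <- data.frame(cue = rep("go", 10),
                    outcome = c("miss", rep("correct", 9)))
  expect_equal(sum(dichotomize(toy, "miss_vs_other")$y), 1)
  # all-correct session: y = 0 everywhere
  p0 <- subject_profile("control_like",
                        error_rates = c(miss = 0, incorrect = 0,
                                        commission = 0))
  b0 <- simulate_behavior(s, p0, seed = 1)
  for (sch in c("incorrect_vs_other", "miss_vs_other",
                "commission_vs_correct", "error_vs_correct"))
    expect_equal(sum(dichotomize(b0, sch)$y), 0)
})

test_that("QC screen flags wrong-rule blocks at the 75% boundary", {
  # one block where 48/64 answers are commissions and misses
  mk_block <- function(subject, block, n_bad) {
    out <- rep("correct", 64)
    if (n_bad > 0) out[seq_len(n_bad)] <- rep(c("commission", "miss"),
                                              length.out = n_bad)
    data.frame(subject = subject, block = block,
               cue = rep(c("go", "nogo"), 32), outcome = out,
               stringsAsFactors = FALSE)
  }
  log <- rbind(mk_block("s1", 1, 48), mk_block("s1", 2, 0),
               mk_block("s2", 1, 0), mk_block("s2", 2, 0))
  qc <- qc_screen(log)
  expect_equal(nrow(qc$wrong_rule_blocks), 1)
  expect_equal(qc$wrong_rule_blocks$block[1], 1)
  expect_identical(qc$wrong_rule_blocks$subject[1], "s1")
  # 47/64 is below the inclusive 75% boundary
  log2 <- rbind(mk_block("s1", 1, 47), mk_block("s1", 2, 0),
                mk_block("s2", 1, 0), mk_block("s2", 2, 0))
  expect_equal(nrow(qc_screen(log2)$wrong_rule_blocks), 0)
})

test_that("identical subjects produce no outlier flags (strict rule)", {
  mk_subj <- function(s) data.frame(subject = s, block = rep(1:2, each = 8),
                                    cue = rep(c("go", "nogo"), 8),
                                    outcome = c("miss",
                                                rep("correct", 15)),
                                    stringsAsFactors = FALSE)
  log <- rbind(mk_subj("s1"), mk_subj("s2"), mk_subj("s3"))
  qc <- qc_screen(log)
  expect_equal(nrow(qc$outlier_subjects), 0)
  expect_error(qc_screen(mk_subj("s1")), "at least 2 subjects")
})

test_that("a constructed outlier subject is flagged, and only that one", {
  set.seed(31)
  n_subj <- 12
  counts <- pmax(0, round(rnorm(n_subj - 1, 10, 2)))
  mu <- mean(counts); sdev <- sd(counts)
  hot <- round(mu + 8 * sdev)  # beyond 2.5 SD even after pooling
  all_counts <- c(counts, hot)
  log <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    n_miss <- all_counts[i]
    data.frame(subject = sprintf("s%02d", i), block = 1,
               cue = "go",
               outcome = c(rep("miss", n_miss), rep("correct", 200 - n_miss)),
               stringsAsFactors = FALSE)
  }))
  qc <- qc_screen(log)
  flagged <- qc$outlier_subjects[qc$outlier_subjects$category == "miss", ]
  expect_identical(flagged$subject, sprintf("s%02d", n_subj))
  expect_gt(flagged$exceedance_sd, 2.5)
})

test_that("outlier blocks exceed the subject's own 3 SD rule", {
  set.seed(7)
  blocks <- lapply(1:16, function(b) {
    err <- if (b == 16) 30 else rpois(1, 2)
    data.frame(subject = "s1", block = b, cue = "go",
               outcome = c(rep("miss", err), rep("correct", 64 - err)),
               stringsAsFactors = FALSE)
  })
  log <- rbind(do.call(rbind, blocks),
               data.frame(subject = "s2", block = 1, cue = "go",
                          outcome = rep("correct", 64),
                          stringsAsFactors = FALSE))
  qc <- qc_screen(log)
  expect_true(16 %in% qc$outlier_blocks$block[qc$outlier_blocks$subject ==
                                                "s1"])
})

test_that("marginal odds ratios reproduce published values and identities", {
  expect_equal(round(marginal_odds_ratio(0.021, 0.047)$or, 2), 0.43)
  expect_equal(round(marginal_odds_ratio(0.047, 0.021)$or, 2), 2.30)
  expect_equal(marginal_odds_ratio(0.3, 0.3)$or, 1)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.99); b <- runif(1, 0.01, 0.99)
    expect_equal(marginal_odds_ratio(a, b)$or *
                   marginal_odds_ratio(b, a)$or, 1)
  }
  expect_error(marginal_odds_ratio(0, 0.5), "degenerate")
  # Wald CI from counts brackets the point estimate
  ci <- marginal_odds_ratio(0.021, 0.047,
                            counts = c(a_event = 236, a_total = 11264,
                                       b_event = 577, b_total = 12288))
  expect_lt(ci$ci[1], ci$or)
  expect_gt(ci$ci[2], ci$or)
})

test_that("trial-level mixed error model recovers the generator", {
  set.seed(41)
  # no subject heterogeneity: mixed OR ~ marginal OR
  n_subj <- 8; n_trials <- 400
  mk <- function(group, p_err, offset)
    do.call(rbind, lapply(seq_len(n_subj), function(i)
      data.frame(subject = sprintf("%s%02d", group, i + offset),
                 group = group,
                 distractor = rep(c("emotional", "neutral"),
                                  n_trials / 2),
                 y = rbinom(n_trials, 1, p_err),
                 stringsAsFactors = FALSE)))
  trials <- rbind(mk("control", 0.02, 0), mk("ofc", 0.05, 100))
  fit <- fit_trial_level_error_model(trials, ref_group = "ofc")
  expect_identical(attr(fit, "backend"), "glmer")
  g <- fit[fit$term == "groupcontrol", ]
  marg <- marginal_odds_ratio(mean(trials$y[trials$group == "control"]),
                              mean(trials$y[trials$group == "ofc"]))$or
  expect_lt(abs(log(g$or) - log(marg)), 0.35)
  # the CI covers the generating OR (0.02 vs 0.05 odds)
  true_or <- (0.02 / 0.98) / (0.05 / 0.95)
  expect_lt(g$ci_lo, true_or)
  expect_gt(g$ci_hi, true_or)
  # emotion has no generating effect: CI covers 1
  e <- fit[fit$term == "emotionemotional", ]
  expect_lt(e$ci_lo, 1)
  expect_gt(e$ci_hi, 1)
})
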