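blank_channels <- function(n, fs = 500, chans = c("Cz", "A1", "A2")) {
  sig <- lapply(chans, function(ch) numeric(n))
  names(sig) <- chans
  sig
}

test_that("downsampling preserves DC, sinusoids and marker positions", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  const <- rep(3, length(t))
  sine <- sin(2 * pi * 10 * t)
  rec <- make_recording(list(Cz = const, Pz = sine, A1 = numeric(length(t)),
                             A2 = numeric(length(t))),
                        fs = fs,
                        markers = data.frame(sample = c(1000L, 5000L),
                                             code = c(1L, 2L)))
  ds <- downsample(rec, 250)
  expect_equal(ds$fs, 250)
  expect_equal(ncol(ds$samples), length(t) / 2)
  # DC invariance
  mid <- 500:4500
  expect_equal(unname(ds$samples["Cz", mid]), rep(3, length(mid)),
               tolerance = 1e-6)
  # 10 Hz amplitude within 1% (compare against the analytic sinusoid)
  t2 <- seq(0, 20 - 1 / 250, by = 1 / 250)
  fitamp <- function(x, t, f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    sqrt(sum(stats::lm.fit(X, x)$coefficients^2))
  }
  expect_equal(fitamp(ds$samples["Pz", mid], t2[mid], 10), 1,
               tolerance = 0.01)
  # marker at sample 1000 (500 Hz) -> sample 500 (250 Hz)
  expect_identical(ds$markers$sample, c(500L, 2500L))
  expect_error(downsample(rec, 330), "integer multiple")
})

test_that("band-pass gain is near unity in band and suppresses out of band", {
  fs <- 250
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  mk <- function(f) sin(2 * pi * f * t)
  rec <- make_recording(list(S5 = mk(5), S60 = mk(60),
                             Z = numeric(length(t))), fs = fs)
  out <- bandpass(rec, 0.01, 30)
  mid <- 2000:8000
  amp <- function(x) max(abs(x[mid]))
  expect_gt(amp(out$samples["S5", ]), 0.95)
  expect_lt(amp(out$samples["S5", ]), 1.05)
  expect_lt(amp(out$samples["S60", ]), 0.2)
  expect_equal(unname(out$samples["Z", ]), numeric(length(t)))
  expect_error(bandpass(rec, 30, 0.01), "corner")
  expect_error(bandpass(rec, 0.01, 200), "corner")
})

test_that("zero-phase filtering leaves sinusoid phase intact", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 8 * t)
  y <- zero_phase_butter(x, 30, fs, "low")
  mid <- 2000:5000
  # zero lag: cross-correlation peaks at zero shift
  lags <- -3:3
  cc <- vapply(lags, function(L)
    sum(x[mid] * y[mid + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("EOG regression removes injected blinks but not clean channels", {
  set.seed(11)
  n <- 20000
  neural <- sin(2 * pi * 6 * seq_len(n) / 250)
  blink <- numeric(n)
  for (s0 in c(3000, 9000, 15000))
    blink[s0 + 0:99] <- 150 * sin(pi * seq(0, 1, length.out = 100))
  rec <- make_recording(list(F3 = neural + 0.5 * blink + rnorm(n, 0, 1),
                             P3 = neural + 0.05 * blink + rnorm(n, 0, 1),
                             EOG = blink + rnorm(n, 0, 1)), fs = 250)
  out <- remove_blinks(rec, "regression")
  blink_idx <- which(blink > 50)
  residual <- function(ch) {
    max(abs(out$samples[ch, blink_idx] - neural[blink_idx]))
  }
  expect_lt(residual("F3"), 0.05 * 150)  # < 5% of injected amplitude
  expect_lt(residual("P3"), 0.05 * 150)
  # blink-free recording passes through almost unchanged
  rec2 <- make_recording(list(F3 = neural, EOG = rnorm(n, 0, 1)), fs = 250)
  out2 <- remove_blinks(rec2, "regression")
  expect_equal(out2$samples["F3", ], rec2$samples["F3", ],
               tolerance = 0.02)
  # passthrough is the identity
  out3 <- remove_blinks(rec, "passthrough")
  expect_identical(out3$samples, rec$samples)
  rec_no_eog <- make_recording(list(F3 = neural), fs = 250)
  expect_error(remove_blinks(rec_no_eog, "regression"), "EOG")
})

test_that("jump artifacts are annotated and small signals are not", {
  set.seed(3)
  n <- 50000
  quiet <- rnorm(n, 0, 5)
  one_jump <- quiet
  one_jump[20000:20075] <- one_jump[20000:20075] + 150
  rec <- make_recording(list(Cz = one_jump), fs = 250)
  out <- reject_jump_artifacts(rec, 100)
  expect_equal(nrow(out$bad_intervals), 1)
  expect_lte(out$bad_intervals$start[1], 20000)
  expect_gte(out$bad_intervals$end[1], 20075)

  # max deviation 50 uV -> zero annotations
  mild <- quiet
  mild[10000:10050] <- mild[10000:10050] + 30
  out2 <- reject_jump_artifacts(make_recording(list(Cz = mild), fs = 250),
                                100)
  expect_equal(nrow(out2$bad_intervals), 0)

  # five known jumps -> five intervals, each containing its jump
  multi <- rnorm(n, 0, 3)
  at <- c(5000, 12000, 21000, 33000, 44000)
  for (s0 in at) multi[s0 + 0:50] <- multi[s0 + 0:50] + 140
  out3 <- reject_jump_artifacts(make_recording(list(Cz = multi), fs = 250),
                                100)
  expect_equal(nrow(out3$bad_intervals), 5)
  for (s0 in at)
    expect_true(any(out3$bad_intervals$start <= s0 &
                      out3$bad_intervals$end >= s0))
})

test_that("linked-earlobe re-referencing obeys its algebra", {
  set.seed(5)
  n <- 1000
  rec <- make_recording(list(Cz = rep(10, n), A1 = rep(2, n),
                             A2 = rep(4, n)), fs = 250)
  out <- rereference_linked_earlobes(rec)
  expect_equal(unname(out$samples["Cz", ]), rep(7, n))
  # (A1 + A2)/2 identically zero afterwards
  expect_equal(unname((out$samples["A1", ] + out$samples["A2", ]) / 2),
               numeric(n))
  # zero-reference recordings are unchanged
  rec0 <- make_recording(list(Cz = rnorm(n), A1 = numeric(n),
                              A2 = numeric(n)), fs = 250)
  expect_equal(rereference_linked_earlobes(rec0)$samples, rec0$samples)
  # idempotence on random recordings
  recr <- make_recording(list(Cz = rnorm(n), Pz = rnorm(n), A1 = rnorm(n),
                              A2 = rnorm(n)), fs = 250)
  once <- rereference_linked_earlobes(recr)
  twice <- rereference_linked_earlobes(once)
  expect_equal(twice$samples, once$samples)
  rec_no_ref <- make_recording(list(Cz = rnorm(n)), fs = 250)
  expect_error(rereference_linked_earlobes(rec_no_ref), "A1/A2")
})

test_that("segmentation produces the canonical grid and baseline", {
  fs <- 250
  n <- 10000
  rec <- make_recording(list(Cz = rep(3, n), A1 = numeric(n),
                             A2 = numeric(n)), fs = fs,
                        markers = data.frame(sample = c(500L, 2000L, 9990L),
                                             code = c(1L, 2L, 3L)))
  ep <- segment_and_baseline(rec)
  # 501 samples, 4 ms step, -200..1800 inclusive
  expect_equal(length(ep$time_ms), 501)
  expect_equal(unique(diff(ep$time_ms)), 4)
  expect_equal(range(ep$time_ms), c(-200, 1800))
  # constant channel -> identically zero after baseline
  expect_equal(unname(ep$data[1, "Cz", ]), numeric(501))
  # marker too close to the edge is dropped, bookkeeping conserved
  expect_identical(ep$kept, c(TRUE, TRUE, FALSE))
  expect_equal(sum(ep$kept) + sum(!ep$kept), nrow(rec$markers))
  # epochs overlapping bad intervals are dropped
  rec$bad_intervals <- data.frame(start = 1900L, end = 1950L,
                                  reason = "jump>threshold")
  ep2 <- segment_and_baseline(rec)
  expect_identical(ep2$kept, c(TRUE, FALSE, FALSE))
  # baseline mean of every kept epoch is zero
  set.seed(8)
  recr <- make_recording(list(Cz = rnorm(n), A1 = numeric(n),
                              A2 = numeric(n)), fs = fs,
                         markers = data.frame(sample = c(500L, 2000L),
                                              code = c(1L, 1L)))
  epr <- segment_and_baseline(recr)
  bsel <- epr$time_ms >= -200 & epr$time_ms <= 0
  for (i in which(epr$kept))
    expect_equal(mean(epr$data[i, "Cz", bsel]), 0, tolerance = 1e-12)
})

test_that("minimum-segment rule is boundary inclusive", {
  fake_counts <- function(counts) {
    cc <- condition_codes()
    n <- sum(counts)
    ep <- list(data = array(0, c(n, 1, 3)),
               time_ms = c(-4, 0, 4),
               condition = rep(cc$condition, counts),
               kept = rep(TRUE, n), fs = 250, channel_names = "Cz")
    class(ep) <- "epoch_set"
    ep
  }
  expect_false(enforce_min_segments(fake_counts(c(64, 64, 49, 64)))$pass)
  expect_true(enforce_min_segments(fake_counts(c(50, 50, 50, 50)))$pass)
  r <- enforce_min_segments(fake_counts(c(256, 256, 256, 256)))
  expect_true(r$pass)
  expect_equal(unname(r$counts), rep(256L, 4))
})

test_that("the preprocessing chain enforces the canonical stage order", {
  s <- generate_schedule(2, 4, seed = 2)
  rec <- simulate_eeg(s, subject_profile("control_like"),
                      noise_model(white_sd = 2, pink_sd = 0,
                                  blink_rate = 0, jump_rate = 0),
                      seed = 3)
  pp <- preprocess_recording(rec)
  expect_identical(sub("\\(.*", "", pp$recording$history),
                   c("simulate_eeg", "downsample", "bandpass",
                     "remove_blinks", "reject_jumps",
                     "rereference_linked_earlobes", "bandpass"))
  expect_equal(length(pp$epochs$kept), nrow(s))
})
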