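test_that("sequence RT is five times the geometric mean of the latencies", {
  expect_equal(sequence_rt(rep(200, 5)), 1000)
  # one slow press: geometric mean damps it relative to the arithmetic mean
  lat <- c(100, 100, 100, 100, 1600)
  expect_equal(sequence_rt(lat), 5 * 100 * 16^(1 / 5))  # 870.55
  expect_false(isTRUE(all.equal(sequence_rt(lat), 5 * mean(lat))))  # != 2000
  expect_error(sequence_rt(c(100, 100)), "exactly 5")
  expect_error(sequence_rt(c(100, 100, -1, 100, 100)), "positive")
})

test_that("sequence RT is scale-equivariant", {
  set.seed(1)
  for (rep in 1:10) {
    lat <- runif(5, 50, 600)
    lambda <- runif(1, 0.1, 10)
    expect_equal(sequence_rt(lambda * lat), lambda * sequence_rt(lat))
  }
})

test_that("scoring extracts correct sequences and attributes error presses", {
  # clean single sequence
  s1 <- score_sequences(press_frame(TARGET, rep(200, 5)))
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$n_errors_before, 0L)
  expect_equal(s1$rt_ms, 1000)
  expect_true(s1$warmup)

  # a leading press that cannot start the target counts as one error
  s2 <- score_sequences(press_frame(c(2L, TARGET), rep(200, 6)))
  expect_identical(nrow(s2), 1L)
  expect_identical(s2$n_errors_before, 1L)

  # a broken partial match: its presses become errors of the next sequence
  s3 <- score_sequences(press_frame(c(4L, 1L, 4L, 1L, 3L, 2L, 4L),
                                    rep(200, 7)))
  expect_identical(nrow(s3), 1L)
  expect_identical(s3$n_errors_before, 2L)

  # two concatenated sequences: matches never overlap (no proper border)
  s4 <- score_sequences(press_frame(rep(TARGET, 2), rep(200, 10)))
  expect_identical(nrow(s4), 2L)
  expect_identical(s4$seq_in_trial, 1:2)
  expect_identical(s4$warmup, c(TRUE, FALSE))

  # trailing incomplete presses are not silently turned into a sequence
  s5 <- score_sequences(press_frame(c(TARGET, 4L, 1L, 3L), rep(200, 8)))
  expect_identical(nrow(s5), 1L)
})

test_that("a five-sequence trial scores five sequences, first flagged warmup", {
  kp <- press_frame(rep(TARGET, 5), rep(200, 25))
  s <- score_sequences(kp, expected_seqs = 5L)
  expect_identical(nrow(s), 5L)
  expect_identical(s$warmup, c(TRUE, rep(FALSE, 4)))
  # short trials are flagged, not dropped
  expect_warning(score_sequences(kp, expected_seqs = 6L), "fewer completed")
})

test_that("warm-up removal aligns each participant with the schedule", {
  for (g in c("M10", "S30")) {
    spec <- make_group_spec(g)
    sch <- build_schedule(spec)
    kp <- generate_participant(tiny_config(), spec)
    seqs <- score_sequences(kp)
    expect_identical(nrow(seqs), 210L)
    modeled <- remove_warmups(seqs, sch)
    expect_identical(nrow(modeled), nrow(sch))
  }
  # misalignment is rejected with counts
  spec <- make_group_spec("M10")
  seqs <- score_sequences(generate_participant(tiny_config(), spec))
  expect_error(remove_warmups(seqs[-5, ], build_schedule(spec)),
               "misaligned")
  # empty input passes through empty
  expect_identical(nrow(remove_warmups(seqs[0, ])), 0L)
})

test_that("error summaries report per-position means with warm-up separate", {
  spec <- make_group_spec("S30")
  cfg <- tiny_config(error_prob = 0.1, n_participants = 4)
  ds <- generate_dataset(cfg, groups = "S30")
  seqs <- score_sequences(ds$keypresses)
  es <- error_rate_summary(seqs)
  expect_identical(sort(unique(es$by_position$seq_in_trial)), 1:5)
  # grand mean near the binomial expectation 5 * error_prob = 0.5
  n_seq <- sum(seqs$phase == "train")
  expect_lt(abs(es$grand_mean$mean_errors - 0.5),
            4 * sqrt(5 * 0.1 * 0.9 / n_seq) + 0.05)
  # all-zero errors give all-zero means
  seqs0 <- score_sequences(generate_participant(tiny_config(), spec))
  es0 <- error_rate_summary(seqs0)
  expect_true(all(es0$by_position$mean_errors == 0))
})

test_that("error-position correlation handles linear, constant, tiny input", {
  mk <- function(pos, err, ntrial = 3) {
    data.frame(participant = "p1", group = "S30", phase = "train",
               trial = rep(seq_len(ntrial), each = length(pos)),
               seq_in_trial = rep(pos, ntrial), rt_ms = 1000,
               n_errors_before = rep(err, ntrial),
               warmup = rep(pos, ntrial) == 1)
  }
  expect_equal(error_seq_correlation(mk(1:5, c(9, 1, 2, 3, 4)))$r, 1)
  expect_warning(r0 <- error_seq_correlation(mk(1:5, rep(2, 5))),
                 "zero variance")
  expect_identical(r0$r, 0)
  expect_error(error_seq_correlation(mk(1:5, 1:5, ntrial = 1),
                                     positions = 2:3),
               "at least 3")
})

test_that("a slope in the generator's error probability shows up as r > 0", {
  cfg <- tiny_config(error_prob = 0.02, error_slope = 0.02,
                     n_participants = 6)
  ds <- generate_dataset(cfg, groups = "M10")
  seqs <- score_sequences(ds$keypresses)
  expect_gt(error_seq_correlation(seqs)$r, 0)
})

test_that("participant averaging returns schedule-aligned means and SEs", {
  spec <- make_group_spec("M10")
  sch <- build_schedule(spec)
  kp1 <- generate_participant(tiny_config(), spec, "p1")
  s1 <- remove_warmups(score_sequences(kp1))
  # identity for a single participant
  avg1 <- average_over_participants(s1, sch)
  expect_equal(avg1$rt_mean, s1$rt_ms)
  expect_identical(unique(avg1$n_participants), 1L)
  # two participants with constant offset: mean is the midpoint
  s2 <- s1
  s2$participant <- "p2"
  s2$rt_ms <- s1$rt_ms + 100
  avg2 <- average_over_participants(rbind(s1, s2), sch)
  expect_equal(avg2$rt_mean, s1$rt_ms + 50)
  expect_equal(avg2$rt_se, rep(50, nrow(sch)))
})

test_that("preprocessing the noise-free generator recovers the model curve", {
  for (m in c("online", "hybridJ")) {
    p <- c(a = 1800, b = 2500, c = 0.004, k = 0.12, y = 20, z = 8)
    if (m == "hybridJ") p <- c(p, j = 3)
    cfg <- tiny_config(model = m, params = p)
    spec <- make_group_spec("S10")
    sch <- build_schedule(spec)
    modeled <- remove_warmups(score_sequences(generate_participant(cfg, spec)),
                              sch)
    expect_lt(max(abs(modeled$rt_ms - predict_rt(m, p, sch))), 1e-9)
  }
})
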