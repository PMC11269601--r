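sch_m <- build_schedule(make_group_spec("M10"))
sch_s <- build_schedule(make_group_spec("S30"))
consts_m <- attr(sch_m, "constants")
consts_s <- attr(sch_s, "constants")

test_that("epsilon shift leaves a 1e-10 base on the first trial", {
  expect_equal(epsilon_shift(1), 1e-10, tolerance = 1e-6)
  expect_equal(epsilon_shift(2), 1.0000000001)
  # inside the offline skill curve at trial 1 the value stays finite and,
  # for near-zero k, approaches a + b (skill before any break)
  p <- c(a = 2000, b = 1000, c = 0.1, k = 1e-12)
  sk <- skill_rt("offline_v1", p, sch_m[1, , drop = FALSE], consts_m)
  direct <- 2000 + 1000 * exp(-0.1 * 1e-10) * (1e-10)^(-1e-12)
  expect_equal(sk, direct, tolerance = 1e-12)
  expect_equal(sk, 3000, tolerance = 1e-6)
})

test_that("reactive inhibition is zero where the design says it must be", {
  p <- c(y = 10, z = 4)
  ri <- ri_rt(p, sch_m)
  # first modeled sequence of training trial 1
  expect_identical(ri[1], 0)
  # first modeled sequence of the first test trial (post-rest reset)
  first_test <- which(sch_m$x == 1)[1]
  expect_identical(ri[first_test], 0)
  # hand-computed interior value: ST = 5, T = 3 -> (5-1)*10 + (3-1)*4
  row <- which(sch_m$trial == 3 & sch_m$st == 5 & sch_m$x == 0)
  expect_identical(ri[row], 48)
  expect_error(ri_rt(c(y = 10), sch_m), "y and z")
})

test_that("reactive inhibition is separately linear in y and z", {
  base <- ri_rt(c(y = 7, z = 3), sch_m)
  only_y <- ri_rt(c(y = 7, z = 1e-300), sch_m)
  only_z <- ri_rt(c(y = 1e-300, z = 3), sch_m)
  expect_equal(base, only_y + only_z, tolerance = 1e-12)
  expect_equal(ri_rt(c(y = 14, z = 3), sch_m) - only_z, 2 * only_y,
               tolerance = 1e-12)
})

test_that("skill curves take their stated closed forms at anchor points", {
  p <- c(a = 1500, b = 2000, c = 0.01, k = 0.2, y = 10, z = 5)
  # online at S = 1: a + b e^{-c}
  expect_equal(skill_rt("online", p, sch_m)[1], 1500 + 2000 * exp(-0.01))
  # offline prediction is constant across ST within a trial
  off <- skill_rt("offline_v1", p[1:4], sch_m)
  expect_true(all(tapply(off, sch_m$trial_cum, function(v) diff(range(v))) == 0))
})

test_that("effective learning units conserve the total and hit hand values", {
  # conservation: on the last test sequence S' equals Stot for any j
  for (j in c(0, 1, 5, 13, 196 / 13)) {
    sp <- effective_units(sch_m, j, consts_m)
    expect_equal(sp[consts_m$Stot], consts_m$Stot, tolerance = 1e-12)
  }
  # j = 0 reduces to pure online units
  expect_equal(effective_units(sch_m, 0, consts_m), as.numeric(sch_m$s))
  # hand arithmetic: massed, j = 2, S = 14, T_cum = 1
  sp <- effective_units(sch_m, 2, consts_m)
  expect_equal(sp[14], 14 * (196 - 26) / 196)
  # monotone non-decreasing and non-negative
  sp <- effective_units(sch_m, 7, consts_m)
  expect_true(all(diff(sp) >= -1e-12))
  expect_true(all(sp >= 0))
  expect_error(effective_units(sch_m, -0.1, consts_m), "Stot/Btot")
  expect_error(effective_units(sch_m, 16, consts_m), "Stot/Btot")
})

test_that("overall predictions add RI only for with-RI variants", {
  p <- c(a = 1500, b = 2000, c = 0.01, k = 0.2, y = 10, z = 5)
  expect_identical(predict_rt("offline_v1", p[1:4], sch_m),
                   skill_rt("offline_v1", p[1:4], sch_m))
  on <- predict_rt("online", p, sch_m)
  expect_equal(on[1], skill_rt("online", p, sch_m)[1])  # RI = 0 on row 1
  expect_equal(on, skill_rt("online", p, sch_m) + ri_rt(p, sch_m))
  # vanishing RI slopes converge to the skill curve
  tiny <- p; tiny[c("y", "z")] <- 1e-9
  expect_equal(predict_rt("online", tiny, sch_m),
               skill_rt("online", tiny, sch_m), tolerance = 1e-6)
})

test_that("model registry exposes the eight variants with correct h", {
  expect_setequal(model_names(),
                  c("offline_v1", "offline_v2", "offline_v1_offset",
                    "offline_v2_offset", "online", "hybridJ", "hybridE",
                    "hybridP"))
  expect_identical(length(model_names(default_only = TRUE)), 6L)
  h <- vapply(model_names(), function(m) model_spec(m)$h, integer(1))
  expect_identical(h[["offline_v1"]], 4L)
  expect_identical(h[["offline_v1_offset"]], 5L)
  expect_identical(h[["offline_v2"]], 6L)
  expect_identical(h[["online"]], 6L)
  expect_identical(h[["hybridE"]], 6L)
  expect_identical(h[["hybridP"]], 6L)
  expect_identical(h[["offline_v2_offset"]], 7L)
  expect_identical(h[["hybridJ"]], 7L)
  expect_error(model_spec("nonsense"), "available models")
})

test_that("non-positive parameters are rejected", {
  p <- c(a = 1500, b = -1, c = 0.01, k = 0.2, y = 10, z = 5)
  expect_error(skill_rt("online", p, sch_m), "> 0")
  expect_error(skill_rt("online", p[-2], sch_m), "requires parameter")
})

test_that("predictions match the literal equation transcriptions", {
  set.seed(42)
  for (m in model_names()) {
    for (sched in list(sch_m, sch_s)) {
      consts <- attr(sched, "constants")
      for (rep in 1:50) {
        p <- oracle_draw(m, consts)
        expect_lt(max(abs(predict_rt(m, p, sched, consts) -
                            oracle_predict(m, p, sched, consts))), 1e-9)
      }
    }
  }
})

test_that("skill curves decrease in their practice argument", {
  set.seed(7)
  for (rep in 1:20) {
    p <- oracle_draw("online", consts_m)
    sk <- skill_rt("online", p, sch_m)
    # monotone throughout; strictly decreasing while increments are
    # representable at double precision
    expect_true(all(diff(sk) <= 0))
    expect_lt(sk[20], sk[1])
    po <- oracle_draw("offline_v1", consts_m)
    by_trial <- tapply(skill_rt("offline_v1", po, sch_m), sch_m$trial_cum,
                       unique)
    expect_true(all(diff(by_trial) <= 0))
    expect_lt(by_trial[3], by_trial[1])
  }
})

test_that("hybrid variants reduce to their limiting special cases", {
  p <- c(a = 1500, b = 2000, c = 0.01, k = 0.2, y = 10, z = 5)
  # hybridJ with j = 0 is the online model to machine precision
  pj <- c(p, j = 0)
  expect_equal(predict_rt("hybridJ", pj, sch_m), predict_rt("online", p, sch_m),
               tolerance = 1e-15)
  # hybridJ at j = Stot/Btot gains no online units within trials
  pj[["j"]] <- consts_m$Stot / consts_m$Btot
  sk <- skill_rt("hybridJ", pj, sch_m)
  within <- tapply(sk, sch_m$trial_cum, function(v) diff(range(v)))
  expect_true(all(within[-1] < 1e-9))
  # hybridE with c -> 0 is a pure power law of S (plus RI)
  pe <- p; pe[["c"]] <- 1e-14
  pure_power <- p[["a"]] + p[["b"]] * sch_m$s^(-p[["k"]]) + ri_rt(p, sch_m)
  expect_equal(predict_rt("hybridE", pe, sch_m), pure_power, tolerance = 1e-9)
  # hybridP with k -> 0 is a pure exponential in S (plus RI)
  pp <- p; pp[["k"]] <- 1e-16
  pure_exp <- p[["a"]] + p[["b"]] * exp(-p[["c"]] * sch_m$s) + ri_rt(p, sch_m)
  expect_equal(predict_rt("hybridP", pp, sch_m), pure_exp, tolerance = 1e-6)
})
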