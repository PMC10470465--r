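test_that("Experiment 1 sessions have 54 trials: 18 cells x 3 repetitions", {
  s <- build_session(1, seed = 1L)
  expect_identical(nrow(s$trials), 54L)
  counts <- table(s$trials$dimension, s$trials$axis, s$trials$irregularity)
  expect_identical(dim(counts), c(2L, 3L, 3L))
  expect_true(all(counts == 3L))
})

test_that("Experiment 2 sessions have 84 trials: 12 cells x 7, no x axis", {
  s <- build_session(2, seed = 1L)
  expect_identical(nrow(s$trials), 84L)
  expect_false("x" %in% s$trials$axis)
  counts <- table(s$trials$dimension, s$trials$axis, s$trials$irregularity)
  expect_true(all(counts == 7L))
})

test_that("unknown experiment ids are rejected", {
  expect_error(build_session(3), "unknown experiment")
})

test_that("session order is seed-deterministic with invariant cell counts", {
  a <- build_session(1, seed = 5L)
  b <- build_session(1, seed = 5L)
  c_ <- build_session(1, seed = 6L)
  expect_identical(a$trials, b$trials)
  expect_false(identical(a$trials, c_$trials))
  count_tab <- function(s) table(s$trials$dimension, s$trials$axis,
                                 s$trials$irregularity)
  expect_identical(count_tab(a), count_tab(c_))
})

test_that("dimension blocks are contiguous and alternate across sessions", {
  s1 <- build_session(1, seed = 2L, session = 1L)
  s2 <- build_session(1, seed = 2L, session = 2L)
  expect_identical(unique(s1$trials$dimension[s1$trials$block == 1]), 3L)
  expect_identical(unique(s2$trials$dimension[s2$trials$block == 1]), 4L)
  expect_identical(rle(s1$trials$block)$values, c(1L, 2L))
})

test_that("rigid placement is balanced within cells up to the odd repetition", {
  s <- build_session(1, seed = 7L)
  per_cell <- tapply(s$trials$rigid_position == "top",
                     interaction(s$trials$dimension, s$trials$axis,
                                 s$trials$irregularity), sum)
  expect_true(all(per_cell %in% 1:2)) # 3 reps: 1 or 2 on top
  s2 <- build_session(2, seed = 7L)
  per_cell2 <- tapply(s2$trials$rigid_position == "top",
                      interaction(s2$trials$dimension, s2$trials$axis,
                                  s2$trials$irregularity), sum)
  expect_true(all(per_cell2 %in% 3:4)) # 7 reps: 3 or 4 on top
})

test_that("a 5-subject cohort records 1,380 trials over both experiments", {
  # 5 x 2 x 54 (Exp 1, training session excluded) + 5 x 2 x 84 (Exp 2)
  sim <- simulate_cohort(5, seed = 11L)
  expect_identical(sum(!sim$results$training), 1380L)
  expect_identical(nrow(sim$results), 5L * 3L * 54L + 5L * 2L * 84L)
})

test_that("trial stimuli contain exactly one rigid trajectory, per the oracle", {
  s <- build_session(1, seed = 3L)
  for (i in c(1L, 30L)) {
    tr <- as.list(s$trials[i, ])
    stim <- make_trial_stimuli(tr, seed = 50L + i, jitter_amplitude = 0,
                               duration = 0.5, frame_rate = 20)
    rigid_flags <- c(top = assess_rigidity(stim$top, tol = 1e-6)$is_rigid,
                     bottom = assess_rigidity(stim$bottom, tol = 1e-6)$is_rigid)
    expect_identical(sum(rigid_flags), 1L)
    expect_true(rigid_flags[[stim$rigid]])
    expect_identical(stim$rigid, tr$rigid_position)
  }
})

test_that("an always-correct fast observer is recorded correct on every trial", {
  s <- build_session(1, seed = 4L)
  obs <- function(trial) list(choice = trial$rigid_position, rt = 500,
                              confidence = 5L)
  run <- run_session(s, obs, "fixed")
  expect_true(all(run$results$correct))
  expect_false(any(run$results$timed_out))
  expect_true(all(run$results$rt_ms <= 3000))
})

test_that("a silent observer times out on every trial with nothing recorded", {
  s <- build_session(2, seed = 4L)
  run <- run_session(s, function(trial) NULL, "active")
  expect_true(all(run$results$timed_out))
  expect_true(all(run$results$choice == "none"))
  expect_true(all(is.na(run$results$rt_ms)))
})

test_that("responses slower than the 3 s window are marked timed out", {
  s <- build_session(1, seed = 4L)
  obs <- function(trial) list(choice = trial$rigid_position,
                              rt = if (trial$trial == 1L) 3200 else 900,
                              confidence = 4L)
  run <- run_session(s, obs, "fixed")
  expect_true(run$results$timed_out[run$results$trial == 1L])
  expect_identical(sum(run$results$timed_out), 1L)
})

test_that("every trial carries a 54-sample head-pose trace", {
  s <- build_session(2, seed = 9L)
  obs <- synthetic_observer(default_profile("table2"))
  run <- run_session(s, obs, "active", seed = 1L)
  per_trial <- table(run$traces$trial)
  expect_identical(length(per_trial), 84L)
  expect_true(all(per_trial == 54L))
  # fixed mode: constant front-view trace
  runf <- run_session(build_session(1, seed = 9L),
                      function(trial) list(choice = "top", rt = 100,
                                           confidence = 3L), "fixed")
  expect_true(all(runf$traces$angle_x == 0 & runf$traces$angle_y == 0 &
                    runf$traces$angle_z == 0))
})

test_that("out-of-range confidence is a protocol violation", {
  s <- build_session(1, seed = 4L)
  expect_error(
    run_session(s, function(trial) list(choice = "top", rt = 500,
                                        confidence = 6L), "fixed"),
    "protocol violation")
  expect_error(
    run_session(s, function(trial) list(choice = "middle", rt = 500,
                                        confidence = 3L), "fixed"),
    "protocol violation")
})
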