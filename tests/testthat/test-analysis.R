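test_that("filtering drops overtime trials and builds the correct-trial RT view", {
  log <- toy_log(correct = c(TRUE, TRUE, FALSE, TRUE, NA, TRUE, FALSE, TRUE,
                             NA, TRUE),
                 timed_out = c(rep(FALSE, 4), TRUE, rep(FALSE, 3), TRUE, FALSE))
  f <- filter_trials(log)
  expect_identical(nrow(f$trials), 8L)
  expect_identical(nrow(f$rt_trials), 6L)
  expect_true(all(f$rt_trials$correct))
  # report reconciles with the input exactly
  rep_ <- setNames(f$report$n, f$report$stage)
  expect_identical(rep_[["input"]], 10L)
  expect_identical(rep_[["overtime"]], 2L)
  expect_identical(rep_[["analysable"]], 8L)
})

test_that("filtering is idempotent", {
  log <- withr::with_seed(1L, toy_log(correct = runif(60) < 0.8,
                                      confidence = sample(3:5, 60, TRUE)))
  f1 <- filter_trials(log)
  f2 <- filter_trials(f1$trials)
  expect_identical(f1$trials[order(f1$trials$trial), ],
                   f2$trials[order(f2$trials$trial), ])
})

test_that("a chance-level low-confidence subject is excluded (54.9%, conf 1.71)", {
  # 108 trials at 54.9% correct ~ 59 correct; mean confidence 1.71
  n <- 108
  correct <- c(rep(TRUE, 59), rep(FALSE, 49))
  conf <- as.integer(round(rep(c(1, 2, 2), length.out = n) * 1.71 / 1.667))
  conf <- pmin(5L, pmax(1L, conf))
  bad <- toy_log(correct = correct, confidence = conf, subject = "ZZ")
  good <- toy_log(correct = rep(c(TRUE, TRUE, TRUE, FALSE), 27),
                  confidence = rep(4L, n), subject = "OK")
  f <- filter_trials(rbind(bad, good))
  ex <- f$excluded_subjects
  expect_true(ex$excluded[ex$subject == "ZZ"])
  expect_false(ex$excluded[ex$subject == "OK"])
  expect_false("ZZ" %in% f$trials$subject)
  # high accuracy protects, as does high confidence at chance accuracy
  conf_high <- toy_log(correct = correct, confidence = rep(4L, n),
                       subject = "HC")
  f2 <- filter_trials(rbind(conf_high, good))
  expect_false(f2$excluded_subjects$excluded[f2$excluded_subjects$subject == "HC"])
})

test_that("condition summaries follow the percent-correct indicator convention", {
  all_correct <- toy_log(correct = rep(TRUE, 10))
  s <- summarize_conditions(all_correct)
  expect_equal(s$accuracy_pct, 100)
  expect_equal(s$accuracy_sd, 0)
  # one correct + one incorrect: mean 50, SD of {0, 100}
  half <- toy_log(correct = c(TRUE, FALSE))
  s2 <- summarize_conditions(half)
  expect_equal(s2$accuracy_pct, 50)
  expect_equal(s2$accuracy_sd, sd(c(0, 100)))
})

test_that("summaries use correct trials only for RT and mark empty cells NA", {
  log <- toy_log(correct = c(TRUE, FALSE, TRUE, FALSE),
                 rt = c(400, 2000, 600, 1800))
  s <- summarize_conditions(log)
  expect_equal(s$rt_mean, 500) # mean of 400, 600
  log2 <- rbind(log, toy_log(correct = logical(2), rt = c(100, 200),
                             dimension = 4L))
  s2 <- summarize_conditions(log2)
  expect_true(is.na(s2$rt_mean[s2$dimension == 4]))
})

test_that("parameter recovery: summaries reproduce the configured profile", {
  # moderately sized recovery run; the acceptance suite runs the full
  # n = 2000/cell sweep
  prof <- default_profile("table1", timeout_rate = 0)
  n_rep <- 40 # 40 sessions x 9 trials per (dimension, axis) cell
  sim <- withr::with_seed(8L, {
    obs <- synthetic_observer(prof)
    do.call(rbind, lapply(seq_len(n_rep), function(i) {
      run_session(build_session(1, seed = i, session = 2L), obs, "fixed")$results
    }))
  })
  s <- summarize_conditions(sim)
  for (i in seq_len(nrow(prof$cells))) {
    cell <- prof$cells[i, ]
    got <- s[s$dimension == cell$dimension & s$axis == cell$axis, ]
    n <- got$n_trials
    se_acc <- 100 * sqrt(cell$accuracy * (1 - cell$accuracy) / n)
    expect_lt(abs(got$accuracy_pct - 100 * cell$accuracy),
              3 * se_acc + 1e-9)
    expect_lt(abs(got$confidence_mean - cell$conf_mean),
              3 * cell$conf_sd / sqrt(n) + 0.25) # rounding to 1..5 biases slightly
  }
})

test_that("LMM F matches one-way ANOVA when between-subject variance is nil", {
  d <- withr::with_seed(10L, {
    dd <- expand.grid(subject = paste0("S", 1:6), g = c("a", "b"), rep = 1:50)
    dd$y <- rnorm(nrow(dd)) + ifelse(dd$g == "a", 0.2, 0)
    dd
  })
  got <- lmm_anova(d, "y", "g", random_group = "subject")
  oracle <- anova(aov(y ~ g, data = d))["g", "F value"]
  expect_equal(got$F[got$term == "g"], oracle, tolerance = 0.01)
  expect_identical(attr(got, "ddf_method"), "satterthwaite")
})

test_that("LMM recovers a known fixed effect with random intercepts", {
  d <- withr::with_seed(11L, {
    dd <- expand.grid(subject = paste0("S", 1:8), g = c("a", "b"), rep = 1:25)
    subj_off <- rnorm(8, sd = 2)[as.integer(factor(dd$subject))]
    dd$y <- 1 + ifelse(dd$g == "b", 1.5, 0) + subj_off + rnorm(nrow(dd))
    dd
  })
  got <- lmm_anova(d, "y", "g", random_group = "subject")
  expect_lt(got$p[got$term == "g"], 1e-6)
  expect_gt(got$df2[got$term == "g"], 10) # within-subject effect: large ddf
})

test_that("degenerate LMM designs are flagged", {
  d <- expand.grid(subject = "S1", g = c("a", "b"), rep = 1:10)
  d$y <- rnorm(nrow(d))
  expect_error(lmm_anova(d, "y", "g"), "degenerate")
  d2 <- expand.grid(subject = paste0("S", 1:4), g = c("a", "b"), rep = 1:10)
  d2$y <- 1
  got <- lmm_anova(d2, "y", "g")
  expect_true(isTRUE(attr(got, "degenerate")))
  expect_equal(got$F, 0)
})

test_that("confidence-RT correlation handles exact and degenerate cases", {
  log <- toy_log(correct = rep(TRUE, 5), rt = c(100, 200, 300, 400, 500),
                 confidence = 5:1)
  expect_equal(confidence_rt_correlation(log)$r, -1)
  const <- toy_log(correct = rep(TRUE, 5), confidence = rep(3L, 5))
  expect_error(confidence_rt_correlation(const), "zero variance")
  expect_error(confidence_rt_correlation(log[1:2, ]), ">= 3")
})

test_that("independent confidence and RT show near-zero correlation", {
  log <- withr::with_seed(12L, toy_log(
    correct = rep(TRUE, 5000),
    rt = runif(5000, 200, 2800),
    confidence = sample(1:5, 5000, replace = TRUE)))
  expect_lt(abs(confidence_rt_correlation(log)$r), 0.05)
})

test_that("head-movement stats follow the quartile oracle", {
  tr <- data.frame(trial = 1L, sample_index = 1:4,
                   angle_x = c(10, 20, 30, 40), angle_y = 5, angle_z = 0)
  got <- head_movement_stats(tr)
  expect_equal(got$median_x, 25)
  # type-7 quartiles of {10,20,30,40}: Q1 = 17.5, Q3 = 32.5
  expect_equal(got$range_x, 15)
  expect_equal(got$median_y, 5)
  expect_equal(got$range_y, 0)
})

test_that("visual angles vanish when gaze is aligned with the head-object vector", {
  pos <- matrix(c(0, 0, 150, 10, -5, 140), 2, 3, byrow = TRUE)
  dirs <- -pos / sqrt(rowSums(pos^2)) # looking straight at the origin
  ang <- visual_angles(pos, dirs)
  expect_lt(max(abs(ang)), 1e-4) # acos roundoff near collinearity
  # a pure yaw (rotation about y) registers on the y angle only
  yaw <- rotation_operator(3, "y", 15)
  ang2 <- visual_angles(pos[1, , drop = FALSE],
                        matrix(dirs[1, ] %*% t(yaw), 1))
  expect_equal(unname(ang2[1, "angle_y"]), 15, tolerance = 1e-9)
})
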