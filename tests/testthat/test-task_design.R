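test_that("modified learning schedule has 240 trials in 3 balanced blocks of 80", {
  spec <- pst_task_spec("modified")
  sch <- build_learning_schedule(spec, seed = 11)
  expect_equal(nrow(sch), 240L)
  expect_equal(as.vector(table(sch$block)), rep(80L, 3L))
  # equal pair allocation per block
  tab <- table(sch$block, sch$pair_label)
  expect_true(all(tab == 40L))
  # left/right counterbalance: high stimulus left on exactly half of
  # each pair's slots per block
  for (b in 1:3) for (p in c("AB", "CD")) {
    rows <- sch[sch$block == b & sch$pair_label == p, ]
    expect_equal(sum(rows$stim_left == rows$stim_hi), 20L)
  }
})

test_that("original learning blocks contain 20 slots per pair", {
  spec <- pst_task_spec("original")
  sch <- build_learning_schedule(spec, seed = 5)
  tab <- table(sch$block, sch$pair_label)
  expect_true(all(tab == 20L))
  expect_equal(nrow(sch), 7L * 60L)
})

test_that("no more than three consecutive trials of the same pair", {
  for (variant in c("modified", "original")) {
    sch <- build_learning_schedule(pst_task_spec(variant), seed = 7)
    for (b in unique(sch$block)) {
      runs <- rle(sch$pair_label[sch$block == b])
      expect_lte(max(runs$lengths), 3L)
    }
  }
})

test_that("schedules are identical for identical spec and seed", {
  spec <- pst_task_spec("modified")
  expect_identical(build_learning_schedule(spec, 42),
                   build_learning_schedule(spec, 42))
  expect_identical(build_session_schedule(spec, 42),
                   build_session_schedule(spec, 42))
  expect_false(identical(build_learning_schedule(spec, 42),
                         build_learning_schedule(spec, 43)))
})

test_that("exact-proportion mode realises feedback counts exactly", {
  spec <- pst_task_spec("modified", feedback_mode = "exact")
  sch <- build_learning_schedule(spec, seed = 3)
  ab <- sch[sch$pair_label == "AB", ]  # 120 slots at 80-20
  expect_equal(sum(ab$fb_hi), round(0.8 * nrow(ab)))
  expect_equal(sum(ab$fb_lo), round(0.2 * nrow(ab)))
  cd <- sch[sch$pair_label == "CD", ]  # 120 slots at 65-35
  expect_equal(sum(cd$fb_hi), round(0.65 * nrow(cd)))
})

test_that("bernoulli feedback converges to the nominal 80% rate", {
  spec <- pst_task_spec("modified")
  sch <- build_learning_schedule(spec, seed = 9, n_blocks = 50L)
  ab <- sch$fb_hi[sch$pair_label == "AB"]  # 2000 slots
  expect_lt(abs(mean(ab) - 0.8), 0.04)     # ~4 binomial SEs
})

test_that("novel phase enumerates all combinations the right number of times", {
  spec <- pst_task_spec("modified")
  nov <- build_novel_schedule(spec, seed = 1)
  expect_equal(nrow(nov), 90L)                       # 6 combos x 15
  expect_equal(as.vector(table(nov$pair_label)), rep(15L, 6L))
  expect_true(all(is.na(nov$fb_hi)))
  # stim_hi is always the higher-probability member
  probs <- spec$stim_probs
  expect_true(all(probs[nov$stim_hi] > probs[nov$stim_lo]))

  orig <- build_novel_schedule(pst_task_spec("original"), seed = 2)
  expect_equal(length(unique(orig$pair_label)), 15L)  # C(6,2)
  expect_equal(nrow(orig), 90L)                       # 15 x 6

  empty <- build_novel_schedule(pst_task_spec("modified", novel_reps = 0),
                                seed = 3)
  expect_equal(nrow(empty), 0L)
})

test_that("novel count equals C(n,2) * reps across spec variants", {
  for (reps in c(1L, 6L, 15L)) {
    for (variant in c("modified", "original")) {
      spec <- pst_task_spec(variant, novel_reps = reps)
      n_stim <- 2L * nrow(spec$pairs)
      expect_equal(nrow(build_novel_schedule(spec, seed = reps)),
                   choose(n_stim, 2L) * reps)
    }
  }
})

test_that("threshold gate requires strictly exceeding every pair's threshold", {
  spec <- pst_task_spec("original")
  expect_true(check_block_thresholds(c(0.70, 0.65, 0.55), spec))
  expect_false(check_block_thresholds(c(0.65, 0.65, 0.55), spec))  # tie fails
  expect_true(check_block_thresholds(c(1, 1, 1), spec))
  expect_false(check_block_thresholds(c(0.9, 0.9, 0.5), spec))
  expect_error(check_block_thresholds(c(0.7, 0.7), spec), "one accuracy")
  expect_error(check_block_thresholds(c(0.7, 0.7, 0.7),
                                      pst_task_spec("modified")),
               "no pass thresholds")
})

test_that("invalid specs are rejected", {
  spec <- pst_task_spec("modified")
  spec$pairs$p_hi[1] <- 0.4
  expect_error(validate_pst_spec(spec), "probabilities")
  spec2 <- pst_task_spec("modified")
  spec2$trials_per_learning_block <- 81L
  expect_error(validate_pst_spec(spec2), "divisible")
})

test_that("two-day session schedule composes all phases on the right days", {
  spec <- pst_task_spec("modified")
  sch <- build_session_schedule(spec, seed = 21)
  expect_equal(nrow(sch), 40L + 240L + 3L * 40L + 90L)
  expect_setequal(unique(sch$phase),
                  c("practice", "learning", "memory_immediate",
                    "memory_30min", "memory_24hr", "novel"))
  expect_true(all(sch$session_day[sch$phase %in%
    c("practice", "learning", "memory_immediate", "memory_30min")] == 1L))
  expect_true(all(sch$session_day[sch$phase %in%
    c("memory_24hr", "novel")] == 2L))
  # memory blocks allocate trials equally across pairs
  mem <- sch[sch$phase == "memory_30min", ]
  expect_equal(as.vector(table(mem$pair_label)), c(20L, 20L))
  expect_true(all(is.na(mem$fb_hi)))
})

test_that("session CSV round-trips through write/read", {
  sch <- build_session_schedule(pst_task_spec("modified"), seed = 4,
                                phases = c("learning"))
  path <- tempfile(fileext = ".csv")
  write_sessions(sch, path)
  back <- read_sessions(path)
  expect_equal(nrow(back), nrow(sch))
  expect_equal(back$pair_label, sch$pair_label)
  unlink(path)
})
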