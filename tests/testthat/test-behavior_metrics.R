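test_that("optimal accuracy counts responded trials only", {
  tr <- make_trials(phase = rep("learning", 4),
                    pair_label = "AB", stim_left = "A", stim_right = "B",
                    choice = c("A", "B", "A", NA),
                    chose_optimal = c(TRUE, FALSE, TRUE, NA),
                    feedback = c(1L, 0L, 1L, NA))
  expect_equal(optimal_accuracy(tr, "learning"), 100 * 2 / 3)
  expect_true(is.na(optimal_accuracy(tr, "novel")))  # empty scope: NA
  all_opt <- make_trials(rep("learning", 2), "AB", "A", "B",
                         c("A", "A"), chose_optimal = c(TRUE, TRUE))
  expect_equal(optimal_accuracy(all_opt), 100)
})

test_that("choose-A and avoid-B exclude learning pairs from the denominator", {
  spec <- pst_task_spec("modified")
  nov <- as.data.frame(build_novel_schedule(spec, seed = 2))
  # eligible choose-A pairs in the modified variant: AC, AD -> 30 trials
  has_a <- nov$stim_hi == "A" | nov$stim_lo == "A"
  eligible <- has_a & !(nov$pair_label %in% c("AB", "CD"))
  expect_equal(sum(eligible), 30L)
  # original variant: AC, AD, AE, AF -> 24 trials at 6 reps
  nov3 <- as.data.frame(build_novel_schedule(pst_task_spec("original"), 3))
  has_a3 <- nov3$stim_hi == "A" | nov3$stim_lo == "A"
  elig3 <- has_a3 & !(nov3$pair_label %in% c("AB", "CD", "EF"))
  expect_equal(sum(elig3), 24L)

  # lexicographic chooser: A always chosen when shown -> choose_a = 100,
  # B chosen whenever it is the alphabetically first stimulus -> avoid_b = 0
  nov$choice <- pmin(nov$stim_left, nov$stim_right)
  nov$phase <- "novel"
  expect_equal(choose_a(nov, learning_pairs = c("AB", "CD")), 100)
  expect_equal(avoid_b(nov, learning_pairs = c("AB", "CD")), 0)
})

test_that("choose-A uses only responded eligible trials and can be undefined", {
  tr <- make_trials(phase = rep("novel", 3),
                    pair_label = c("AC", "AC", "AD"),
                    stim_left = c("A", "C", "A"),
                    stim_right = c("C", "A", "D"),
                    choice = c("A", NA, "D"))
  expect_equal(choose_a(tr, learning_pairs = c("AB", "CD")), 50)
  # A never shown in eligible trials -> NA
  tr2 <- make_trials("novel", "AB", "A", "B", "A")
  expect_true(is.na(choose_a(tr2, learning_pairs = c("AB", "CD"))))
})

test_that("win-stay/lose-shift matches hand enumeration on a fixed sequence", {
  # within one pair: wins at t1,t2,t3 (2 stays), losses at t4,t5 (1 shift)
  tr <- make_trials(phase = rep("learning", 6),
                    pair_label = "AB", stim_left = "A", stim_right = "B",
                    choice = c("A", "A", "A", "B", "A", "A"),
                    feedback = c(1L, 1L, 1L, 0L, 0L, 1L))
  w <- wsls(tr)
  expect_equal(w[["win_stay"]], 2 / 3)
  expect_equal(w[["lose_shift"]], 1 / 2)
})

test_that("always-repeating and indifferent agents bracket the WSLS range", {
  tr <- make_trials(phase = rep("learning", 8),
                    pair_label = "AB", stim_left = "A", stim_right = "B",
                    choice = rep("A", 8),
                    feedback = c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 1L))
  w <- wsls(tr)
  expect_equal(w[["win_stay"]], 1)
  expect_equal(w[["lose_shift"]], 0)
  # beta = 0 agent hovers near 0.5 for both
  sch <- build_session_schedule(pst_task_spec("modified"), seed = 12,
                                phases = "learning")
  ses <- simulate_session(agent_params(beta = 0), sch, "HC", seed = 13)
  w2 <- wsls(ses)
  expect_lt(abs(w2[["win_stay"]] - 0.5), 0.12)
  expect_lt(abs(w2[["lose_shift"]] - 0.5), 0.12)
})

test_that("WSLS transitions are within-pair, so interleaving other pairs is inert", {
  base <- make_trials(phase = rep("learning", 4),
                      pair_label = "AB", stim_left = "A", stim_right = "B",
                      choice = c("A", "A", "B", "B"),
                      feedback = c(1L, 0L, 0L, 1L))
  mixed <- make_trials(phase = rep("learning", 8),
                       pair_label = rep(c("AB", "CD"), each = 1,
                                        times = 4),
                       stim_left = rep(c("A", "C"), 4),
                       stim_right = rep(c("B", "D"), 4),
                       choice = c("A", "C", "A", "D", "B", "C", "B", "D"),
                       feedback = c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L))
  # base AB sequence: one win transition (stay) -> win_stay = 1,
  # two loss transitions (one shift) -> lose_shift = 1/2
  expect_equal(wsls(base)[["win_stay"]], 1)
  expect_equal(wsls(base)[["lose_shift"]], 1 / 2)
  # interleaved: AB transitions unchanged; CD adds win->shift twice and
  # lose->shift once
  expect_equal(wsls(mixed)[["win_stay"]], 1 / 3)
  expect_equal(wsls(mixed)[["lose_shift"]], 2 / 3)
})

test_that("memory differences are later minus earlier and propagate NA", {
  expect_equal(unname(memory_differences(80, 80, 80)), c(0, 0))
  expect_equal(memory_differences(80, 75, 85)[["mem_diff_24_30"]], 10)
  expect_true(is.na(memory_differences(80, NA, 85)[["mem_diff_24_30"]]))
})

test_that("the chance-level filter flags conditions at or below 50% AB accuracy", {
  m <- data.frame(subject_id = c("s1", "s1", "s2"),
                  condition = c("ON-ON", "OFF-OFF", "ON-ON"),
                  ab_novel_accuracy = c(50, 90, NA))
  out <- apply_filter(m)
  expect_identical(out$filtered_out, c(TRUE, FALSE, NA))
})

test_that("filtering is per condition and leaves other metrics untouched", {
  cfg <- cohort_config("exp1", n_pd = 3, n_hc = 1, seed = 77,
                       beta_mean = 1, beta_sd = 0.3)  # weak learners
  m <- cohort_metrics(generate_cohort(cfg)$sessions)
  expect_true(all(c("filtered_out", "final_learning_accuracy") %in%
                    names(m)))
  # one row per (subject, condition)
  expect_equal(nrow(m), 3 * 4 + 1)
  # learning metrics are computed for filtered-out conditions too
  flagged <- m[!is.na(m$filtered_out) & m$filtered_out, ]
  if (nrow(flagged))
    expect_true(all(!is.na(flagged$final_learning_accuracy)))
})

test_that("phase metrics are invariant to row shuffling (except WSLS)", {
  sch <- build_session_schedule(pst_task_spec("modified"), seed = 91)
  ses <- simulate_session(agent_params(0.35, 0.3, 4), sch, "ON-ON",
                          seed = 92)
  set.seed(1)
  shuf <- ses[sample(nrow(ses)), ]
  expect_equal(optimal_accuracy(shuf, "learning"),
               optimal_accuracy(ses, "learning"))
  expect_equal(choose_a(shuf), choose_a(ses))
  expect_equal(avoid_b(shuf), avoid_b(ses))
})
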