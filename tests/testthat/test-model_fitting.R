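test_that("session likelihood matches an independent brute-force oracle", {
  set.seed(7)
  for (i in 1:10) {
    ses <- tiny_session(n_trials = 20, seed = i,
                        params = agent_params(runif(1), runif(1),
                                              runif(1, 0, 8)))
    ag <- runif(1); al <- runif(1); b <- runif(1, 0, 10)
    got <- session_nll(agent_params(ag, al, b), ses)
    want <- oracle_nll(ses, ag, al, b)
    expect_equal(as.numeric(got), want, tolerance = 1e-10)
  }
})

test_that("oracle equivalence also holds across phases with frozen values", {
  sch <- build_session_schedule(pst_task_spec("modified"), seed = 55)
  ses <- simulate_session(agent_params(0.4, 0.25, 3), sch, "ON-ON",
                          seed = 56)
  got <- session_nll(agent_params(0.31, 0.22, 2.5), ses)
  want <- oracle_nll(ses, 0.31, 0.22, 2.5)
  expect_equal(as.numeric(got), want, tolerance = 1e-8)
})

test_that("beta = 0 gives nll = n log 2, and a first trial contributes log 2", {
  ses <- tiny_session(n_trials = 20, seed = 3)
  nll <- session_nll(agent_params(beta = 0), ses)
  expect_equal(as.numeric(nll), attr(nll, "n_obs") * log(2),
               tolerance = 1e-12)
  one <- ses[1, , drop = FALSE]  # values still at q0: p = 0.5
  expect_equal(as.numeric(session_nll(agent_params(beta = 5), one)),
               log(2), tolerance = 1e-12)
})

test_that("equal-rate dual parameters reproduce the single-rate likelihood", {
  ses <- tiny_session(n_trials = 60, seed = 8)
  expect_equal(as.numeric(session_nll(agent_params(0.3, 0.3, 4), ses)),
               as.numeric(session_nll(agent_params(alpha_gain = 0.3,
                                                   alpha_loss = 0.3,
                                                   beta = 4), ses)))
  # and via the variant mapping used in fitting
  v <- model_variant("single")
  sp <- pstlearn:::variant_session_pars(c(0.3, 4), v, "ON")
  expect_equal(sp, c(0.3, 0.3, 4))
})

test_that("information criteria follow their definitions", {
  mk_fit <- function(nll, k, n, name = "dual") {
    structure(list(variant = list(name = name, k = k), nll = nll,
                   aic = 2 * k + 2 * nll, bic = k * log(n) + 2 * nll,
                   n_obs = n, converged = TRUE),
              class = "pst_fit")
  }
  f <- mk_fit(100, 3, 240)
  expect_equal(f$aic, 206)
  expect_equal(f$bic, 3 * log(240) + 200, tolerance = 1e-10)  # ~216.44
  # identical nll: smaller k ranked first
  tab <- compare_models(list(mk_fit(100, 3, 240, "dual"),
                             mk_fit(100, 2, 240, "single")))
  expect_equal(tab$variant[1], "single")
  expect_equal(sum(tab$weight), 1)
  # mismatched data refused
  expect_error(compare_models(list(mk_fit(100, 2, 240),
                                   mk_fit(90, 2, 200))),
               "identical data")
})

test_that("fitted models respect the nested-likelihood inequality", {
  for (i in 1:3) {
    ses <- tiny_session(n_trials = 160, seed = 20 + i,
                        params = agent_params(0.4, 0.2, 5))
    f1 <- fit_mle(ses, "single", n_restarts = 6, seed = 1)
    f2 <- fit_mle(ses, "dual", n_restarts = 6, seed = 1,
                  extra_starts = nested_start(f1, "dual"))
    expect_lte(f2$nll, f1$nll + 1e-6)
    expect_true(f1$converged && f2$converged)
  }
})

test_that("fitting is deterministic given the seed and beats its start points", {
  ses <- tiny_session(n_trials = 160, seed = 33,
                      params = agent_params(0.35, 0.35, 5))
  f_a <- fit_mle(ses, "dual", n_restarts = 8, seed = 4)
  f_b <- fit_mle(ses, "dual", n_restarts = 8, seed = 4)
  expect_identical(f_a$estimates, f_b$estimates)
  # fitted nll no worse than a mid-range start evaluated directly
  mid <- session_nll(agent_params(0.5, 0.5, 5), ses,
                     likelihood_phases = pstlearn:::LIK_PHASES)
  expect_lte(f_a$nll, as.numeric(mid))
})

test_that("learning rates recover from 240-trial sessions", {
  rec <- parameter_recovery_report(alpha_grid = c(0.15, 0.45, 0.75),
                                   beta = 5, n_sims = 3, n_trials = 240,
                                   n_restarts = 4, seed = 11)
  expect_equal(nrow(rec), 3L)
  expect_gt(attr(rec, "recovery_cor")[["alpha"]], 0.5)
  expect_true(all(abs(rec$bias) < 0.25))
})

test_that("recovery degrades with fewer trials", {
  rec_big <- parameter_recovery_report(alpha_grid = c(0.2, 0.6),
                                       n_sims = 4, n_trials = 240,
                                       n_restarts = 4, seed = 21)
  rec_small <- parameter_recovery_report(alpha_grid = c(0.2, 0.6),
                                         n_sims = 4, n_trials = 24,
                                         n_restarts = 4, seed = 21)
  expect_gt(mean(rec_small$rmse), mean(rec_big$rmse))
})

test_that("an empty recovery request returns an empty table", {
  rec <- parameter_recovery_report(n_sims = 0)
  expect_s3_class(rec, "data.frame")
  expect_equal(nrow(rec), 0L)
})

test_that("a near-random generator triggers the identifiability warning", {
  ses <- tiny_session(n_trials = 240, seed = 61,
                      params = agent_params(beta = 0))
  f <- fit_mle(ses, "single", n_restarts = 6, seed = 2)
  expect_lt(f$estimates[["beta"]], 1)
  expect_true(f$identifiability_warning)
})

test_that("state-conditional fits need both medication states", {
  on <- tiny_session(n_trials = 40, seed = 71, condition = "ON")
  expect_error(fit_mle(list(on), "dual_by_state"), "per state")
  off <- tiny_session(n_trials = 40, seed = 72, condition = "OFF")
  f <- fit_mle(list(on, off), "dual_by_state", n_restarts = 4, seed = 3)
  expect_equal(f$variant$k, 5L)
  expect_named(f$estimates, c("alpha_gain_ON", "alpha_loss_ON",
                              "alpha_gain_OFF", "alpha_loss_OFF", "beta"))
})
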