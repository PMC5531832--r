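# Independent oracles and small fixture builders used across tests.

# Straight-line reimplementation of the session likelihood: tracks values
# in a named list, computes each softmax probability from its exponential
# form, and multiplies probabilities trial by trial.  Deliberately written
# differently from the package's likelihood code.
oracle_nll <- function(trials, alpha_gain, alpha_loss, beta, q0 = 0.5,
                       lik_phases = c("learning", "memory_immediate",
                                      "memory_30min", "memory_24hr",
                                      "novel"),
                       upd_phases = c("practice", "learning")) {
  stims <- unique(c(trials$stim_left, trials$stim_right))
  q <- as.list(stats::setNames(rep(q0, length(stims)), stims))
  total <- 1
  log_total <- 0
  for (i in seq_len(nrow(trials))) {
    ch <- trials$choice[i]
    if (is.na(ch) || ch == "") next
    ot <- if (ch == trials$stim_left[i]) trials$stim_right[i]
          else trials$stim_left[i]
    ea <- exp(beta * q[[ch]])
    eb <- exp(beta * q[[ot]])
    p <- ea / (ea + eb)
    if (trials$phase[i] %in% lik_phases) log_total <- log_total + log(p)
    if (trials$phase[i] %in% upd_phases && !is.na(trials$feedback[i])) {
      delta <- trials$feedback[i] - q[[ch]]
      a <- if (delta > 0) alpha_gain else alpha_loss
      q[[ch]] <- q[[ch]] + a * delta
    }
  }
  -log_total
}

# Exact Wilcoxon signed-rank p-value by full enumeration of all 2^n sign
# assignments (two-tailed doubling convention, ties via average ranks).
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Classical sums-of-squares decomposition of a fully within-subject 2x2
# design, with effect-specific (effect x subject) error terms.  Columns
# ordered (A1B1, A1B2, A2B1, A2B2).  Returns F statistics for factor A,
# factor B and the interaction.
rm_anova_ss <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  grand <- mean(scores)
  subj <- rowMeans(scores)
  a_means <- c(mean(scores[, 1:2]), mean(scores[, 3:4]))
  b_means <- c(mean(scores[, c(1, 3)]), mean(scores[, c(2, 4)]))
  cell_means <- colMeans(scores)
  a_of <- c(1, 1, 2, 2); b_of <- c(1, 2, 1, 2)
  ss_total <- sum((scores - grand)^2)
  ss_s <- 4 * sum((subj - grand)^2)
  ss_a <- 2 * n * sum((a_means - grand)^2)
  ss_b <- 2 * n * sum((b_means - grand)^2)
  ss_ab <- n * sum((cell_means - a_means[a_of] - b_means[b_of] + grand)^2)
  y_ia <- cbind(rowMeans(scores[, 1:2]), rowMeans(scores[, 3:4]))
  ss_as <- 2 * sum((sweep(y_ia, 2, a_means) - (subj - grand))^2)
  y_ib <- cbind(rowMeans(scores[, c(1, 3)]), rowMeans(scores[, c(2, 4)]))
  ss_bs <- 2 * sum((sweep(y_ib, 2, b_means) - (subj - grand))^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  df_err <- n - 1
  c(A = ss_a / (ss_as / df_err),
    B = ss_b / (ss_bs / df_err),
    AB = ss_ab / (ss_abs / df_err))
}

# A small learning-only session: first `n_trials` rows of a modified
# learning schedule, simulated with the given agent.
tiny_session <- function(n_trials = 20, seed = 1, params = agent_params(),
                         condition = "HC") {
  spec <- pst_task_spec("modified")
  sch <- build_learning_schedule(spec, seed)
  sch <- sch[seq_len(n_trials), , drop = FALSE]
  attr(sch, "spec") <- spec
  simulate_session(params, sch, condition, seed = seed + 1000)
}

# Hand-built trial-record data frame (defaults give a valid skeleton).
make_trials <- function(phase, pair_label, stim_left, stim_right, choice,
                        feedback = NA_integer_, chose_optimal = NA,
                        block = 1L) {
  data.frame(subject_id = "s1", group = "PD", condition = "ON",
             session_day = 1L, phase = phase, block = block,
             trial = seq_along(phase), pair_label = pair_label,
             stim_left = stim_left, stim_right = stim_right,
             choice = choice, chose_optimal = chose_optimal,
             feedback = feedback, stringsAsFactors = FALSE)
}
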