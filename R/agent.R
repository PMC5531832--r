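#' Q-learning agent parameters
#'
#' Bundles the parameters of a softmax Q-learning agent with separate
#' learning rates for positive and negative reward prediction errors, an
#' inverse temperature, an initial action value and an overnight
#' retention fraction.
#'
#' `alpha_gain`, `alpha_loss`, `beta` and `rho` may each be either a
#' single number (state-independent) or a named vector `c(ON = , OFF = )`
#' conditioning the parameter on medication state. When simulating a
#' two-day condition such as `"ON-OFF"`, the day-1 state selects the
#' learning rates and the retention fraction, and the day-2 state selects
#' the test-phase inverse temperature, so learning, consolidation and
#' expression effects can be injected independently.
#'
#' @param alpha_gain Learning rate in `[0, 1]` applied when the
#'   prediction error `r - Q` is positive.
#' @param alpha_loss Learning rate in `[0, 1]` applied when it is
#'   negative (a single-rate agent sets `alpha_loss = alpha_gain`).
#' @param beta Softmax inverse temperature, `>= 0`.
#' @param q0 Initial action value for every stimulus (default 0.5,
#'   chance-level prior on a 0/1 reward scale).
#' @param rho Retention fraction in `[0, 1]`: the proportion of each
#'   value's deviation from `q0` preserved across the overnight interval.
#' @param beta_test Optional inverse temperature used in the
#'   feedback-free test phases (memory and novel), resolved by the
#'   medication state of the day the phase falls on; defaults to `beta`.
#'   Lets an expression effect be injected without touching learning.
#' @return An object of class `pst_agent`.
#' @examples
#' agent_params(alpha_gain = 0.4, alpha_loss = 0.2, beta = 5)
#' # consolidation depends on day-1 medication state:
#' agent_params(0.3, 0.3, 5, rho = c(ON = 0.95, OFF = 0.6))
#' @export
agent_params <- function(alpha_gain = 0.3, alpha_loss = 0.3, beta = 5,
                         q0 = 0.5, rho = 1, beta_test = NULL) {
  check_bounds <- function(x, lo, hi, nm) {
    if (any(x < lo | x > hi))
      stop(sprintf("%s must lie in [%g, %g]", nm, lo, hi))
  }
  check_bounds(alpha_gain, 0, 1, "alpha_gain")
  check_bounds(alpha_loss, 0, 1, "alpha_loss")
  if (any(beta < 0)) stop("beta must be non-negative")
  check_bounds(q0, 0, 1, "q0")
  check_bounds(rho, 0, 1, "rho")
  if (!is.null(beta_test) && any(beta_test < 0))
    stop("beta_test must be non-negative")
  structure(list(alpha_gain = alpha_gain, alpha_loss = alpha_loss,
                 beta = beta, q0 = q0, rho = rho,
                 beta_test = beta_test),
            class = "pst_agent")
}

## Pick the value of a possibly state-conditional parameter.
state_param <- function(x, state) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && state %in% names(x)) return(unname(x[[state]]))
  unname(x[[1L]])
}

#' Parse a condition label into day-1 and day-2 medication states
#'
#' `"ON-OFF"` means ON medication during day-1 learning, OFF during
#' day-2 testing. Single-day labels (`"ON"`, `"OFF"`) apply to both
#' phases; `"HC"` (healthy control) has no medication state and resolves
#' to the agent's unconditioned parameter values.
#'
#' @param condition Condition label.
#' @return List with elements `day1` and `day2`.
#' @export
parse_condition <- function(condition) {
  known <- c("ON-ON", "ON-OFF", "OFF-ON", "OFF-OFF", "ON", "OFF", "HC")
  if (!condition %in% known)
    stop("unknown condition label: ", condition)
  if (condition == "HC") return(list(day1 = "HC", day2 = "HC"))
  parts <- strsplit(condition, "-", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  list(day1 = parts[1L], day2 = parts[2L])
}

#' Delta-rule value update
#'
#' `Q <- Q + alpha * (r - Q)` for the chosen stimulus only, with
#' `alpha = alpha_gain` when the prediction error `r - Q` is positive and
#' `alpha = alpha_loss` when negative (at exactly zero no update occurs,
#' so the selector is irrelevant there). With feedback in `{0, 1}` and
#' `alpha` in `[0, 1]`, values stay in `[0, 1]`.
#'
#' @param values Named numeric vector of current action values.
#' @param choice Stimulus id of the chosen option.
#' @param feedback 0 or 1.
#' @param params A [agent_params()] object (state-conditional parameters
#'   must already be resolved to scalars, or `state` given).
#' @param state Optional medication state used to resolve
#'   state-conditional learning rates.
#' @return The updated value vector.
#' @examples
#' q <- c(A = 0.5, B = 0.5)
#' q_update(q, "A", 0, agent_params(alpha_loss = 0.2))["A"]  # 0.4
#' @export
q_update <- function(values, choice, feedback, params, state = "HC") {
  if (!choice %in% names(values))
    stop("unknown stimulus: ", choice)
  stopifnot(feedback %in% c(0, 1))
  pe <- feedback - values[[choice]]
  alpha <- if (pe > 0) state_param(params$alpha_gain, state)
           else state_param(params$alpha_loss, state)
  values[[choice]] <- values[[choice]] + alpha * pe
  values
}

#' Softmax probability of choosing option a over option b
#'
#' `p(a) = 1 / (1 + exp(-beta * (q_a - q_b)))`; the two options'
#' probabilities sum to 1, and `beta = 0` yields indifference (0.5).
#'
#' @param q_a,q_b Action values.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability of choosing `a`, in `(0, 1)`.
#' @examples
#' softmax_choice_prob(0.8, 0.3, 2)  # 1/(1 + exp(-1)) = 0.7311
#' @export
softmax_choice_prob <- function(q_a, q_b, beta) {
  if (any(beta < 0)) stop("beta must be non-negative")
  stats::plogis(beta * (q_a - q_b))
}

#' Overnight value retention (consolidation stage)
#'
#' Shrinks every action value toward the initial value:
#' `Q' = q0 + rho * (Q - q0)`. `rho = 1` preserves the learned values
#' perfectly, `rho = 0` resets them to baseline; intermediate values
#' model partial overnight consolidation of the learned preferences.
#'
#' @param values Named numeric vector of action values.
#' @param rho Retention fraction in `[0, 1]`.
#' @param q0 Baseline value.
#' @return The transformed value vector.
#' @examples
#' apply_retention(c(A = 0.9), rho = 0.5, q0 = 0.5)  # 0.7
#' @export
apply_retention <- function(values, rho, q0) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  q0 + rho * (values - q0)
}

#' Simulate an agent performing a full session
#'
#' Walks a session schedule trial by trial: choices are sampled from the
#' softmax over current action values, values are updated by the delta
#' rule on feedback trials only (practice and learning phases), memory
#' and novel phases are performed with frozen values, and the retention
#' transform is applied once between the 30-min and 24-hr memory blocks
#' when the schedule spans two days. For the threshold-gated design,
#' learning blocks stop early once every pair's within-block accuracy
#' strictly exceeds its threshold (at the latest after `max_blocks`).
#'
#' @param params An [agent_params()] object.
#' @param schedule A schedule from [build_session_schedule()] (or any
#'   schedule data frame with the same columns and a `spec` attribute).
#' @param condition Condition label (see [parse_condition()]); selects
#'   state-conditional parameters.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param subject_id,group Identifiers copied into the output records.
#' @return A data frame of trial records with columns `subject_id`,
#'   `group`, `condition`, `session_day`, `phase`, `block`, `trial`,
#'   `pair_label`, `stim_left`, `stim_right`, `choice`, `chose_optimal`
#'   and `feedback` (`NA` outside feedback phases).
#' @export
simulate_session <- function(params, schedule, condition = "HC", seed,
                             subject_id = "s1", group = NULL) {
  stopifnot(inherits(params, "pst_agent"))
  spec <- attr(schedule, "spec")
  if (is.null(spec)) stop("schedule carries no task spec")
  states <- parse_condition(condition)
  group <- group %||% if (condition == "HC") "HC" else "PD"

  a_gain <- state_param(params$alpha_gain, states$day1)
  a_loss <- state_param(params$alpha_loss, states$day1)
  beta1 <- state_param(params$beta, states$day1)
  bt <- params$beta_test %||% params$beta
  beta_test1 <- state_param(bt, states$day1)
  beta_test2 <- state_param(bt, states$day2)
  rho <- state_param(params$rho, states$day1)
  q0 <- params$q0

  stims <- names(spec$stim_probs)
  n <- nrow(schedule)
  phase <- schedule$phase
  block <- schedule$block
  day <- schedule$session_day
  hi_i <- match(schedule$stim_hi, stims)
  lo_i <- match(schedule$stim_lo, stims)
  fb_hi <- schedule$fb_hi
  fb_lo <- schedule$fb_lo
  is_fb <- phase %in% c("practice", "learning")
  gated <- !is.null(spec$pass_thresholds)
  n_pairs <- nrow(spec$pairs)
  pair_of_hi <- match(schedule$stim_hi, spec$pairs$hi)

  q <- rep(q0, length(stims))
  u <- with_seed(seed, stats::runif(n))
  choice <- character(n)
  chose_opt <- logical(n)
  fb_out <- rep(NA_integer_, n)
  keep <- rep(TRUE, n)
  learning_done <- FALSE
  retention_done <- FALSE
  blk_correct <- rep(0L, n_pairs)
  blk_total <- rep(0L, n_pairs)
  last_block <- 0L

  for (t in seq_len(n)) {
    ph <- phase[t]
    if (ph == "learning" && gated) {
      if (block[t] != last_block && last_block > 0L) {
        accs <- ifelse(blk_total > 0L, blk_correct / blk_total, 0)
        if (check_block_thresholds(accs, spec)) learning_done <- TRUE
        blk_correct[] <- 0L; blk_total[] <- 0L
      }
      last_block <- block[t]
      if (learning_done) { keep[t] <- FALSE; next }
    }
    if (ph == "memory_24hr" && !retention_done) {
      q <- q0 + rho * (q - q0)
      retention_done <- TRUE
    }
    b <- if (is_fb[t]) beta1
         else if (isTRUE(day[t] == 2L)) beta_test2 else beta_test1
    p_hi <- stats::plogis(b * (q[hi_i[t]] - q[lo_i[t]]))
    hi_chosen <- u[t] < p_hi
    idx <- if (hi_chosen) hi_i[t] else lo_i[t]
    choice[t] <- stims[idx]
    chose_opt[t] <- hi_chosen
    if (is_fb[t]) {
      r <- if (hi_chosen) fb_hi[t] else fb_lo[t]
      fb_out[t] <- r
      pe <- r - q[idx]
      alpha <- if (pe > 0) a_gain else a_loss
      q[idx] <- q[idx] + alpha * pe
      if (ph == "learning" && gated) {
        pr <- pair_of_hi[t]
        blk_total[pr] <- blk_total[pr] + 1L
        blk_correct[pr] <- blk_correct[pr] + as.integer(hi_chosen)
      }
    }
  }

  out <- fast_df(list(
    subject_id = subject_id, group = group, condition = condition,
    session_day = day, phase = phase, block = block,
    trial = seq_len(n),
    pair_label = schedule$pair_label,
    stim_left = schedule$stim_left, stim_right = schedule$stim_right,
    choice = choice, chose_optimal = chose_opt, feedback = fb_out))
  out <- out[keep, , drop = FALSE]
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}
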