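## Likelihood, maximum-likelihood fitting and model comparison for the
## Q-learning variant family.

LIK_PHASES <- c("learning", "memory_immediate", "memory_30min",
                "memory_24hr", "novel")
UPDATE_PHASES <- c("practice", "learning")

## Precompute per-session integer/logical vectors once so the inner
## likelihood loop stays cheap inside the optimiser.
prep_session <- function(trials, likelihood_phases, update_phases) {
  responded <- !is.na(trials$choice) & trials$choice != ""
  stims <- sort(unique(c(trials$stim_left, trials$stim_right)))
  other <- ifelse(trials$choice == trials$stim_left,
                  trials$stim_right, trials$stim_left)
  keep <- responded
  list(
    ci = match(trials$choice, stims)[keep],
    oi = match(other, stims)[keep],
    fb = trials$feedback[keep],
    upd = (trials$phase %in% update_phases &
             !is.na(trials$feedback))[keep],
    lik = (trials$phase %in% likelihood_phases)[keep],
    n_stim = length(stims)
  )
}

nll_core <- function(prep, alpha_gain, alpha_loss, beta, q0) {
  q <- rep(q0, prep$n_stim)
  ci <- prep$ci; oi <- prep$oi; fb <- prep$fb
  upd <- prep$upd; lik <- prep$lik
  nll <- 0
  for (t in seq_along(ci)) {
    if (lik[t])
      nll <- nll - stats::plogis(beta * (q[ci[t]] - q[oi[t]]),
                                 log.p = TRUE)
    if (upd[t]) {
      pe <- fb[t] - q[ci[t]]
      a <- if (pe > 0) alpha_gain else alpha_loss
      q[ci[t]] <- q[ci[t]] + a * pe
    }
  }
  nll
}

#' Negative log-likelihood of one session under a Q-learning agent
#'
#' Replays the observed choices: action values start at `q0`, evolve by
#' the delta rule on feedback trials (practice and learning phases) using
#' the *observed* choices and feedback, and stay frozen during memory and
#' novel phases. Every responded choice trial in `likelihood_phases`
#' contributes `-log p(observed choice)` under the softmax; unanswered
#' trials are skipped. Practice trials update values (their stimuli are
#' disjoint from the learning pairs) but do not contribute likelihood by
#' default.
#'
#' @param params An [agent_params()] object, or any list with scalar
#'   `alpha_gain`, `alpha_loss`, `beta`, `q0`.
#' @param trials Trial records of one session ([simulate_session()]
#'   output or a session CSV read back).
#' @param likelihood_phases Phases whose choices enter the likelihood.
#' @param update_phases Phases whose feedback drives value updates.
#' @param state Medication state used to resolve state-conditional
#'   parameters (defaults to the session's day-1 state).
#' @return The negative log-likelihood (non-negative), with the number of
#'   contributing choice trials attached as attribute `n_obs`.
#' @examples
#' sch <- build_session_schedule(pst_task_spec("modified"), seed = 1,
#'                               design = "same_day")
#' ses <- simulate_session(agent_params(beta = 3), sch, "HC", seed = 2)
#' session_nll(agent_params(beta = 3), ses)
#' @export
session_nll <- function(params, trials,
                        likelihood_phases = LIK_PHASES,
                        update_phases = UPDATE_PHASES,
                        state = NULL) {
  if (is.null(trials) || nrow(trials) == 0L)
    stop("empty session")
  state <- state %||%
    parse_condition(trials$condition[1L] %||% "HC")$day1
  prep <- prep_session(trials, likelihood_phases, update_phases)
  if (sum(prep$lik) == 0L) stop("session has no likelihood-contributing trials")
  nll <- nll_core(prep,
                  state_param(params$alpha_gain, state),
                  state_param(params$alpha_loss, state),
                  state_param(params$beta, state),
                  params$q0 %||% 0.5)
  structure(nll, n_obs = sum(prep$lik))
}

#' Q-learning model variants
#'
#' The fitted family: `"single"` one learning rate plus inverse
#' temperature (k = 2); `"dual"` separate gain/loss learning rates
#' (k = 3); `"dual_by_state"` gain/loss rates per day-1 medication state
#' with a shared inverse temperature (k = 5). `"single"` is nested in
#' `"dual"`, which is nested in `"dual_by_state"`.
#'
#' @param name Variant name.
#' @return List with `name`, parameter `names`, and count `k`.
#' @export
model_variant <- function(name = c("single", "dual", "dual_by_state")) {
  name <- match.arg(name)
  par_names <- switch(name,
    single = c("alpha", "beta"),
    dual = c("alpha_gain", "alpha_loss", "beta"),
    dual_by_state = c("alpha_gain_ON", "alpha_loss_ON",
                      "alpha_gain_OFF", "alpha_loss_OFF", "beta"))
  list(name = name, names = par_names, k = length(par_names))
}

## Map a raw parameter vector to per-session (alpha_gain, alpha_loss,
## beta) triples given each session's day-1 state.
variant_session_pars <- function(par, variant, state) {
  switch(variant$name,
    single = c(par[1L], par[1L], par[2L]),
    dual = c(par[1L], par[2L], par[3L]),
    dual_by_state = if (state == "OFF") c(par[3L], par[4L], par[5L])
                    else c(par[1L], par[2L], par[5L]))
}

#' Fit a Q-learning variant to one subject's sessions by maximum likelihood
#'
#' Bounded multi-start local optimisation (`optim` L-BFGS-B) of the
#' summed session negative log-likelihoods. Learning rates are bounded to
#' `[0, 1]` and the inverse temperature to `[0, beta_max]`; starting
#' points are drawn uniformly within bounds, and the lowest-NLL solution
#' across restarts is returned. Deterministic given `seed`.
#'
#' @param sessions A single session data frame or a list of them, all
#'   from one subject. The state-conditional variant requires at least
#'   one session per medication state.
#' @param variant Variant name or [model_variant()] object.
#' @param n_restarts Number of optimisation restarts (default 20).
#' @param seed Integer seed for the start draws.
#' @param q0 Initial action value (fixed, not fitted).
#' @param beta_max Upper bound on the inverse temperature; beyond ~50
#'   choices are effectively greedy and the likelihood is flat.
#' @param likelihood_phases,update_phases Passed to [session_nll()].
#' @param extra_starts Optional numeric matrix (rows of length `k`) of
#'   additional start points, e.g. a nested model's solution expanded to
#'   this variant's parameterisation (warm-starting guarantees the
#'   nested-model likelihood inequality up to optimiser tolerance).
#' @return An object of class `pst_fit`: fitted `estimates`, `nll`,
#'   `aic` (`2k + 2 nll`), `bic` (`k log n_obs + 2 nll`), `n_obs`,
#'   `n_restarts`, `converged` (any restart converged) and
#'   `identifiability_warning` (inverse temperature near zero, under
#'   which the learning rates are weakly identified).
#' @export
fit_mle <- function(sessions, variant = "dual", n_restarts = 20L,
                    seed = 1L, q0 = 0.5, beta_max = 50,
                    likelihood_phases = LIK_PHASES,
                    update_phases = UPDATE_PHASES,
                    extra_starts = NULL) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  if (!length(sessions)) stop("no sessions supplied")
  if (is.character(variant)) variant <- model_variant(variant)
  states <- vapply(sessions, function(s)
    parse_condition(s$condition[1L] %||% "HC")$day1, character(1L))
  if (variant$name == "dual_by_state" &&
      !all(c("ON", "OFF") %in% states))
    stop("state-conditional variant needs at least one session per state")
  preps <- lapply(sessions, prep_session, likelihood_phases,
                  update_phases)
  n_obs <- sum(vapply(preps, function(p) sum(p$lik), integer(1L)))
  if (n_obs == 0L) stop("no likelihood-contributing trials")

  objective <- function(par) {
    tot <- 0
    for (i in seq_along(preps)) {
      sp <- variant_session_pars(par, variant, states[i])
      tot <- tot + nll_core(preps[[i]], sp[1L], sp[2L], sp[3L], q0)
    }
    tot
  }

  k <- variant$k
  lower <- rep(0, k); upper <- c(rep(1, k - 1L), beta_max)
  # learning-rate starts uniform in [0,1]; inverse-temperature starts
  # log-uniform in [0.5, beta_max] (uniform starts concentrate in the
  # flat near-greedy region, where gradient steps stall); the first
  # start is a fixed mid-range point so every fit tries a sane basin
  starts <- with_seed(seed, {
    m <- matrix(stats::runif(n_restarts * k), nrow = n_restarts)
    m[, k] <- exp(stats::runif(n_restarts, log(0.5), log(beta_max)))
    m[1L, ] <- c(rep(0.3, k - 1L), 4)
    m
  })
  if (!is.null(extra_starts)) {
    es <- matrix(as.numeric(extra_starts), ncol = k)
    es <- pmin(pmax(es, rep(lower, each = nrow(es))),
               rep(upper, each = nrow(es)))
    starts <- rbind(starts, es)
  }
  n_restarts <- nrow(starts)
  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[r, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(variant = variant, estimates = NULL,
                          nll = NA_real_, aic = NA_real_, bic = NA_real_,
                          n_obs = n_obs, n_restarts = n_restarts,
                          converged = FALSE,
                          identifiability_warning = TRUE),
                     class = "pst_fit"))
  est <- stats::setNames(best$par, variant$names)
  nll <- best$value
  structure(list(
    variant = variant, estimates = est, nll = nll,
    aic = 2 * variant$k + 2 * nll,
    bic = variant$k * log(n_obs) + 2 * nll,
    n_obs = n_obs, n_restarts = n_restarts, converged = any_conv,
    identifiability_warning = unname(est["beta"] < 0.2)),
    class = "pst_fit")
}

#' @export
print.pst_fit <- function(x, ...) {
  cat("Q-learning fit:", x$variant$name,
      sprintf("(k = %d, n_obs = %d)\n", x$variant$k, x$n_obs))
  if (!is.null(x$estimates))
    print(round(x$estimates, 4))
  cat(sprintf("  nll = %.3f  AIC = %.2f  BIC = %.2f  converged: %s\n",
              x$nll, x$aic, x$bic, x$converged))
  if (isTRUE(x$identifiability_warning))
    cat("  warning: inverse temperature near zero; learning rates weakly identified\n")
  invisible(x)
}

#' Expand a fitted variant's estimates into a larger variant's space
#'
#' Maps a nested model's solution to an equivalent parameter vector of a
#' richer variant (e.g. a single-rate fit becomes a dual-rate start with
#' both learning rates equal), for use as `extra_starts` in [fit_mle()].
#'
#' @param fit A `pst_fit`.
#' @param to Target variant name.
#' @return A one-row matrix, or `NULL` if the fit has no estimates.
#' @export
nested_start <- function(fit, to) {
  if (is.null(fit$estimates)) return(NULL)
  e <- fit$estimates
  out <- switch(paste(fit$variant$name, to, sep = "->"),
    "single->dual" = c(e[["alpha"]], e[["alpha"]], e[["beta"]]),
    "single->dual_by_state" = c(rep(e[["alpha"]], 4L), e[["beta"]]),
    "dual->dual_by_state" = c(e[["alpha_gain"]], e[["alpha_loss"]],
                              e[["alpha_gain"]], e[["alpha_loss"]],
                              e[["beta"]]),
    stop("no nesting from ", fit$variant$name, " to ", to))
  matrix(out, nrow = 1L)
}

#' Rank fitted model variants by information criterion
#'
#' @param fits List of `pst_fit` objects computed on identical data.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @return Data frame sorted by the chosen criterion with columns
#'   `variant`, `k`, `nll`, `aic`, `bic`, `delta` (criterion difference
#'   to the best model) and `weight` (Akaike weights for the chosen
#'   criterion).
#' @export
compare_models <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  n_obs <- vapply(fits, function(f) as.numeric(f$n_obs), numeric(1L))
  if (length(unique(n_obs)) != 1L)
    stop("fits were not computed on identical data (n_obs differ)")
  tab <- data.frame(
    variant = vapply(fits, function(f) f$variant$name, character(1L)),
    k = vapply(fits, function(f) as.integer(f$variant$k), integer(1L)),
    nll = vapply(fits, `[[`, numeric(1L), "nll"),
    aic = vapply(fits, `[[`, numeric(1L), "aic"),
    bic = vapply(fits, `[[`, numeric(1L), "bic"),
    stringsAsFactors = FALSE)
  crit <- tab[[criterion]]
  tab$delta <- crit - min(crit)
  w <- exp(-0.5 * tab$delta)
  tab$weight <- w / sum(w)
  tab <- tab[order(crit, tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Parameter-recovery harness
#'
#' Simulates agents on learning-phase schedules over a grid of true
#' parameter values, refits the chosen variant, and summarises recovery
#' per grid cell (bias and RMSE) together with the overall true-versus-
#' recovered correlations.
#'
#' @param variant Variant name (currently the recovery grid varies the
#'   learning rate of the `"single"` variant).
#' @param alpha_grid True learning-rate values.
#' @param beta True inverse temperature used for all simulations.
#' @param n_sims Simulated subjects per grid cell (0 gives an empty
#'   table).
#' @param n_trials Learning trials per simulated subject.
#' @param n_restarts Restarts per fit.
#' @param seed Root seed.
#' @param spec Task spec (default modified variant).
#' @return Data frame with one row per grid cell (`true_alpha`, `bias`,
#'   `rmse`, `mean_est`); raw draws in attribute `draws` and overall
#'   correlations in attribute `recovery_cor`.
#' @export
parameter_recovery_report <- function(variant = "single",
                                      alpha_grid = seq(0.1, 0.9, by = 0.2),
                                      beta = 5, n_sims = 5L,
                                      n_trials = 240L, n_restarts = 5L,
                                      seed = 1L,
                                      spec = pst_task_spec("modified")) {
  if (n_sims == 0L || !length(alpha_grid)) {
    out <- data.frame(true_alpha = numeric(), bias = numeric(),
                      rmse = numeric(), mean_est = numeric())
    attr(out, "draws") <- data.frame()
    return(out)
  }
  if (any(alpha_grid < 0 | alpha_grid > 1)) stop("alpha grid out of bounds")
  n_blocks <- ceiling(n_trials / spec$trials_per_learning_block)
  seeds <- child_seeds(seed, length(alpha_grid) * n_sims * 3L)
  draws <- vector("list", length(alpha_grid) * n_sims)
  i <- 0L
  for (a in alpha_grid) {
    for (s in seq_len(n_sims)) {
      i <- i + 1L
      sch <- build_learning_schedule(spec, seeds[3L * i - 2L], n_blocks)
      sch2 <- sch[seq_len(n_trials), , drop = FALSE]
      attr(sch2, "spec") <- spec
      ses <- simulate_session(agent_params(a, a, beta), sch2, "HC",
                              seed = seeds[3L * i - 1L])
      fit <- fit_mle(ses, variant, n_restarts = n_restarts,
                     seed = seeds[3L * i],
                     likelihood_phases = "learning")
      draws[[i]] <- data.frame(true_alpha = a, true_beta = beta, sim = s,
                               est_alpha = unname(fit$estimates[1L]),
                               est_beta = unname(fit$estimates["beta"]))
    }
  }
  draws <- do.call(rbind, draws)
  cells <- split(draws, draws$true_alpha)
  out <- do.call(rbind, lapply(cells, function(d) data.frame(
    true_alpha = d$true_alpha[1L],
    bias = mean(d$est_alpha) - d$true_alpha[1L],
    rmse = sqrt(mean((d$est_alpha - d$true_alpha[1L])^2)),
    mean_est = mean(d$est_alpha))))
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  attr(out, "recovery_cor") <- c(
    alpha = if (length(unique(draws$true_alpha)) > 1L)
      stats::cor(draws$true_alpha, draws$est_alpha) else NA_real_)
  out
}
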