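## Trial-schedule generation.
##
## A schedule is a data frame with one row per trial slot and columns
##   phase, block, trial, pair_label, stim_hi, stim_lo, stim_left,
##   stim_right, fb_hi, fb_lo, session_day
## fb_hi / fb_lo are the pre-realised feedback outcomes (1/0) the agent
## would receive for choosing the high / low stimulus; NA in
## feedback-free phases.  Attributes carry the spec and the seed.

PHASES <- c("practice", "learning", "memory_immediate", "memory_30min",
            "memory_24hr", "novel")

## Interleaved pair order with no more than `max_run` consecutive
## trials of the same pair.  Greedy weighted draw with restart.
interleave_pairs <- function(counts, max_run = 3L) {
  n_pairs <- length(counts)
  total <- sum(counts)
  if (n_pairs == 1L) return(rep(1L, total))  # constraint void
  for (attempt in 1:200) {
    left <- counts
    out <- integer(total)
    run <- 0L
    last <- 0L
    ok <- TRUE
    u <- stats::runif(total)
    for (t in seq_len(total)) {
      w <- left
      if (run >= max_run) w[last] <- 0L
      tot_w <- sum(w)
      if (tot_w == 0L) { ok <- FALSE; break }
      # weighted draw by remaining counts, using one pre-drawn uniform
      cum <- cumsum(w)
      pick <- which(cum >= u[t] * tot_w)[1L]
      out[t] <- pick
      left[pick] <- left[pick] - 1L
      run <- if (pick == last) run + 1L else 1L
      last <- pick
    }
    if (ok) return(out)
  }
  stop("could not interleave pairs under the run-length constraint")
}

## Left/right side assignment: within a block the high stimulus of each
## pair goes left on floor(n/2) of its slots, chosen at random.
assign_sides <- function(pair_idx) {
  hi_left <- logical(length(pair_idx))
  for (p in unique(pair_idx)) {
    slots <- which(pair_idx == p)
    n_left <- length(slots) %/% 2L
    hi_left[sample(slots, n_left)] <- TRUE
  }
  hi_left
}

realise_feedback <- function(p_hi, n, mode) {
  if (mode == "exact") {
    fb_hi <- sample(rep(c(1L, 0L), c(round(n * p_hi), n - round(n * p_hi))))
    fb_lo <- sample(rep(c(1L, 0L),
                        c(round(n * (1 - p_hi)), n - round(n * (1 - p_hi)))))
  } else {
    fb_hi <- stats::rbinom(n, 1L, p_hi)
    fb_lo <- stats::rbinom(n, 1L, 1 - p_hi)
  }
  list(hi = fb_hi, lo = fb_lo)
}

## Core block builder shared by practice / learning / memory phases.
build_blocks <- function(pairs, n_blocks, trials_per_block, phase,
                         feedback, feedback_mode) {
  n_pairs <- nrow(pairs)
  per_pair <- trials_per_block %/% n_pairs
  idx <- integer(0)
  hi_left <- logical(0)
  blk <- integer(0)
  for (b in seq_len(n_blocks)) {
    bi <- interleave_pairs(rep(per_pair, n_pairs))
    idx <- c(idx, bi)
    hi_left <- c(hi_left, assign_sides(bi))
    blk <- c(blk, rep(b, length(bi)))
  }
  out <- fast_df(list(
    phase = phase, block = blk,
    trial = stats::ave(blk, blk, FUN = seq_along),
    pair_label = paste0(pairs$hi[idx], pairs$lo[idx]),
    stim_hi = pairs$hi[idx], stim_lo = pairs$lo[idx],
    stim_left = ifelse(hi_left, pairs$hi[idx], pairs$lo[idx]),
    stim_right = ifelse(hi_left, pairs$lo[idx], pairs$hi[idx]),
    fb_hi = NA_integer_, fb_lo = NA_integer_))
  if (feedback) {
    for (p in seq_len(n_pairs)) {
      slots <- which(out$stim_hi == pairs$hi[p])
      fb <- realise_feedback(pairs$p_hi[p], length(slots), feedback_mode)
      out$fb_hi[slots] <- fb$hi
      out$fb_lo[slots] <- fb$lo
    }
  }
  out
}

#' Generate a learning-phase trial schedule
#'
#' Produces `n_learning_blocks` (or `max_blocks` for the threshold-gated
#' variant) blocks of `trials_per_learning_block` slots with equal pair
#' allocation per block, pseudorandom interleaving (at most 3 consecutive
#' trials of the same pair), left/right counterbalancing of each pair's
#' high stimulus within block, and pre-realised feedback outcomes for
#' either possible choice. Deterministic given `(spec, seed)`.
#'
#' @param spec A [pst_task_spec()].
#' @param seed Integer seed.
#' @param n_blocks Override the number of blocks (e.g. to generate more
#'   learning trials for parameter-recovery studies).
#' @return A schedule data frame (see package vignette for the column
#'   contract), with the spec and seed attached as attributes.
#' @examples
#' sch <- build_learning_schedule(pst_task_spec("modified"), seed = 1)
#' nrow(sch)            # 240
#' table(sch$block)     # 3 blocks of 80
#' @export
build_learning_schedule <- function(spec, seed, n_blocks = NULL) {
  stopifnot(inherits(spec, "pst_spec"))
  n_blocks <- n_blocks %||% spec$n_learning_blocks %||% spec$max_blocks
  out <- with_seed(seed, build_blocks(
    spec$pairs, n_blocks, spec$trials_per_learning_block,
    "learning", feedback = TRUE, feedback_mode = spec$feedback_mode))
  out$session_day <- 1L
  structure(out, spec = spec, seed = seed)
}

#' Generate a novel-pairs test schedule
#'
#' All `choose(n_stimuli, 2)` unordered combinations of the learning
#' stimuli, each repeated `spec$novel_reps` times, in random order with
#' random left/right placement and no feedback. Within each slot
#' `stim_hi` is the member with the higher generative reward probability,
#' so optimality is always defined (no ties exist by design).
#'
#' @inheritParams build_learning_schedule
#' @return A schedule data frame with phase `"novel"`.
#' @examples
#' nrow(build_novel_schedule(pst_task_spec("modified"), 1))  # 6*15 = 90
#' nrow(build_novel_schedule(pst_task_spec("original"), 1))  # 15*6 = 90
#' @export
build_novel_schedule <- function(spec, seed) {
  stopifnot(inherits(spec, "pst_spec"))
  stims <- c(spec$pairs$hi, spec$pairs$lo)
  combos <- utils::combn(sort(stims), 2L)
  probs <- spec$stim_probs
  with_seed(seed, {
    a <- rep(combos[1L, ], spec$novel_reps)
    b <- rep(combos[2L, ], spec$novel_reps)
    if (!length(a)) {
      empty <- fast_df(list(
        phase = character(0), block = integer(0), trial = integer(0),
        pair_label = character(0), stim_hi = character(0),
        stim_lo = character(0), stim_left = character(0),
        stim_right = character(0), fb_hi = integer(0),
        fb_lo = integer(0), session_day = integer(0)))
      return(structure(empty, spec = spec, seed = seed))
    }
    ord <- sample(length(a))
    a <- a[ord]; b <- b[ord]
    hi <- ifelse(probs[a] >= probs[b], a, b)
    lo <- ifelse(probs[a] >= probs[b], b, a)
    hi_left <- stats::runif(length(a)) < 0.5
    out <- data.frame(
      phase = "novel", block = 1L, trial = seq_along(a),
      pair_label = paste0(a, b),
      stim_hi = hi, stim_lo = lo,
      stim_left = ifelse(hi_left, hi, lo),
      stim_right = ifelse(hi_left, lo, hi),
      fb_hi = NA_integer_, fb_lo = NA_integer_,
      session_day = NA_integer_,
      stringsAsFactors = FALSE)
    structure(out, spec = spec, seed = seed)
  })
}

build_memory_schedule <- function(spec, seed, phase) {
  if (spec$memory_block_trials == 0L) return(NULL)
  out <- with_seed(seed, build_blocks(
    spec$pairs, 1L, spec$memory_block_trials, phase,
    feedback = FALSE, feedback_mode = spec$feedback_mode))
  out
}

build_practice_schedule <- function(spec, seed) {
  if (spec$practice_trials == 0L) return(NULL)
  practice_pair <- data.frame(hi = "X", lo = "Y", p_hi = 0.8,
                              stringsAsFactors = FALSE)
  with_seed(seed, build_blocks(
    practice_pair, 1L, spec$practice_trials, "practice",
    feedback = TRUE, feedback_mode = spec$feedback_mode))
}

#' Generate a complete session schedule
#'
#' Composes practice, learning, memory and novel phases into one ordered
#' schedule according to the session design:
#'
#' * `"two_day"`: practice, learning, immediate and 30-min memory blocks
#'   on day 1; 24-hr memory block and novel-pairs test on day 2 (the
#'   four-condition within-subject design).
#' * `"same_day"`: practice, learning, then the novel-pairs test
#'   immediately, all on day 1 (no memory blocks).
#' * `"gated"`: practice, up to `max_blocks` threshold-gated learning
#'   blocks, then the novel-pairs test on day 1 (original variant).
#'
#' @inheritParams build_learning_schedule
#' @param design Session design; defaults to `"two_day"` for the modified
#'   variant and `"gated"` for the original.
#' @param phases Optional character subset of phases to keep (targeted
#'   simulations, e.g. learning + memory only).
#' @return A schedule data frame spanning all requested phases, ordered
#'   as run, with attributes `spec`, `seed` and `design`.
#' @export
build_session_schedule <- function(spec, seed,
                                   design = NULL, phases = NULL) {
  stopifnot(inherits(spec, "pst_spec"))
  design <- design %||%
    if (spec$variant_name == "original") "gated" else "two_day"
  design <- match.arg(design, c("two_day", "same_day", "gated"))
  seeds <- child_seeds(seed, 6L)
  parts <- list()
  parts$practice <- build_practice_schedule(spec, seeds[1L])
  if (!is.null(parts$practice)) parts$practice$session_day <- 1L
  learn <- build_learning_schedule(spec, seeds[2L])
  learn$session_day <- 1L
  parts$learning <- as.data.frame(learn)
  if (design == "two_day") {
    m0 <- build_memory_schedule(spec, seeds[3L], "memory_immediate")
    m30 <- build_memory_schedule(spec, seeds[4L], "memory_30min")
    m24 <- build_memory_schedule(spec, seeds[5L], "memory_24hr")
    if (!is.null(m0)) m0$session_day <- 1L
    if (!is.null(m30)) m30$session_day <- 1L
    if (!is.null(m24)) m24$session_day <- 2L
    parts$memory_immediate <- m0
    parts$memory_30min <- m30
    parts$memory_24hr <- m24
  }
  novel <- as.data.frame(build_novel_schedule(spec, seeds[6L]))
  novel$session_day <- if (design == "two_day") 2L else 1L
  parts$novel <- novel
  if (!is.null(phases)) parts <- parts[intersect(names(parts), phases)]
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out$trial <- seq_len(nrow(out))
  structure(out, spec = spec, seed = seed, design = design)
}

#' Write / read session tables as CSV
#'
#' Long-format CSV with one row per trial; `NA` encodes the NONE feedback
#' sentinel and unanswered choices.
#'
#' @param x Data frame of trial records or schedule rows.
#' @param path File path.
#' @return `read_sessions` returns the data frame; `write_sessions`
#'   returns `path` invisibly.
#' @export
write_sessions <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
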