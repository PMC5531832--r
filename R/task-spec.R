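#' Define a Probabilistic Selection Task variant
#'
#' Builds the full parameterisation of a PST variant. Two variants are
#' built in:
#'
#' * `"modified"`: 2 pairs (AB at 80--20%, CD at 65--35%), 240 learning
#'   trials in 3 blocks of 80, 40-trial memory blocks, and a novel-pairs
#'   test showing every unordered stimulus combination 15 times
#'   (6 x 15 = 90 trials).
#' * `"original"`: 3 pairs (AB 80--20%, CD 70--30%, EF 60--40%),
#'   threshold-gated learning blocks of 60 trials (20 per pair, at most 7
#'   blocks), no memory blocks, and a novel-pairs test with all 15
#'   combinations shown 6 times (90 trials). To exit training a learner
#'   must, within one block, score strictly above 65% on AB, 60% on CD
#'   and 50% on EF.
#'
#' In every pair the low stimulus's reward probability is the complement
#' of the high stimulus's, and feedback on a trial depends only on the
#' chosen stimulus.
#'
#' @param variant `"modified"` or `"original"`.
#' @param novel_reps Repetitions of each unordered stimulus combination in
#'   the novel-pairs phase. Defaults to 15 (modified) or 6 (original).
#' @param practice_trials Number of practice trials with dedicated
#'   stimuli (default 40).
#' @param feedback_mode `"bernoulli"` draws each trial's pre-realised
#'   feedback i.i.d. at the pair's probabilities; `"exact"` permutes a
#'   fixed outcome multiset so realised proportions match the nominal
#'   probabilities exactly (per pair, across the learning phase).
#' @return An object of class `pst_spec`: a list with elements
#'   `variant_name`, `pairs` (data frame with `hi`, `lo`, `p_hi`),
#'   `trials_per_learning_block`, `n_learning_blocks` or `max_blocks`,
#'   `practice_trials`, `memory_block_trials`, `novel_reps`,
#'   `pass_thresholds`, `max_trial_duration`, `feedback_duration`,
#'   `feedback_mode` and `stim_probs` (named vector mapping every
#'   stimulus, practice stimuli included, to its reward probability).
#' @examples
#' spec <- pst_task_spec("modified")
#' spec$pairs
#' @export
pst_task_spec <- function(variant = c("modified", "original"),
                          novel_reps = NULL,
                          practice_trials = 40,
                          feedback_mode = c("bernoulli", "exact")) {
  variant <- match.arg(variant)
  feedback_mode <- match.arg(feedback_mode)
  spec <- switch(variant,
    modified = list(
      variant_name = "modified",
      pairs = data.frame(hi = c("A", "C"), lo = c("B", "D"),
                         p_hi = c(0.80, 0.65),
                         stringsAsFactors = FALSE),
      trials_per_learning_block = 80L,
      n_learning_blocks = 3L,
      max_blocks = NULL,
      practice_trials = as.integer(practice_trials),
      memory_block_trials = 40L,
      novel_reps = as.integer(novel_reps %||% 15L),
      pass_thresholds = NULL,
      max_trial_duration = 2,
      feedback_duration = 2
    ),
    original = list(
      variant_name = "original",
      pairs = data.frame(hi = c("A", "C", "E"), lo = c("B", "D", "F"),
                         p_hi = c(0.80, 0.70, 0.60),
                         stringsAsFactors = FALSE),
      trials_per_learning_block = 60L,
      n_learning_blocks = NULL,
      max_blocks = 7L,
      practice_trials = as.integer(practice_trials),
      memory_block_trials = 0L,
      novel_reps = as.integer(novel_reps %||% 6L),
      pass_thresholds = c(0.65, 0.60, 0.50),
      max_trial_duration = 4,
      feedback_duration = 2
    )
  )
  spec$feedback_mode <- feedback_mode
  # reward-probability map over all stimuli; X/Y are the practice pair
  probs <- c(spec$pairs$p_hi, 1 - spec$pairs$p_hi, 0.8, 0.2)
  names(probs) <- c(spec$pairs$hi, spec$pairs$lo, "X", "Y")
  spec$stim_probs <- probs
  class(spec) <- "pst_spec"
  validate_pst_spec(spec)
  spec
}

#' @keywords internal
validate_pst_spec <- function(spec) {
  p <- spec$pairs$p_hi
  if (any(p <= 0.5) || any(p > 1))
    stop("high-stimulus reward probabilities must lie in (0.5, 1]")
  n_pairs <- nrow(spec$pairs)
  if (spec$trials_per_learning_block %% n_pairs != 0L)
    stop("trials_per_learning_block must be divisible by the number of pairs")
  if (!is.null(spec$pass_thresholds) &&
      length(spec$pass_thresholds) != n_pairs)
    stop("one pass threshold per pair is required")
  if (spec$memory_block_trials > 0L &&
      spec$memory_block_trials %% n_pairs != 0L)
    stop("memory_block_trials must be divisible by the number of pairs")
  invisible(spec)
}

#' @export
print.pst_spec <- function(x, ...) {
  cat("PST spec:", x$variant_name, "\n")
  cat("  pairs:", paste0(x$pairs$hi, x$pairs$lo, " (",
                         round(100 * x$pairs$p_hi), "-",
                         round(100 * (1 - x$pairs$p_hi)), "%)",
                         collapse = ", "), "\n")
  if (!is.null(x$n_learning_blocks)) {
    cat("  learning:", x$n_learning_blocks, "blocks of",
        x$trials_per_learning_block, "trials\n")
  } else {
    cat("  learning: up to", x$max_blocks, "threshold-gated blocks of",
        x$trials_per_learning_block, "trials\n")
  }
  cat("  memory block trials:", x$memory_block_trials,
      " novel reps:", x$novel_reps, "\n")
  invisible(x)
}

#' Check whether per-pair block accuracies pass the training thresholds
#'
#' A block passes only if every pair's accuracy is strictly above its
#' threshold; ties fail. Used by the threshold-gated (original) variant,
#' whose gated loop always terminates after `max_blocks` blocks
#' regardless of accuracy.
#'
#' @param block_accuracies Numeric vector, one proportion in `[0, 1]` per
#'   pair, in the order of `spec$pairs`.
#' @param spec A `pst_spec` with `pass_thresholds`.
#' @return `TRUE` if every pair strictly exceeds its threshold.
#' @examples
#' spec <- pst_task_spec("original")
#' check_block_thresholds(c(0.70, 0.65, 0.55), spec) # TRUE
#' check_block_thresholds(c(0.65, 0.65, 0.55), spec) # FALSE: tie on AB
#' @export
check_block_thresholds <- function(block_accuracies, spec) {
  stopifnot(inherits(spec, "pst_spec"))
  if (is.null(spec$pass_thresholds))
    stop("spec has no pass thresholds (fixed-block variant)")
  if (length(block_accuracies) != nrow(spec$pairs))
    stop("need exactly one accuracy per pair")
  if (any(block_accuracies < 0 | block_accuracies > 1))
    stop("accuracies must lie in [0, 1]")
  all(block_accuracies > spec$pass_thresholds)
}
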