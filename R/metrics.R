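## Behavioural metrics computed from session trial tables.
##
## Undefined metrics (empty scopes, missing blocks) propagate as NA,
## never as zero.

responded <- function(trials) !is.na(trials$choice) & trials$choice != ""

#' Percentage of optimal choices in a phase
#'
#' A choice is optimal when the selected stimulus has the higher
#' generative reward probability, regardless of the feedback actually
#' shown on that trial. Unanswered trials are excluded from the
#' denominator; an empty scope returns `NA`.
#'
#' @param trials Trial records.
#' @param phase Optional phase filter (e.g. `"learning"`).
#' @param block Optional block filter within the phase.
#' @return Percentage in `[0, 100]`, or `NA` if no responded trials are
#'   in scope.
#' @export
optimal_accuracy <- function(trials, phase = NULL, block = NULL) {
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(phase)) keep <- keep & trials$phase %in% phase
  if (!is.null(block)) keep <- keep & trials$block %in% block
  keep <- keep & responded(trials)
  if (!any(keep)) return(NA_real_)
  100 * mean(trials$chose_optimal[keep])
}

## Learning pairs of the session (labels like "AB"), taken from the
## learning-phase rows; falls back to the canonical labels.
learning_pair_labels <- function(trials) {
  lp <- unique(trials$pair_label[trials$phase == "learning"])
  if (!length(lp)) lp <- c("AB", "CD", "EF")
  lp
}

novel_metric <- function(trials, stim, want_chosen, learning_pairs) {
  nov <- trials[trials$phase == "novel" & responded(trials), ,
                drop = FALSE]
  if (!nrow(nov)) return(NA_real_)
  has_stim <- nov$stim_left == stim | nov$stim_right == stim
  eligible <- has_stim & !(nov$pair_label %in% learning_pairs)
  if (!any(eligible)) return(NA_real_)
  hit <- if (want_chosen) nov$choice[eligible] == stim
         else nov$choice[eligible] != stim
  100 * mean(hit)
}

#' Choose-A: expression of positive reinforcement
#'
#' Percentage of novel-pairs trials containing the most-rewarded stimulus
#' (A) in which it was chosen, excluding the learning pairs themselves
#' (AB and CD, plus EF in the original variant) as well as unanswered
#' trials. In the modified variant the eligible pairs are AC and AD, so
#' at 15 repetitions the denominator is 30.
#'
#' @param trials Trial records including a novel phase.
#' @param stim The most-rewarded stimulus id (default `"A"`).
#' @param learning_pairs Pair labels to exclude; derived from the
#'   session's learning phase when present.
#' @return Percentage, or `NA` when the stimulus never appears in an
#'   eligible trial.
#' @export
choose_a <- function(trials, stim = "A", learning_pairs = NULL) {
  novel_metric(trials, stim, want_chosen = TRUE,
               learning_pairs %||% learning_pair_labels(trials))
}

#' Avoid-B: expression of negative reinforcement
#'
#' Percentage of eligible novel-pairs trials containing the
#' least-rewarded stimulus (B) in which it was *not* chosen; exclusions
#' as in [choose_a()].
#'
#' @inheritParams choose_a
#' @param stim The least-rewarded stimulus id (default `"B"`).
#' @export
avoid_b <- function(trials, stim = "B", learning_pairs = NULL) {
  novel_metric(trials, stim, want_chosen = FALSE,
               learning_pairs %||% learning_pair_labels(trials))
}

#' Win-stay / lose-shift rates on the learning trials
#'
#' Transitions are defined within pair: consecutive presentations of the
#' same pair form a transition, and win-stay is the probability of
#' repeating the previous choice of that pair given the previous feedback
#' was positive; lose-shift the probability of switching given it was
#' negative. A `"global"` scope using consecutive trials regardless of
#' pair is available for comparison with analyses that pool pairs.
#'
#' @param trials Trial records.
#' @param scope `"pair"` (default) or `"global"`.
#' @return Named numeric vector `c(win_stay = , lose_shift = )`; `NA`
#'   entries when no qualifying transitions exist.
#' @export
wsls <- function(trials, scope = c("pair", "global")) {
  scope <- match.arg(scope)
  lt <- trials[trials$phase == "learning" & responded(trials), ,
               drop = FALSE]
  stays_win <- logical(0)
  shifts_lose <- logical(0)
  groups <- if (scope == "pair") split(seq_len(nrow(lt)), lt$pair_label)
            else list(seq_len(nrow(lt)))
  for (idx in groups) {
    if (length(idx) < 2L) next
    prev_fb <- lt$feedback[idx][-length(idx)]
    same <- lt$choice[idx][-1L] == lt$choice[idx][-length(idx)]
    stays_win <- c(stays_win, same[prev_fb %in% 1])
    shifts_lose <- c(shifts_lose, !same[prev_fb %in% 0])
  }
  c(win_stay = if (length(stays_win)) mean(stays_win) else NA_real_,
    lose_shift = if (length(shifts_lose)) mean(shifts_lose) else NA_real_)
}

#' Memory-difference scores
#'
#' Signed percentage-point differences between memory blocks, later minus
#' earlier, so an overnight *increase* in accuracy is positive. Missing
#' blocks propagate `NA`.
#'
#' @param memory_immediate,memory_30min,memory_24hr Block accuracies in
#'   percent.
#' @return Named vector `c(mem_diff_30_0 = , mem_diff_24_30 = )`.
#' @examples
#' memory_differences(80, 75, 85)  # c(-5, +10)
#' @export
memory_differences <- function(memory_immediate, memory_30min,
                               memory_24hr) {
  c(mem_diff_30_0 = memory_30min - memory_immediate,
    mem_diff_24_30 = memory_24hr - memory_30min)
}

#' Per-session behavioural summary
#'
#' Computes every behavioural statistic for one session (one subject in
#' one condition): per-block learning accuracy, final-block accuracy,
#' memory-block accuracies and difference scores, novel-pairs overall
#' accuracy, choose-A, avoid-B, AB-pair novel accuracy (the filtering
#' criterion), and win-stay/lose-shift.
#'
#' @param trials Trial records of one session.
#' @return One-row data frame.
#' @export
subject_metrics <- function(trials) {
  stopifnot(length(unique(trials$subject_id)) == 1L)
  lblocks <- sort(unique(trials$block[trials$phase == "learning"]))
  final_block <- if (length(lblocks)) max(lblocks) else NA_integer_
  ws <- wsls(trials)
  lp <- learning_pair_labels(trials)
  mem <- vapply(c("memory_immediate", "memory_30min", "memory_24hr"),
                function(ph) optimal_accuracy(trials, phase = ph),
                numeric(1L))
  md <- memory_differences(mem[1L], mem[2L], mem[3L])
  nov <- trials[trials$phase == "novel", , drop = FALSE]
  ab_label <- paste0(sort(c("A", "B")), collapse = "")
  ab_rows <- nov[nov$pair_label == ab_label & responded(nov), ,
                 drop = FALSE]
  data.frame(
    subject_id = trials$subject_id[1L],
    group = trials$group[1L],
    condition = trials$condition[1L],
    blocks_completed = length(lblocks),
    final_learning_accuracy =
      optimal_accuracy(trials, "learning", final_block),
    learning_accuracy = optimal_accuracy(trials, "learning"),
    memory_immediate = unname(mem[1L]),
    memory_30min = unname(mem[2L]),
    memory_24hr = unname(mem[3L]),
    mem_diff_30_0 = unname(md[1L]),
    mem_diff_24_30 = unname(md[2L]),
    novel_overall = optimal_accuracy(trials, "novel"),
    choose_a = choose_a(trials, learning_pairs = lp),
    avoid_b = avoid_b(trials, learning_pairs = lp),
    ab_novel_accuracy = if (nrow(ab_rows))
      100 * mean(ab_rows$choice == "A") else NA_real_,
    win_stay = unname(ws["win_stay"]),
    lose_shift = unname(ws["lose_shift"]),
    stringsAsFactors = FALSE)
}

#' Behavioural summaries for a whole cohort
#'
#' @param sessions Trial records of many sessions (stacked), with
#'   `subject_id` and `condition` columns.
#' @return Data frame with one row per (subject, condition), with the
#'   chance-level filter applied (see [apply_filter()]).
#' @export
cohort_metrics <- function(sessions) {
  key <- interaction(sessions$subject_id, sessions$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(sessions, key), subject_metrics))
  rownames(out) <- NULL
  apply_filter(out)
}

#' Flag conditions that failed the easiest novel-pairs choice
#'
#' A condition's novel-pairs data are flagged for exclusion when the
#' subject scored 50% or lower on the A-vs-B choice in the novel-pairs
#' test (at or below chance on the easiest discrimination, taken as not
#' having learnt the task). Each condition is checked separately, so one
#' condition of a subject can be excluded while the others remain, and
#' the flag applies only to novel-pairs analyses -- learning and memory
#' statistics are never filtered. Conditions without any responded AB
#' novel trial cannot be assessed and get `NA`.
#'
#' @param metrics Cohort metrics data frame (one row per subject x
#'   condition) containing `ab_novel_accuracy`.
#' @return The same data frame with a logical `filtered_out` column.
#' @export
apply_filter <- function(metrics) {
  metrics$filtered_out <- ifelse(is.na(metrics$ab_novel_accuracy), NA,
                                 metrics$ab_novel_accuracy <= 50)
  metrics
}
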