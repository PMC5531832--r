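## Inferential battery: t-tests with Cohen's d variants, one-way and
## 2x2 repeated-measures ANOVA with partial eta squared, exact Wilcoxon
## signed-rank, Pearson correlation, Bonferroni control.

pst_test <- function(statistic_name, statistic, df, p, n,
                     extras = list()) {
  structure(c(list(statistic_name = statistic_name,
                   statistic = statistic, df = df, p = p, n = n),
              extras),
            class = "pst_test")
}

#' @export
print.pst_test <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s(%s) = %.4f, p = %.4g, n = %d\n",
              x$statistic_name, dfs, x$statistic, x$p, x$n))
  extra <- setdiff(names(x), c("statistic_name", "statistic", "df",
                               "p", "n", "note"))
  for (nm in extra)
    if (is.numeric(x[[nm]]) && length(x[[nm]]) == 1L)
      cat(sprintf("  %s = %.4f\n", nm, x[[nm]]))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Two-tailed p-value from a t statistic
#'
#' `p = 2 * (1 - F_t(|t|; df))` under the central t distribution.
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (`>= 1`).
#' @return Two-tailed probability.
#' @examples
#' p_from_t(2.894, 16)   # 0.0106
#' @export
p_from_t <- function(t, df) {
  if (df < 1) stop("df must be >= 1")
  2 * stats::pt(-abs(t), df)
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the proportion of
#' effect-plus-error variance attributable to the effect.
#'
#' @param f Observed F statistic (`>= 0`).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Value in `[0, 1]`.
#' @examples
#' partial_eta_squared(2.803, 1, 16)  # 0.149
#' @export
partial_eta_squared <- function(f, df1, df2) {
  if (f < 0) stop("F must be non-negative")
  f * df1 / (f * df1 + df2)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param family_alpha Family-wise error rate.
#' @param m Number of comparisons (`>= 1`).
#' @return `family_alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 4)  # 0.0125
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (m < 1) stop("m must be >= 1")
  family_alpha / m
}

## Cohen's d variants for paired designs.  d_z standardises by the SD of
## the differences; d_av by the average of the two condition SDs.
cohens_d_paired <- function(x, y) {
  d <- x - y
  list(d_z = mean(d) / stats::sd(d),
       d_av = mean(d) / mean(c(stats::sd(x), stats::sd(y))))
}

#' Paired-samples t-test with effect sizes
#'
#' Drops incomplete pairs, runs the standard paired t-test
#' (`df = n - 1`) and attaches both Cohen's d variants: `d_z` (mean
#' difference over SD of differences) and `d_av` (mean difference over
#' the average of the two condition SDs). Zero variance of the
#' differences yields a degenerate-result sentinel rather than an error.
#'
#' @param x,y Paired numeric vectors.
#' @return A `pst_test` with fields `statistic`, `df`, `p`, `n`, `d_z`,
#'   `d_av`.
#' @export
paired_t <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs")
  if (stats::sd(x - y) == 0)
    return(pst_test("t", NA_real_, n - 1L, NA_real_, n,
                    extras = list(d_z = NA_real_, d_av = NA_real_,
                    note = "degenerate: zero variance of differences")))
  ht <- stats::t.test(x, y, paired = TRUE)
  d <- cohens_d_paired(x, y)
  pst_test("t", unname(ht$statistic), unname(ht$parameter),
           ht$p.value, n, extras = list(d_z = d$d_z, d_av = d$d_av))
}

#' Independent-samples t-test with Cohen's d
#'
#' Student's t (pooled variance) with `d` standardised by the pooled SD.
#'
#' @param x,y Numeric vectors from the two groups.
#' @return A `pst_test` with field `d`.
#' @export
independent_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) /
             (length(x) + length(y) - 2))
  d <- if (sp == 0) NA_real_ else (mean(x) - mean(y)) / sp
  pst_test("t", unname(ht$statistic), unname(ht$parameter),
           ht$p.value, length(x) + length(y), extras = list(d = d))
}

#' One-way between-groups ANOVA with partial eta squared
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @return A `pst_test` with `statistic_name = "F"`, `df = c(df1, df2)`
#'   and `eta_p2`.
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  f <- tab$`F value`[1L]
  df1 <- tab$Df[1L]; df2 <- tab$Df[2L]
  pst_test("F", f, c(df1, df2), tab$`Pr(>F)`[1L], length(values),
           extras = list(eta_p2 = partial_eta_squared(f, df1, df2)))
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors (incomplete pairs dropped).
#' @return A `pst_test` with `statistic_name = "r"` (the statistic is the
#'   correlation coefficient; `df = n - 2`).
#' @export
pearson_r <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  ht <- stats::cor.test(x[keep], y[keep])
  pst_test("r", unname(ht$estimate), unname(ht$parameter),
           ht$p.value, sum(keep))
}

#' Two-by-two repeated-measures ANOVA
#'
#' For a fully within-subject 2x2 design each effect has one degree of
#' freedom, so each is computed as a one-sample t-test on the
#' corresponding per-subject contrast score and reported as `F = t^2`
#' with `df = (1, n - 1)`; partial eta squared is attached. This is
#' algebraically identical to the classical sums-of-squares decomposition
#' with effect-specific error terms. Subjects missing any cell are
#' dropped (pairwise complete across the four cells).
#'
#' @param scores Numeric matrix or data frame, one row per subject, four
#'   columns in the cell order `(A1B1, A1B2, A2B1, A2B2)` where A is the
#'   first factor (e.g. day-1 medication) and B the second (day-2
#'   medication).
#' @param factor_names Length-2 character vector naming the factors.
#' @return Named list of three `pst_test` objects: the two main effects
#'   and the interaction.
#' @export
rm_anova_2x2 <- function(scores, factor_names = c("day1", "day2")) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 4L) stop("scores must have 4 within-subject cells")
  scores <- scores[stats::complete.cases(scores), , drop = FALSE]
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 complete subjects")
  contrasts <- list(
    c(1, 1, -1, -1) / 2,   # main effect of factor A
    c(1, -1, 1, -1) / 2,   # main effect of factor B
    c(1, -1, -1, 1) / 2)   # interaction
  names(contrasts) <- c(factor_names, paste(factor_names, collapse = ":"))
  lapply(contrasts, function(ct) {
    cs <- drop(scores %*% ct)
    if (stats::sd(cs) == 0)
      return(pst_test("F", 0, c(1L, n - 1L), 1, n, extras = list(eta_p2 = 0)))
    tt <- stats::t.test(cs)
    f <- unname(tt$statistic)^2
    pst_test("F", f, c(1L, n - 1L), tt$p.value, n,
             extras = list(eta_p2 = partial_eta_squared(f, 1, n - 1)))
  })
}

## Exact null distribution of the signed-rank statistic: probability
## generating function over doubled ranks (average ranks under ties are
## half-integers, so doubling keeps the support integral).
signed_rank_exact_p <- function(w2, ranks2) {
  pmf <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), pmf)
    pmf <- (c(pmf, rep(0, r)) + shifted) / 2
  }
  support <- seq_along(pmf) - 1L
  p_le <- sum(pmf[support <= w2 + 1e-9])
  p_ge <- sum(pmf[support >= w2 - 1e-9])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are dropped (signed-rank convention), ties
#' among the absolute differences receive average ranks, and the
#' statistic is `W+`, the sum of ranks of the positive differences. For
#' `n <= 25` retained pairs the two-tailed p-value comes from the exact
#' null distribution (all `2^n` equiprobable sign assignments, computed
#' by convolution, valid under ties); above that a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y Paired numeric vectors (incomplete pairs dropped).
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return A `pst_test` with `statistic_name = "W"`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  keep <- stats::complete.cases(x, y)
  d <- (x - y)[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(pst_test("W", NA_real_, NA_integer_, NA_real_, 0L,
                    extras = list(note = "degenerate: all differences zero")))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(2 * w, as.integer(round(2 * r)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  pst_test("W", w, NA_integer_, p, n)
}
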