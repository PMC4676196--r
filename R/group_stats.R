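#' @title Group-comparison statistics
#' @description The statistical procedures of a three-arm pre/post
#'   design: one-way ANOVA from raw data or from published summary
#'   statistics, 2x3 mixed repeated-measures ANOVA (time within, group
#'   between), paired t with the t/sqrt(n) effect size (Cohen's dz),
#'   Pearson chi-squared tests (no continuity correction) and Pearson
#'   correlation.  No multiple-testing adjustment is applied anywhere:
#'   planned comparisons are reported at the nominal alpha.
#' @name group_stats
NULL

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the between-group sum of squares from the group means
#' and sizes and the within-group sum of squares from the standard
#' deviations (`sum((n_i - 1) * sd_i^2)`), exactly equivalent to a
#' raw-data one-way ANOVA on any sample matching those moments.
#'
#' @param mean,sd,n Numeric vectors of per-group mean, SD and size.
#' @return An `anova_result`: `F`, `df_between`, `df_within`, `p`.
#' @export
#' @examples
#' # an IQ row: three groups matched at baseline
#' oneway_anova_summary(mean = c(85.92, 86.53, 76.28),
#'                      sd = c(29.25, 17.46, 17.71), n = c(13, 17, 18))
oneway_anova_summary <- function(mean, sd, n) {
  k <- length(mean)
  if (k < 2 || length(sd) != k || length(n) != k) stop("need >= 2 groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(sd < 0)) stop("sd must be >= 0")
  N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- k - 1; df2 <- N - k
  Fv <- if (ssw == 0) { if (ssb == 0) 0 else Inf } else
    (ssb / df1) / (ssw / df2)
  structure(list(F = Fv, df_between = df1, df_within = df2,
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d,%d) = %.3f, p = %.4f\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' 2x3 mixed repeated-measures ANOVA
#'
#' Time (pre/post) as the within-subject factor and group as the
#' between-subject factor, via the standard univariate mixed-design
#' decomposition.  With a 2-level within factor sphericity holds
#' trivially, so no correction is needed.  The between stratum tests
#' group against subjects-within-groups; the within stratum tests time
#' and time x group against the time x subject residual, with the
#' interaction on (g - 1, N - g) degrees of freedom.  Effects with zero
#' sum of squares report F = 0.
#'
#' @param pre,post Numeric per-subject scores.
#' @param group Per-subject group labels (factor or character).
#' @return List of three `anova_result`s: `time`, `group`,
#'   `interaction`, plus the sums of squares table `ss`.
#' @export
mixed_anova_2x3 <- function(pre, post, group) {
  n <- length(pre)
  if (length(post) != n || length(group) != n)
    stop("pre, post and group must have equal length")
  if (anyNA(pre) || anyNA(post)) stop("missing cell")
  group <- factor(group)
  g <- nlevels(group)
  if (any(table(group) < 2)) stop("every group needs >= 2 subjects")
  N <- n
  m_i <- (pre + post) / 2                # subject means
  d_i <- post - pre                      # within-subject differences
  # between-subject stratum (on subject means, x2 for the two cells)
  mbar_g <- tapply(m_i, group, mean)
  ng <- as.numeric(table(group))
  gm <- mean(c(pre, post))
  ss_group <- 2 * sum(ng * (mbar_g - gm)^2)
  ss_bse <- 2 * sum((m_i - mbar_g[group])^2)
  # within-subject stratum (on differences)
  dbar_g <- tapply(d_i, group, mean)
  # sequential: time fitted before the interaction
  ss_time <- sum(d_i)^2 / (2 * N)
  ss_int <- sum(ng * dbar_g^2) / 2 - ss_time
  ss_wse <- sum((d_i - dbar_g[group])^2) / 2
  fstat <- function(ssb, dfb, sse, dfe) {
    Fv <- if (sse == 0) { if (ssb == 0) 0 else Inf } else
      if (ssb <= 0) 0 else (ssb / dfb) / (sse / dfe)
    structure(list(F = Fv, df_between = dfb, df_within = dfe,
                   p = stats::pf(Fv, dfb, dfe, lower.tail = FALSE)),
              class = "anova_result")
  }
  list(time = fstat(ss_time, 1, ss_wse, N - g),
       group = fstat(ss_group, g - 1, ss_bse, N - g),
       interaction = fstat(ss_int, g - 1, ss_wse, N - g),
       ss = c(group = ss_group, subjects = ss_bse, time = ss_time,
              interaction = ss_int, residual = ss_wse))
}

#' Paired t-test with the t/sqrt(n) effect size
#'
#' Standard paired t on matched pre/post values; the effect size is
#' Cohen's dz computed as `t / sqrt(n)` (identically
#' `mean(diff) / sd(diff)`).
#'
#' @param pre,post Matched numeric vectors, n >= 2.
#' @return A `ttest_result`: `t`, `df`, `p`, `effect_size_d`.
#' @export
paired_t <- function(pre, post) {
  n <- length(pre)
  if (length(post) != n || n < 2) stop("need >= 2 matched pairs")
  d <- post - pre
  if (stats::sd(d) == 0) {
    tv <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    pv <- if (mean(d) == 0) 1 else 0
    if (!is.finite(tv)) warning("zero variance of differences with nonzero mean")
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    tv <- unname(tt$statistic); pv <- tt$p.value
  }
  structure(list(t = tv, df = n - 1, p = pv,
                 effect_size_d = tv / sqrt(n)), class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4f, dz = %.3f\n",
              x$df, x$t, x$p, x$effect_size_d))
  invisible(x)
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction (the Yates correction is never applied).
#'
#' @param table r x c matrix of non-negative counts.
#' @return A `chisq_result`: `chi2`, `df`, `p`.
#' @export
chi_square_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) == 0) stop("counts must be >= 0, not all zero")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value), class = "chisq_result")
}

#' Pearson goodness-of-fit chi-squared
#'
#' @param observed Vector of non-negative counts.
#' @param expected Vector of expected proportions (sums to 1).
#' @return A `chisq_result`.
#' @export
#' @examples
#' chi_square_goodness(c(13, 5), c(0.5, 0.5))  # equal-split sign tally
chi_square_goodness <- function(observed, expected = NULL) {
  if (is.null(expected)) expected <- rep(1 / length(observed), length(observed))
  if (abs(sum(expected) - 1) > 1e-8) stop("expected proportions must sum to 1")
  if (any(expected <= 0)) stop("zero expected cell")
  ct <- suppressWarnings(stats::chisq.test(observed, p = expected))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value), class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.4f\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Pearson correlation with two-tailed test
#'
#' @param x,y Numeric vectors, n >= 3, finite, non-constant.
#' @return List `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Reconstruct attrition counts from printed percentages
#'
#' Converts per-group dropout percentages of a common starting size
#' into integer counts (round half away from zero) and validates that
#' the counts re-yield the printed percentage at 1 decimal place.
#'
#' @param percent Dropout percentages (e.g. `c(40.9, 22.7, 18.2)`).
#' @param n_start Starting group size (default 22).
#' @return Matrix with rows `dropped`, `retained`.
#' @export
reconstruct_attrition <- function(percent, n_start = 22) {
  dropped <- sign(percent) * floor(abs(percent) / 100 * n_start + 0.5)
  back <- round(dropped / n_start * 100, 1)
  if (any(abs(back - percent) > 0.05 + 1e-9))
    stop("reconstructed counts do not re-yield the printed percentages")
  rbind(dropped = dropped, retained = n_start - dropped)
}
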