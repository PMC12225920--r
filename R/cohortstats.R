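# Group-comparison battery: normality-gated two-group tests (Shapiro-Wilk ->
# t-test with means, otherwise Mann-Whitney rank-sum with medians and U) and
# the subtype x nucleus two-way ANOVA with Type-II sums of squares (computed
# by nested model comparison so it stays defined for unbalanced and even
# zero-residual designs).

#' Normality-gated two-group comparison
#'
#' Both samples are tested with Shapiro-Wilk at `alpha_normality`; if both
#' pass, a plain two-sample t-test (pooled variance, two-sided) is run and the
#' group centers are reported as means. Otherwise a Mann-Whitney rank-sum test
#' is run and the centers are medians. The U statistic of the first sample is
#' reported together with `min(U1, U2)`; the p-value uses the exact
#' distribution when there are no ties and `n1 * n2 <= 400`, and the normal
#' approximation with tie correction otherwise.
#'
#' @param x,y Numeric samples (each of size >= 3).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param welch Use the Welch correction instead of the pooled-variance t-test
#'   (default FALSE).
#' @return A `test_result` list: `test` (`"t"` or `"rank-sum"`), `statistic`
#'   (t or U of the first sample), `u_min`, `df` (t only), `p_value`,
#'   `center_x`, `center_y`, `center_type`, `normality_p`, `degenerate` flag
#'   (all observations tied).
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05, welch = FALSE) {
  if (length(x) < 3L || length(y) < 3L) stop("each sample needs >= 3 values")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs where x wins (+ half-ties)
  u2 <- n1 * n2 - u1
  degenerate <- length(unique(c(x, y))) == 1L
  if (degenerate) {
    return(structure(list(test = "rank-sum", statistic = u1, u1 = u1,
                          u_min = min(u1, u2), df = NA_real_,
                          p_value = 1, center_x = stats::median(x),
                          center_y = stats::median(y), center_type = "median",
                          normality_p = c(NA_real_, NA_real_),
                          degenerate = TRUE), class = "test_result"))
  }
  swp <- function(s) if (length(unique(s)) == 1L) 0 else stats::shapiro.test(s)$p.value
  np <- c(swp(x), swp(y))
  if (all(np > alpha_normality)) {
    tt <- stats::t.test(x, y, var.equal = !welch)
    return(structure(list(test = "t", statistic = unname(tt$statistic),
                          u1 = u1, u_min = min(u1, u2),
                          df = unname(tt$parameter),
                          p_value = tt$p.value, center_x = mean(x),
                          center_y = mean(y), center_type = "mean",
                          normality_p = np, degenerate = FALSE),
                     class = "test_result"))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && n1 * n2 <= 400
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  structure(list(test = "rank-sum", statistic = u1, u1 = u1,
                 u_min = min(u1, u2),
                 df = NA_real_, p_value = wt$p.value,
                 center_x = stats::median(x), center_y = stats::median(y),
                 center_type = "median", normality_p = np,
                 degenerate = FALSE), class = "test_result")
}

#' Two-way ANOVA with Type-II sums of squares
#'
#' F statistics for both main effects and the interaction of a 2x2 design
#' (e.g. SST subtype x thalamic nucleus) using Type-II sums of squares, which
#' reduce to the classical two-way ANOVA when the design is balanced and
#' remain appropriate for the unbalanced cell counts of real cohorts.
#'
#' @param values Numeric response (e.g. EPSP amplitude per cell).
#' @param factor_a,factor_b Factors of the design (two levels each; every
#'   cell of the design needs >= 2 observations for the interaction).
#' @return Data frame (`anova_table`) with rows for `factor_a`, `factor_b`,
#'   `interaction` and `residuals`: `sum_sq`, `df`, `f`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L) stop("each factor needs two levels")
  tab <- table(a, b)
  if (any(tab == 0L)) stop("empty design cell: interaction inestimable")
  if (any(tab < 2L)) warning("design cell with < 2 observations")
  dat <- data.frame(y = values, a = a, b = b)
  rss <- function(fml) sum(stats::residuals(stats::lm(fml, data = dat))^2)
  # Type-II: each effect adjusted for the other main effect, the interaction
  # adjusted for both main effects
  rss_a <- rss(y ~ b); rss_b <- rss(y ~ a)
  rss_ab <- rss(y ~ a + b); rss_full <- rss(y ~ a * b)
  ss <- c(rss_a - rss_ab, rss_b - rss_ab, rss_ab - rss_full)
  df_eff <- c(nlevels(a) - 1L, nlevels(b) - 1L,
              (nlevels(a) - 1L) * (nlevels(b) - 1L))
  df_res <- length(values) - nlevels(a) * nlevels(b)
  ms_res <- rss_full / df_res
  f <- if (ms_res > 0) (ss / df_eff) / ms_res else rep(NA_real_, 3L)
  out <- data.frame(
    term = c("factor_a", "factor_b", "interaction", "residuals"),
    sum_sq = c(ss, rss_full),
    df = c(df_eff, df_res),
    f = c(f, NA_real_),
    p = c(stats::pf(f, df_eff, df_res, lower.tail = FALSE), NA_real_)
  )
  class(out) <- c("anova_table", class(out))
  out
}
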