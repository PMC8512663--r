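# Hypothesis-testing layer: distributional checks, paired comparisons with
# a normality gate, the rank-based two-way (Scheirer-Ray-Hare) test, and
# Benjamini-Hochberg FDR adjustment. All tests are two-sided.

test_result <- function(test_name, statistic, df = NA_real_, p_value) {
  data.frame(test_name = test_name, statistic = unname(statistic),
             df = unname(df), p_value = unname(p_value),
             stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return One-row data frame: `test_name`, `statistic` (W), `df`, `p_value`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000) {
    stop("shapiro_wilk: sample size must be in [3, 5000]")
  }
  r <- stats::shapiro.test(x)
  test_result("shapiro_wilk", r$statistic, p_value = r$p.value)
}

#' Levene test for homogeneity of variance
#'
#' Brown-Forsythe variant (deviations from the group medians).
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 2).
#' @return One-row data frame with the F statistic and p-value.
#' @export
levene <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("levene: need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) stop("levene: each group needs n >= 2")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  r <- car::leveneTest(y, g)
  test_result("levene", r[1, "F value"], df = r[1, "Df"], p_value = r[1, "Pr(>F)"])
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are excluded; the exact null distribution is used for
#' n <= 25 without ties, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b Paired numeric samples of equal length.
#' @return One-row data frame with the V statistic and p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) stop("wilcoxon_signed_rank: all differences are zero")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  r <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result("wilcoxon_signed_rank", r$statistic, p_value = r$p.value)
}

#' Paired t-test
#'
#' @param a,b Paired numeric samples.
#' @return One-row data frame with t, df and p-value.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a - b) == 0 && all(a == b)) {
    return(test_result("paired_t", 0, df = length(a) - 1, p_value = 1))
  }
  r <- stats::t.test(a, b, paired = TRUE)
  test_result("paired_t", r$statistic, df = r$parameter, p_value = r$p.value)
}

#' One-way ANOVA
#'
#' @param groups List of numeric samples.
#' @return One-row data frame with F, numerator df and p-value; the
#'   `eta_sq` column gives the effect size SS_between / SS_total.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("one_way_anova: need >= 2 groups")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  out <- test_result("one_way_anova", s[1, "F value"], df = s[1, "Df"],
                     p_value = s[1, "Pr(>F)"])
  out$eta_sq <- s[1, "Sum Sq"] / sum(s[, "Sum Sq"])
  out
}

#' Scheirer-Ray-Hare test
#'
#' Rank-based extension of the two-way ANOVA for non-parametric factorial
#' data: all values are ranked jointly, two-way ANOVA sums of squares are
#' computed on the ranks, and each effect's statistic
#' `H = SS_effect / MS_total` is referred to a chi-square distribution with
#' the effect's degrees of freedom.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factor labels (fully crossed design).
#' @return Data frame with one row per effect (A, B, A:B): `effect`, `df`,
#'   `statistic` (H) and `p_value`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (any(table(a, b) == 0)) stop("scheirer_ray_hare: design must be fully crossed")
  r <- rank(values)
  n <- length(r)
  fit <- stats::aov(r ~ a * b)
  s <- summary(fit)[[1]]
  ss <- s[, "Sum Sq"]
  df <- s[, "Df"]
  ms_total <- sum((r - mean(r))^2) / (n - 1)
  eff <- c("A", "B", "A:B")
  h <- ss[1:3] / ms_total
  data.frame(effect = eff, df = df[1:3], statistic = h,
             p_value = stats::pchisq(h, df[1:3], lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p_(i) * m / i` with monotone enforcement,
#' capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("bh_fdr: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Normality-gated pairwise comparisons against a reference condition
#'
#' For every non-reference condition the paired differences against the
#' reference are tested for normality (Shapiro-Wilk at alpha = 0.05); a
#' paired t-test is used where the gate passes and the Wilcoxon signed-rank
#' test otherwise. All p-values are BH-adjusted jointly.
#'
#' @param values Numeric matrix, subjects x conditions, with condition
#'   column names.
#' @param reference Reference condition (column name).
#' @param gate_alpha Normality-gate significance level.
#' @return Data frame: `comparison`, `test_name`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
gated_pairwise <- function(values, reference, gate_alpha = 0.05) {
  stopifnot(is.matrix(values), reference %in% colnames(values),
            ncol(values) >= 2)
  conds <- setdiff(colnames(values), reference)
  rows <- lapply(conds, function(cond) {
    a <- values[, cond]
    b <- values[, reference]
    d <- a - b
    use_t <- if (stats::sd(d) == 0) TRUE else {
      shapiro_wilk(d)$p_value >= gate_alpha
    }
    res <- if (use_t) paired_t(a, b) else wilcoxon_signed_rank(a, b)
    cbind(comparison = paste(cond, "vs", reference), res)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  row.names(out) <- NULL
  out
}
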