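## Statistical procedures used throughout the analysis chain. Standard
## tests delegate to base R / car; the wrappers fix the conventions
## (two-sided throughout, exact small-sample Mann-Whitney, Type II ANOVA,
## conditional-MLE odds ratio) and return uniform result records.

#' Two-tailed Mann-Whitney U test
#'
#' Computes the U statistic for `x` versus `y` and a two-sided p-value:
#' exact (full permutation distribution of the ranks) when the combined
#' sample size is at most `exact_max_n` and there are no ties, otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max_n combined-size cutoff for the exact method
#'   (default 16); ties always force the approximation.
#' @return A list: `statistic_U` (U for `x`), `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 16L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (n1 + n2) <= exact_max_n
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic_U = unname(wt$statistic),
       p_two_sided = min(1, unname(wt$p.value)),
       method = if (use_exact) "exact" else "normal_approx",
       n1 = n1, n2 = n2)
}

#' Unpaired two-tailed t-test
#'
#' Student's pooled-variance test by default (the convention behind an
#' "unpaired two-tailed t-test"); Welch's unequal-variance variant via
#' `equal_var = FALSE`.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param equal_var pool the variances (default `TRUE`).
#' @return A list: `statistic`, `p_two_sided`, `df`, `method`, `n1`, `n2`.
#' @export
t_test_unpaired <- function(x, y, equal_var = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, p_two_sided = 1,
                  df = length(x) + length(y) - 2L, method = "t",
                  n1 = length(x), n2 = length(y)))
    }
    stop("zero variance in both samples")
  }
  tt <- stats::t.test(x, y, var.equal = equal_var,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p_two_sided = tt$p.value,
       df = unname(tt$parameter), method = "t",
       n1 = length(x), n2 = length(y))
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `value ~ A * B` and reports Type II sums of squares (identical to
#' Type I/III for balanced designs), with F and p per term.
#'
#' @param values numeric response.
#' @param a,b factor labels (coerced to factor), at least 2 levels each.
#' @return A data frame with rows `A`, `B`, `A:B`, `Residuals` and columns
#'   `sum_sq`, `df`, `F`, `p`.
#' @export
anova_two_way <- function(values, a, b) {
  a <- factor(a); b <- factor(b)
  stopifnot(nlevels(a) >= 2, nlevels(b) >= 2,
            length(values) == length(a), length(a) == length(b))
  fit <- stats::lm(values ~ a * b)
  if (stats::df.residual(fit) < 1L) stop("zero residual degrees of freedom")
  rss <- sum(stats::residuals(fit)^2)
  if (rss > 1e-12 * max(sum((values - mean(values))^2), 1)) {
    an <- car::Anova(fit, type = 2)
    out <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                      sum_sq = an[["Sum Sq"]], df = an[["Df"]],
                      F = an[["F value"]], p = an[["Pr(>F)"]])
  } else {
    # an exact fit (zero residual SS): F is undefined; report the Type II
    # SS decomposition via model comparisons
    r2 <- function(f) sum(stats::residuals(f)^2)
    f_ab <- stats::lm(values ~ a + b)
    ss <- c(r2(stats::lm(values ~ b)) - r2(f_ab),
            r2(stats::lm(values ~ a)) - r2(f_ab),
            r2(f_ab) - rss, rss)
    out <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                      sum_sq = ss,
                      df = c(nlevels(a) - 1L, nlevels(b) - 1L,
                             (nlevels(a) - 1L) * (nlevels(b) - 1L),
                             stats::df.residual(fit)),
                      F = c(NA_real_, NA_real_, NA_real_, NA_real_),
                      p = c(NA_real_, NA_real_, NA_real_, NA_real_))
  }
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of all tables
#' (margins fixed) no more probable than the observed one; odds ratio as
#' the conditional maximum-likelihood estimate with an exact central
#' confidence interval (tails inverted at `alpha/2`). The sample odds
#' ratio `ad/bc` is reported alongside for transparency.
#'
#' @param a,b,c,d non-negative integer cell counts: rows are groups,
#'   columns outcomes, so the table is `rbind(c(a, b), c(c, d))`.
#' @param alpha confidence level complement (default 0.05 for a 95% CI).
#' @return A list: `p_two_sided`, `odds_ratio` (conditional MLE; `NA` and
#'   `or_defined = FALSE` for a degenerate margin), `ci_low`, `ci_high`,
#'   `sample_or`, `alpha`.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)
#' @export
fisher_exact_2x2 <- function(a, b, c, d, alpha = 0.05) {
  cnt <- c(a, b, c, d)
  stopifnot(all(cnt >= 0), all(cnt == floor(cnt)), sum(cnt) > 0,
            alpha > 0, alpha < 1)
  tab <- matrix(as.integer(cnt), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(p_two_sided = 1, odds_ratio = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_,
                sample_or = NA_real_, or_defined = FALSE, alpha = alpha))
  }
  ft <- stats::fisher.test(tab, conf.level = 1 - alpha)
  list(p_two_sided = ft$p.value,
       odds_ratio = unname(ft$estimate),
       ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
       sample_or = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       or_defined = TRUE, alpha = alpha)
}

#' Germline carrier frequency as a printed percentage
#'
#' Percentage of carriers in a cohort, rounded half-up to two decimals and
#' formatted as `"X.XX%"` (the convention of cohort summaries such as
#' 13 carriers among 17654 patients printing as 0.07%).
#'
#' @param carriers,cohort non-negative integers, `carriers <= cohort`,
#'   `cohort > 0`.
#' @return A list: `percent` (numeric, rounded) and `label` (string).
#' @examples
#' carrier_frequency(13, 17654)$label  # "0.07%"
#' @export
carrier_frequency <- function(carriers, cohort) {
  stopifnot(length(carriers) == 1, length(cohort) == 1,
            carriers >= 0, carriers == floor(carriers),
            cohort == floor(cohort))
  if (cohort <= 0) stop("cohort must be positive")
  if (carriers > cohort) stop("carriers cannot exceed cohort")
  pct <- 100 * carriers / cohort
  rounded <- floor(pct * 100 + 0.5) / 100        # round half-up
  list(percent = rounded, label = sprintf("%.2f%%", rounded))
}
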