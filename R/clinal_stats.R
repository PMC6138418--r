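# The tropical-vs-temperate statistics: 2x2 contingency tests on haplotype
# distributions and one-sided group comparisons of sleep metrics.
#
# Conventions matched to the source analyses: no continuity correction on the
# Pearson chi-square, a one-sided Fisher default (enrichment of row 1 in
# column 1), classic pooled-variance Student's t (Welch behind a flag), and no
# multiple-testing correction anywhere (raw p-values are reported as such).

.test_result <- function(test, statistic, p, sidedness, df = NA_real_) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p), sidedness = sidedness, df = unname(df)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g%s, %s p = %.4g\n", x$test, x$statistic,
              if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$sidedness, x$p_value))
  invisible(x)
}

.check_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2, 2)))
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) == 0) stop("empty table")
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default (no Yates continuity correction): the statistic is
#' the plain `sum((O - E)^2 / E)` with df = 1 and an upper-tail p-value.
#'
#' @param m 2x2 matrix of counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return a `test_result`.
#' @export
chi_square_2x2 <- function(m, correct = FALSE) {
  m <- .check_2x2(m)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: expected counts undefined")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  .test_result("chi-square", ct$statistic, ct$p.value, "two-sided", df = 1)
}

#' Fisher exact test on a 2x2 table
#'
#' One-sided by default, in the direction of enrichment of row 1 in column 1
#' (the hypergeometric upper tail `P(A >= a)` with margins fixed); two-sided
#' sums the probabilities of all tables no more likely than the observed one.
#'
#' @param m 2x2 matrix of counts.
#' @param alternative `"one.sided"` (default) or `"two.sided"`.
#' @return a `test_result` (statistic = sample odds ratio estimate).
#' @export
fisher_exact_2x2 <- function(m, alternative = c("one.sided", "two.sided")) {
  m <- .check_2x2(m)
  alternative <- match.arg(alternative)
  ft <- stats::fisher.test(m, alternative = if (alternative == "one.sided")
    "greater" else "two.sided")
  .test_result("fisher-exact", ft$estimate, ft$p.value, alternative)
}

#' One-sided two-sample Student's t-test
#'
#' Classic pooled-variance Student's t by default. When both groups are
#' constant and equal the statistic is 0/0; by convention p = 0.5 (no evidence
#' either way).
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param direction `"greater"` tests mean(a) > mean(b); `"less"` the reverse.
#' @param welch use the Welch unequal-variance form instead (default FALSE).
#' @return a `test_result`.
#' @export
t_test_one_sided <- function(a, b, direction = c("greater", "less"),
                             welch = FALSE) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(.test_result("student-t", 0, 0.5, paste0("one-sided (", direction, ")"),
                        df = length(a) + length(b) - 2))
  tt <- stats::t.test(a, b, alternative = direction, var.equal = !welch)
  .test_result(if (welch) "welch-t" else "student-t", tt$statistic, tt$p.value,
               paste0("one-sided (", direction, ")"), df = tt$parameter)
}

#' One-way ANOVA across groups
#'
#' Standard F statistic with upper-tail p. With two groups the F statistic
#' equals the square of the pooled two-sample t statistic.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return a `test_result`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  if (length(values) != length(groups)) stop("length mismatch")
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  f <- unname(ow$statistic)
  p <- ow$p.value
  if (is.nan(f)) { f <- 0; p <- 1 }   # zero between- and within-group variance
  .test_result("oneway-anova", f, p, "upper-tail",
               df = unname(ow$parameter[1]))
}
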