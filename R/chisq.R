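# Chi-squared comparison of conservative/non-conservative counts between
# two groups (2x2 contingency tables, df = 1).

#' Chi-squared test on a 2x2 table
#'
#' Pearson chi-squared statistic for the table
#' \preformatted{  a  b
#'   c  d}
#' via the closed form n(ad - bc)^2 / \[(a+b)(c+d)(a+c)(b+d)\] with
#' n = a+b+c+d, and the p-value from the chi-squared distribution with one
#' degree of freedom. No continuity correction by default; `correct = TRUE`
#' applies the Yates correction (|ad - bc| reduced by n/2, floored at 0).
#'
#' @param a,b,c,d Non-negative counts; every row and column margin must be
#'   positive.
#' @param correct Apply the Yates continuity correction.
#' @return A `contingency_result`: `table`, `statistic`, `df`, `p_value`,
#'   `correction`.
#' @export
chi2_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("zero margin: groups are not comparable by chi-squared")
  delta <- abs(a * d - b * c)
  if (correct) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / prod(margins)
  structure(list(table = matrix(counts, 2, 2, byrow = TRUE,
                                dimnames = list(c("group1", "group2"),
                                                c("conservative", "non_conservative"))),
                 statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 correction = correct),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Chi-squared (df = 1%s): statistic %.4f, p = %.3g %s\n",
              if (x$correction) ", Yates-corrected" else "",
              x$statistic, x$p_value, significance_tier(x$p_value)))
  invisible(x)
}

#' Compare two conservative fractions by chi-squared
#'
#' Builds the (conservative, non-conservative) x (group1, group2) table from
#' the underlying counts -- never from the fractions themselves -- and
#' delegates to [chi2_2x2()].
#'
#' @param r1,r2 `fraction_result` objects with defined fractions.
#' @param correct Apply the Yates continuity correction.
#' @return A `contingency_result`.
#' @export
compare_fractions <- function(r1, r2, correct = FALSE) {
  stopifnot(inherits(r1, "fraction_result"), inherits(r2, "fraction_result"))
  if (!r1$defined || !r2$defined)
    stop("cannot compare an undefined fraction (no substitutions in a group)")
  chi2_2x2(r1$n_conservative, r1$n_total - r1$n_conservative,
           r2$n_conservative, r2$n_total - r2$n_conservative,
           correct = correct)
}

#' Significance tier for report annotation
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
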