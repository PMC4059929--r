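#' One-sided Fisher's exact test for case enrichment
#'
#' Computes the upper-tail hypergeometric probability for a 2x2
#' carrier/non-carrier table, together with the cross-product odds ratio.
#' The table is laid out as cases vs controls:
#'
#' \tabular{lcc}{
#'            \tab carrier \tab non-carrier \cr
#'   cases    \tab a       \tab b           \cr
#'   controls \tab c       \tab d
#' }
#'
#' With the margins fixed, the number of case carriers follows a
#' hypergeometric distribution; the reported p-value is \eqn{P(X \ge a)},
#' the probability of observing at least as many case carriers as seen.
#' This one-sided (case-enrichment) orientation is the convention used
#' throughout the package: a small p means carriers concentrate in cases.
#'
#' The odds ratio is the unconditional cross-product \eqn{(a d)/(b c)}. It is
#' \code{Inf} when \eqn{b c = 0} and \eqn{a d > 0}, and \code{NaN} when both
#' products vanish (no information). Note this is not the conditional MLE
#' that [stats::fisher.test()] reports.
#'
#' @param a,b,c,d Non-negative counts, vectorised and recycled to a common
#'   length. `a + b` (cases) and `c + d` (controls) must be positive.
#' @return A list with components `p_one_sided` and `odds_ratio`, numeric
#'   vectors of the common length.
#' @examples
#' # 265/4602 case carriers vs 153/4722 control carriers
#' fisher_one_sided(265, 4602 - 265, 153, 4722 - 153)
#' @seealso [confusion_metrics()]
#' @export
fisher_one_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  d <- rep_len(as.numeric(d), n)
  check_that(all(is.finite(c(a, b, c, d))) && all(c(a, b, c, d) >= 0),
             "all four counts must be finite and non-negative")
  check_that(all(a + b > 0), "case margin a + b must be positive")
  check_that(all(c + d > 0), "control margin c + d must be positive")
  check_that(all(a + b + c + d > 0), "all-zero table: test undefined")

  # P(X >= a) for X ~ Hypergeometric(white = a+b cases, black = c+d controls,
  # drawn = a+c carriers)
  p <- stats::phyper(a - 1, m = a + b, n = c + d, k = a + c,
                     lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  ad <- a * d
  bc <- b * c
  or <- ifelse(bc > 0, ad / bc, ifelse(ad > 0, Inf, NaN))
  list(p_one_sided = p, odds_ratio = or)
}

#' Validation confusion-matrix summary
#'
#' Sensitivity, specificity, positive and negative predictive value from
#' true/false positive/negative counts, as used to summarise qPCR validation
#' of CNV predictions. A ratio with a zero denominator is reported as `NA`
#' (absent), never as zero.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return A list with components `sensitivity`, `specificity`, `ppv`, `npv`.
#' @examples
#' confusion_metrics(tp = 13, fn = 7, fp = 0, tn = 50)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  check_that(all(is.finite(counts)) && all(counts >= 0),
             "counts must be finite and non-negative")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over [stats::p.adjust()] provided for post-hoc FDR control of
#' CNVR or network p-values. Not applied by default anywhere in the package:
#' region selection follows raw p-value thresholds.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
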