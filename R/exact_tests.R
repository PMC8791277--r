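#' One-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric upper-tail probability P(X >= a) for the table
#' \preformatted{
#'     a  b      (labeled-in,  other-expressed-in)
#'     c  d      (labeled-out, other-expressed-out)
#' }
#' testing enrichment of the first-row class in the first column. This is the
#' shared exact-test primitive behind the chromosome and sliding-window scans
#' and the interval-overlap test.
#'
#' @param a,b,c,d non-negative integer cell counts (vectorized).
#' @return Numeric vector of one-sided p values. An all-zero table returns 1.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  cells <- cbind(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  n_tot <- a + b + c + d
  k_row <- a + b   # first-row total
  n_col <- a + c   # first-column total
  p <- rep(1, length(a))
  nz <- n_tot > 0
  # upper tail P(X >= a) for X ~ Hypergeom(N, K = row1 total, n = col1 total)
  p[nz] <- stats::phyper(a[nz] - 1, k_row[nz], n_tot[nz] - k_row[nz],
                         n_col[nz], lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Pearson chi-squared test for a 2x2 incidence table
#'
#' Pearson statistic without continuity correction, compared against the
#' 1-df chi-squared reference distribution. Used for intron-retention and
#' inverted-SINE incidence contrasts.
#'
#' @param a,b,c,d non-negative cell counts of the 2x2 table (row-wise).
#' @return List with \code{chi2} and \code{p}.
#' @export
incidence_chi2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), nrow = 2)  # byrow layout (a b; c d)
  if (any(tab < 0)) stop("cell counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Shared 2x2 incidence test with small-sample fallback
#'
#' Builds the (with-feature, without-feature) x (labeled, control) table from
#' two logical flag vectors and tests whether the feature is more frequent in
#' the first group. When every expected cell is at least 5 the Pearson
#' chi-squared test (two-sided, no continuity correction) is used; otherwise
#' the one-sided exact hypergeometric test replaces it.
#'
#' @param flags_labeled,flags_control logical vectors (one entry per gene).
#' @return List with \code{table} (2x2 matrix), \code{method}
#'   ("chi-squared" or "fisher"), \code{chi2} (NA for the exact route) and
#'   \code{p}.
#' @export
incidence_test <- function(flags_labeled, flags_control) {
  a <- sum(flags_labeled); b <- sum(!flags_labeled)
  c_ <- sum(flags_control); d <- sum(!flags_control)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("labeled", "control"),
                                c("with", "without")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) {
    p <- fisher_one_sided(a, b, c_, d)
    list(table = tab, method = "fisher", chi2 = NA_real_, p = p)
  } else {
    res <- incidence_chi2(a, b, c_, d)
    list(table = tab, method = "chi-squared", chi2 = res$chi2, p = res$p)
  }
}

#' One-sided rank-sum test
#'
#' Wilcoxon rank-sum test of location shift between two samples. For combined
#' sample sizes up to \code{exact_limit} the p value is computed by exhaustive
#' enumeration of all group assignments of the pooled values (exact even with
#' ties); larger samples use the normal approximation with tie correction and
#' no continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative "greater" tests whether x tends to exceed y; "less" the
#'   reverse.
#' @param exact_limit combined-size cutoff for the enumeration route.
#' @return One-sided p value.
#' @export
rank_sum_test <- function(x, y, alternative = c("greater", "less"),
                          exact_limit = 20) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  m <- length(x); n <- length(y)
  if (m + n <= exact_limit) {
    pooled <- c(x, y)
    r <- rank(pooled)
    obs <- sum(r[seq_len(m)])
    idx <- utils::combn(m + n, m)
    sums <- colSums(matrix(r[idx], nrow = m))
    if (alternative == "greater") {
      mean(sums >= obs)
    } else {
      mean(sums <= obs)
    }
  } else {
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = FALSE, correct = FALSE)$p.value
  }
}

#' Benjamini-Hochberg adjusted p values
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} so every module
#' corrects multiple tests identically.
#'
#' @param p numeric vector of p values.
#' @return Numeric vector of q values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
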