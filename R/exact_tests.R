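# Exact tests used throughout the ASE pipeline.
#
# The two-sided conventions are fixed here for bit-reproducibility:
# every test sums the probabilities of all outcomes/tables no more likely
# than the observed one ("minimum-likelihood" rule), with the standard
# floating-point tie guard prob <= observed * (1 + 1e-7).

.TIE_GUARD <- 1 + 1e-7

#' Two-sided exact binomial test
#'
#' Exact two-sided p-value for `x` successes in `n` Bernoulli trials with
#' null success probability `p0`, by the minimum-likelihood rule: the sum of
#' `dbinom(k, n, p0)` over all outcomes `k` whose probability does not
#' exceed that of the observed outcome.
#'
#' @param x Number of successes (non-negative integer, `x <= n`).
#' @param n Number of trials (positive integer).
#' @param p0 Null success probability, default 0.5 (the no-imbalance null
#'   for depth-adjusted allele counts).
#' @return A single p-value in (0, 1].
#' @examples
#' binomial_exact_test(10, 10)        # 2 * 0.5^10
#' binomial_exact_test(5, 10)         # 1: observed outcome is the mode
#' @export
binomial_exact_test <- function(x, n, p0 = 0.5) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n))
    stop("x and n must be single non-missing values")
  if (x < 0 || x != round(x) || n < 1 || n != round(n))
    stop("x must be a non-negative integer and n a positive integer")
  if (x > n) stop("x must not exceed n (got x = ", x, ", n = ", n, ")")
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  d <- stats::dbinom(0:n, n, p0)
  p <- sum(d[d <= d[x + 1L] * .TIE_GUARD])
  min(1, p)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value for independence in the table `[[a, b], [c, d]]`, by
#' enumeration of the hypergeometric support at fixed margins and summing
#' the probabilities of all tables no more likely than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows first:
#'   `a` and `b` are the first row, `c` and `d` the second.
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3)   # 0.1
#' fisher_exact_2x2(5, 5, 5, 5)   # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (length(cells) != 4L || anyNA(cells) || any(cells < 0) ||
      any(cells != round(cells)))
    stop("a, b, c, d must be single non-negative integers")
  if (sum(cells) == 0) stop("all-zero table has no defined test")
  m <- a + b       # first-row margin
  n2 <- c + d      # second-row margin
  k <- a + c       # first-column margin
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  supp <- lo:hi
  d0 <- stats::dhyper(supp, m, n2, k)
  p <- sum(d0[d0 <= d0[a - lo + 1L] * .TIE_GUARD])
  min(1, p)
}

#' Freeman-Halton exact test for tables up to 2x3
#'
#' Exact p-value by exhaustive enumeration of all tables sharing the
#' observed margins, summing the (multivariate hypergeometric)
#' probabilities of tables no more likely than the observed one.  For 2x2
#' inputs it reduces to [fisher_exact_2x2()].  Enumeration is capped at
#' 2 rows x 3 columns and a grand total of 200; larger problems are
#' rejected rather than approximated.
#'
#' @param table Non-negative integer matrix, at most 2 rows and 3 columns.
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact_rxc(rbind(c(10, 10, 10), c(10, 10, 10)))  # 1
#' fisher_exact_rxc(rbind(c(36, 16), c(2, 50)))           # < 1e-3
#' @export
fisher_exact_rxc <- function(table) {
  tab <- as.matrix(table)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("table must contain non-negative integers")
  if (nrow(tab) > 2L || ncol(tab) > 3L)
    stop("unsupported table size ", nrow(tab), "x", ncol(tab),
         ": enumeration is capped at 2x3")
  total <- sum(tab)
  if (total == 0) stop("all-zero table has no defined test")
  if (total > 200) stop("table total ", total, " exceeds enumeration cap 200")
  if (nrow(tab) == 1L || ncol(tab) == 1L) return(1)
  cs <- colSums(tab)
  r1 <- sum(tab[1L, ])
  # log-probability of a first row (x1, ..., xc) at fixed margins
  log_prob_row <- function(row) {
    sum(lchoose(cs, row)) - lchoose(total, r1)
  }
  obs_lp <- log_prob_row(tab[1L, ])
  guard <- log(.TIE_GUARD)
  p <- 0
  if (ncol(tab) == 2L) {
    lo <- max(0L, r1 - cs[2L]); hi <- min(r1, cs[1L])
    for (x1 in lo:hi) {
      lp <- log_prob_row(c(x1, r1 - x1))
      if (lp <= obs_lp + guard) p <- p + exp(lp)
    }
  } else {
    for (x1 in 0:min(r1, cs[1L])) {
      rem <- r1 - x1
      lo2 <- max(0L, rem - cs[3L]); hi2 <- min(rem, cs[2L])
      if (lo2 > hi2) next
      for (x2 in lo2:hi2) {
        lp <- log_prob_row(c(x1, x2, rem - x2))
        if (lp <= obs_lp + guard) p <- p + exp(lp)
      }
    }
  }
  min(1, p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate correction.  Thin wrapper over
#' `stats::p.adjust(method = "BH")` kept as the package-wide surface so the
#' correction applied to the three ASE test families is in one place.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}
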