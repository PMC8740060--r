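# Hybrid inheritance-mode classification and group spectrum comparison.
#
# The pipeline normally consumes external differential-expression calls
# (e.g. a DESeq2 + edgeR consensus at FDR 5% and |lfc| > 1);
# simple_pairwise_test is a self-contained stand-in so synthetic
# end-to-end runs need no external caller.

#' Simple pairwise differential-expression stand-in test
#'
#' Welch two-sample t-test on `log2(count + 1)` replicate values.  The
#' log2 fold change is the difference of group means on that scale
#' (first group over second); the call is significant iff `p < alpha`
#' and `|lfc| > lfc_threshold`.
#'
#' @param counts_a,counts_b Numeric replicate count vectors (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param lfc_threshold Minimum |log2 fold change| (default 1).
#' @return List: `lfc`, `p`, `significant`.
#' @export
simple_pairwise_test <- function(counts_a, counts_b, alpha = 0.05,
                                 lfc_threshold = 1) {
  if (length(counts_a) < 2L || length(counts_b) < 2L)
    stop("need >= 2 replicates per group")
  la <- log2(counts_a + 1)
  lb <- log2(counts_b + 1)
  lfc <- mean(la) - mean(lb)
  p <- if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
  } else {
    stats::t.test(la, lb)$p.value
  }
  list(lfc = lfc, p = p, significant = p < alpha && abs(lfc) > lfc_threshold)
}

#' Classify a gene's hybrid inheritance mode
#'
#' From the hybrid-vs-each-parent differential-expression calls:
#' transgressive_up iff significantly above both parents;
#' transgressive_down iff significantly below both; non_differential iff
#' significant versus neither; additive otherwise (significant versus at
#' least one parent without being transgressive, i.e. intermediate).
#'
#' @param call_vs_ppse,call_vs_pbog Lists with `gene_id` (optional),
#'   `lfc` (hybrid over parent) and `significant`.
#' @return One of `"transgressive_up"`, `"transgressive_down"`,
#'   `"additive"`, `"non_differential"`.
#' @export
classify_inheritance <- function(call_vs_ppse, call_vs_pbog) {
  ga <- call_vs_ppse$gene_id; gb <- call_vs_pbog$gene_id
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb))
    stop("gene_id mismatch between the two calls: ", ga, " vs ", gb)
  sa <- isTRUE(call_vs_ppse$significant)
  sb <- isTRUE(call_vs_pbog$significant)
  if (sa && sb && call_vs_ppse$lfc > 0 && call_vs_pbog$lfc > 0)
    return("transgressive_up")
  if (sa && sb && call_vs_ppse$lfc < 0 && call_vs_pbog$lfc < 0)
    return("transgressive_down")
  if (!sa && !sb) return("non_differential")
  "additive"
}

#' Classify inheritance for matrices of replicate counts
#'
#' Applies [simple_pairwise_test()] of hybrid vs each parent per gene and
#' maps the two calls through [classify_inheritance()].
#'
#' @param parent_a,parent_b,hybrid Count matrices (genes x replicates)
#'   with matching rownames.
#' @param alpha,lfc_threshold Passed to [simple_pairwise_test()].
#' @return Data frame: `gene_id`, `mode`.
#' @export
classify_inheritance_matrix <- function(parent_a, parent_b, hybrid,
                                        alpha = 0.05, lfc_threshold = 1) {
  if (!identical(rownames(parent_a), rownames(hybrid)) ||
      !identical(rownames(parent_b), rownames(hybrid)))
    stop("count matrices must share identical gene rownames")
  modes <- vapply(seq_len(nrow(hybrid)), function(i) {
    ca <- simple_pairwise_test(hybrid[i, ], parent_a[i, ], alpha,
                               lfc_threshold)
    cb <- simple_pairwise_test(hybrid[i, ], parent_b[i, ], alpha,
                               lfc_threshold)
    classify_inheritance(ca, cb)
  }, character(1))
  data.frame(gene_id = rownames(hybrid), mode = modes,
             stringsAsFactors = FALSE)
}

#' Compare inheritance-mode spectra between two hybrid groups
#'
#' Builds the contingency table of mode counts for the two groups —
#' either 2x2 (transgressive vs rest, pooling up/down) or 2x3
#' (transgressive / additive / non_differential) — and applies the exact
#' Freeman-Halton test.
#'
#' @param modes_a,modes_b Character vectors (or `mode` columns) of
#'   inheritance calls for the two groups.
#' @param collapse `"transgressive_vs_rest"` or `"three_way"`.
#' @return List: `table` (the contingency table, groups as rows) and `p`.
#' @export
compare_inheritance_spectra <- function(modes_a, modes_b,
                                        collapse = c("transgressive_vs_rest",
                                                     "three_way")) {
  collapse <- match.arg(collapse)
  if (length(modes_a) == 0L || length(modes_b) == 0L)
    stop("both groups must be non-empty")
  pool <- function(m) {
    m <- as.character(m)
    bad <- setdiff(m, INHERITANCE_MODES)
    if (length(bad)) stop("unknown inheritance mode(s): ",
                          paste(unique(bad), collapse = ", "))
    if (collapse == "transgressive_vs_rest") {
      f <- ifelse(m %in% c("transgressive_up", "transgressive_down"),
                  "transgressive", "rest")
      table(factor(f, levels = c("transgressive", "rest")))
    } else {
      f <- ifelse(m %in% c("transgressive_up", "transgressive_down"),
                  "transgressive", m)
      table(factor(f, levels = c("transgressive", "additive",
                                 "non_differential")))
    }
  }
  tab <- rbind(groupA = pool(modes_a), groupB = pool(modes_b))
  list(table = tab, p = fisher_exact_rxc(tab))
}
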