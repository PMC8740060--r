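# Six-category cis/trans regulatory-divergence classification from
# depth-adjusted parent-of-origin counts.
#
# Three exact tests per gene:
#   test 1 (parent): P_pse vs P_bog, binomial against 0.5 — any regulatory
#     divergence between the subspecies.
#   test 2 (hybrid): H_pse vs H_bog, binomial against 0.5 — allelic
#     imbalance inside the hybrid, where both alleles share one trans
#     environment, so imbalance is a cis signal.
#   test 3 (ratio):  Fisher 2x2 on (P_pse, P_bog) vs (H_pse, H_bog) — does
#     the parental ratio differ from the hybrid allelic ratio (a trans
#     signal).
# Each family is BH-corrected across genes and flags (q < alpha) map to
# categories.

REG_CATEGORIES <- c("conserved", "cis_only", "trans_only", "cis_and_trans",
                    "compensatory", "ambiguous")
CIS_EFFECT_CATEGORIES <- c("cis_only", "cis_and_trans", "compensatory")

# (sig_parent, sig_hybrid, sig_ratio) -> category
.category_from_flags <- function(sig_parent, sig_hybrid, sig_ratio) {
  ifelse(!sig_parent & !sig_hybrid & !sig_ratio, "conserved",
  ifelse( sig_parent &  sig_hybrid & !sig_ratio, "cis_only",
  ifelse( sig_parent & !sig_hybrid &  sig_ratio, "trans_only",
  ifelse( sig_parent &  sig_hybrid &  sig_ratio, "cis_and_trans",
  ifelse(!sig_parent &  sig_hybrid &  sig_ratio, "compensatory",
         "ambiguous")))))
}

#' Classify genes into six regulatory-divergence categories
#'
#' Runs the parental binomial test, the hybrid-allele binomial test and the
#' parent-vs-hybrid-ratio Fisher test on each gene's depth-adjusted counts
#' (rounded half-up to integers), corrects each test family across genes by
#' Benjamini-Hochberg, and maps the significance flags (q < `alpha`) to one
#' of: conserved, cis_only, trans_only, cis_and_trans, compensatory,
#' ambiguous.  `cis_effect` is `TRUE` for the broad group
#' cis_only/cis_and_trans/compensatory.
#'
#' @param counts Data frame with `gene_id` and the four adjusted class
#'   counts `P_pse`, `P_bog`, `H_pse`, `H_bog` (all >= 1 after
#'   [adjust_depth()]).
#' @param alpha Per-family q-value significance cutoff; default 0.005
#'   (q < 0.5%).
#' @return A list with `tests` (per-gene p/q-values and flags) and `calls`
#'   (per-gene `category` and `cis_effect`).
#' @export
classify_regulatory_divergence <- function(counts, alpha = 0.005) {
  stopifnot_cols(counts, c("gene_id", ALLELE_CLASSES), "counts")
  if (nrow(counts) == 0L) stop("counts table is empty")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  pp <- round_half_up(counts$P_pse)
  pb <- round_half_up(counts$P_bog)
  hp <- round_half_up(counts$H_pse)
  hb <- round_half_up(counts$H_bog)
  n <- nrow(counts)
  p_parent <- p_hybrid <- p_ratio <- numeric(n)
  for (i in seq_len(n)) {
    p_parent[i] <- binomial_exact_test(pp[i], pp[i] + pb[i])
    p_hybrid[i] <- binomial_exact_test(hp[i], hp[i] + hb[i])
    p_ratio[i] <- fisher_exact_2x2(pp[i], pb[i], hp[i], hb[i])
  }
  q_parent <- bh_fdr(p_parent)
  q_hybrid <- bh_fdr(p_hybrid)
  q_ratio <- bh_fdr(p_ratio)
  sig_parent <- q_parent < alpha
  sig_hybrid <- q_hybrid < alpha
  sig_ratio <- q_ratio < alpha
  category <- .category_from_flags(sig_parent, sig_hybrid, sig_ratio)
  tests <- data.frame(gene_id = counts$gene_id,
                      p_parent = p_parent, p_hybrid = p_hybrid,
                      p_ratio = p_ratio,
                      q_parent = q_parent, q_hybrid = q_hybrid,
                      q_ratio = q_ratio,
                      sig_parent = sig_parent, sig_hybrid = sig_hybrid,
                      sig_ratio = sig_ratio,
                      stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = counts$gene_id,
                      category = factor(category, levels = REG_CATEGORIES),
                      cis_effect = category %in% CIS_EFFECT_CATEGORIES,
                      stringsAsFactors = FALSE)
  list(tests = tests, calls = calls)
}

#' Tally regulatory-divergence categories and the broad cis-effects group
#'
#' @param calls Call table from [classify_regulatory_divergence()].
#' @return List with `counts` (named tally over the six categories),
#'   `n` and `cis_effect_fraction` (share of genes in
#'   cis_only/cis_and_trans/compensatory).
#' @export
summarize_cis_effects <- function(calls) {
  stopifnot_cols(calls, c("gene_id", "category"), "calls")
  if (nrow(calls) == 0L) stop("calls table is empty")
  category <- factor(as.character(calls$category), levels = REG_CATEGORIES)
  tab <- table(category)
  list(counts = tab,
       n = nrow(calls),
       cis_effect_fraction =
         sum(tab[CIS_EFFECT_CATEGORIES]) / nrow(calls))
}
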