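# Fixed-SNP calling, parent-of-origin aggregation and depth adjustment.
#
# Input observations are per-site, per-sample allele read counts from the
# two parental subspecies ("pse" and "bog").  A site is a usable diagnostic
# SNP only when each subspecies is monomorphic for a different allele with
# enough supporting reads; hybrid reads at those sites can then be assigned
# a parent of origin unambiguously.

ALLELE_CLASSES <- c("P_pse", "P_bog", "H_pse", "H_bog")

#' Call fixed diagnostic SNPs between two parental subspecies
#'
#' A site is emitted as a fixed SNP iff each subspecies shows exactly one
#' allele at that site (tri-allelic or within-subspecies polymorphic sites
#' are rejected), the two alleles differ, and each subspecies' allele has at
#' least `min_support` reads summed across that subspecies' samples.
#'
#' @param observations Data frame with columns `chromosome`, `position`
#'   (1-based), `sample`, `subspecies` (`"pse"` or `"bog"`), `allele`
#'   (single character) and `count` (non-negative integer reads).
#' @param min_support Minimum summed read support per subspecies allele
#'   (default 3).
#' @return Data frame of fixed SNPs: `chromosome`, `position`, `allele_pse`,
#'   `allele_bog`, `support_pse`, `support_bog`.
#' @export
call_fixed_snps <- function(observations, min_support = 3) {
  stopifnot_cols(observations,
                 c("chromosome", "position", "sample", "subspecies",
                   "allele", "count"),
                 "observations")
  if (any(observations$count < 0)) stop("counts must be non-negative")
  if (!all(observations$subspecies %in% c("pse", "bog")))
    stop("subspecies labels must be 'pse' or 'bog'")
  key <- paste(observations$chromosome, observations$position,
               observations$sample, observations$allele, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- observations[duplicated(key), , drop = FALSE]
    stop("conflicting duplicate observation record(s), e.g. ",
         dup$chromosome[1], ":", dup$position[1], " sample ", dup$sample[1],
         " allele ", dup$allele[1])
  }
  obs <- observations[observations$count > 0, , drop = FALSE]
  if (nrow(obs) == 0L) return(.empty_fixed_snps())
  site <- paste(obs$chromosome, obs$position, sep = "\r")
  out <- lapply(split(obs, site), function(s) {
    res <- lapply(c("pse", "bog"), function(sub) {
      ss <- s[s$subspecies == sub, , drop = FALSE]
      tapply(ss$count, ss$allele, sum)
    })
    names(res) <- c("pse", "bog")
    if (length(res$pse) != 1L || length(res$bog) != 1L) return(NULL)
    if (names(res$pse) == names(res$bog)) return(NULL)
    if (res$pse < min_support || res$bog < min_support) return(NULL)
    data.frame(chromosome = s$chromosome[1], position = s$position[1],
               allele_pse = names(res$pse), allele_bog = names(res$bog),
               support_pse = unname(res$pse), support_bog = unname(res$bog),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(.empty_fixed_snps())
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_fixed_snps <- function() {
  data.frame(chromosome = character(), position = integer(),
             allele_pse = character(), allele_bog = character(),
             support_pse = numeric(), support_bog = numeric(),
             stringsAsFactors = FALSE)
}

#' Aggregate per-site allele counts to per-gene parent-of-origin totals
#'
#' Sums, per gene, the reads of the four allele classes (`P_pse`, `P_bog`,
#' `H_pse`, `H_bog`) over all fixed SNPs falling inside the gene's span and
#' over all samples/replicates.  Genes whose summed parental reads
#' (`P_pse + P_bog`) fall below `min_reads` are dropped; SNPs outside every
#' locus are ignored; a SNP inside two loci is an error.
#'
#' @param snps Fixed-SNP data frame as from [call_fixed_snps()].
#' @param site_counts Data frame of per-site class counts with columns
#'   `chromosome`, `position`, `class` (one of `P_pse`, `P_bog`, `H_pse`,
#'   `H_bog`) and `count`; multiple rows per site/class (replicates) are
#'   summed.
#' @param loci Data frame of gene loci: `gene_id`, `chromosome`, `start`,
#'   `end` (1-based inclusive).
#' @param min_reads Minimum summed parental reads to retain a gene
#'   (default 20).
#' @return Data frame: `gene_id`, `P_pse`, `P_bog`, `H_pse`, `H_bog`,
#'   `raw_total` (parental sum used for the filter), `n_snps`.
#' @export
aggregate_gene_counts <- function(snps, site_counts, loci, min_reads = 20) {
  stopifnot_cols(snps, c("chromosome", "position"), "snps")
  stopifnot_cols(site_counts, c("chromosome", "position", "class", "count"),
                 "site_counts")
  stopifnot_cols(loci, c("gene_id", "chromosome", "start", "end"), "loci")
  if (!all(site_counts$class %in% ALLELE_CLASSES))
    stop("site_counts$class must be one of: ",
         paste(ALLELE_CLASSES, collapse = ", "))
  # map each SNP to the (unique) containing locus
  gene_of <- rep(NA_character_, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    hit <- loci$chromosome == snps$chromosome[i] &
      loci$start <= snps$position[i] & loci$end >= snps$position[i]
    n_hit <- sum(hit)
    if (n_hit > 1L)
      stop("SNP ", snps$chromosome[i], ":", snps$position[i],
           " overlaps multiple loci: ",
           paste(loci$gene_id[hit], collapse = ", "))
    if (n_hit == 1L) gene_of[i] <- loci$gene_id[hit]
  }
  keep <- !is.na(gene_of)
  if (!any(keep)) return(.empty_gene_counts())
  snp_key <- paste(snps$chromosome, snps$position, sep = "\r")[keep]
  snp_gene <- gene_of[keep]
  sc_key <- paste(site_counts$chromosome, site_counts$position, sep = "\r")
  idx <- match(sc_key, snp_key)
  sc <- site_counts[!is.na(idx), , drop = FALSE]
  sc$gene_id <- snp_gene[idx[!is.na(idx)]]
  genes <- unique(snp_gene)
  out <- data.frame(gene_id = genes, P_pse = 0, P_bog = 0, H_pse = 0,
                    H_bog = 0, stringsAsFactors = FALSE)
  for (cl in ALLELE_CLASSES) {
    part <- sc[sc$class == cl, , drop = FALSE]
    if (nrow(part)) {
      sums <- tapply(part$count, part$gene_id, sum)
      v <- as.numeric(sums[out$gene_id])
      v[is.na(v)] <- 0
      out[[cl]] <- v
    }
  }
  out$raw_total <- out$P_pse + out$P_bog
  out$n_snps <- as.integer(table(snp_gene)[out$gene_id])
  out <- out[out$raw_total >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_gene_counts <- function() {
  data.frame(gene_id = character(), P_pse = numeric(), P_bog = numeric(),
             H_pse = numeric(), H_bog = numeric(), raw_total = numeric(),
             n_snps = integer(), stringsAsFactors = FALSE)
}

#' Adjust per-gene class counts for sequencing depth
#'
#' Rescales each allele class by `min(class_totals) / class_totals[class]`
#' so all four classes are on the depth of the smallest library, rounds
#' half-up to integers, then replaces any zero with 1 so the exact tests
#' are defined for every retained gene.
#'
#' @param counts Data frame from [aggregate_gene_counts()] (columns
#'   `P_pse`, `P_bog`, `H_pse`, `H_bog`).
#' @param class_totals Named numeric vector of library totals for the four
#'   classes; all must be positive.
#' @return `counts` with the four class columns adjusted; gene order
#'   preserved.
#' @export
adjust_depth <- function(counts, class_totals) {
  stopifnot_cols(counts, ALLELE_CLASSES, "counts")
  if (!all(ALLELE_CLASSES %in% names(class_totals)))
    stop("class_totals must be named with: ",
         paste(ALLELE_CLASSES, collapse = ", "))
  if (any(!is.finite(class_totals[ALLELE_CLASSES])) ||
      any(class_totals[ALLELE_CLASSES] <= 0))
    stop("class_totals must all be positive")
  ref <- min(class_totals[ALLELE_CLASSES])
  for (cl in ALLELE_CLASSES) {
    v <- round_half_up(counts[[cl]] * ref / class_totals[[cl]])
    v[v == 0] <- 1
    counts[[cl]] <- v
  }
  counts
}
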