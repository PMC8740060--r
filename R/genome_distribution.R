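# Chromosomal distribution of target genes: densities per Mb, chi-square
# goodness-of-fit, and <=~5 kb cluster detection.

#' Closest-edge gap between two gene loci
#'
#' Loci are canonicalized to `start <= end` first; the gap is
#' `max(0, later.start - earlier.end)`, with overlapping spans giving 0.
#'
#' @param a,b Lists or one-row data frames with `chromosome`, `start`,
#'   `end`.
#' @return Non-negative integer distance in bp.
#' @export
gene_gap <- function(a, b) {
  if (a$chromosome != b$chromosome)
    stop("gene_gap is defined within one chromosome (got ",
         a$chromosome, " and ", b$chromosome, ")")
  canon <- function(x) c(min(x$start, x$end), max(x$start, x$end))
  sa <- canon(a); sb <- canon(b)
  if (sa[1] > sb[1]) { tmp <- sa; sa <- sb; sb <- tmp }
  max(0, sb[1] - sa[2])
}

#' Detect gene clusters by chaining small inter-gene gaps
#'
#' Per chromosome, loci are sorted by canonical start and adjacent genes
#' whose closest-edge gap is at most `max_gap` are chained into maximal
#' clusters; singletons are not reported.
#'
#' @param loci Locus data frame: `gene_id`, `chromosome`, `start`, `end`.
#' @param max_gap Maximum chaining gap in bp (default 5500, i.e.
#'   "approximately 5 kb" with headroom for gaps just above 5000).
#' @return Data frame with one row per cluster: `chromosome`, `n_genes`,
#'   `gene_ids` (list column) and `gaps` (list column of consecutive
#'   closest-edge gaps).
#' @export
detect_clusters <- function(loci, max_gap = 5500) {
  stopifnot_cols(loci, c("gene_id", "chromosome", "start", "end"), "loci")
  if (anyDuplicated(loci$gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(loci$gene_id[duplicated(loci$gene_id)]),
               collapse = ", "))
  out <- list()
  lo <- pmin(loci$start, loci$end)
  hi <- pmax(loci$start, loci$end)
  loci$start <- lo; loci$end <- hi
  for (ch in unique(loci$chromosome)) {
    part <- loci[loci$chromosome == ch, , drop = FALSE]
    part <- part[order(part$start, part$end), , drop = FALSE]
    if (nrow(part) < 2L) next
    gaps <- vapply(seq_len(nrow(part) - 1L), function(i) {
      gene_gap(part[i, ], part[i + 1L, ])
    }, numeric(1))
    # chain genes across sub-threshold gaps into maximal runs
    run_id <- cumsum(c(0, gaps > max_gap))
    for (r in unique(run_id)) {
      members <- which(run_id == r)
      if (length(members) < 2L) next
      out[[length(out) + 1L]] <- list(
        chromosome = ch,
        gene_ids = part$gene_id[members],
        gaps = gaps[members[-length(members)]])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chromosome = character(), n_genes = integer(),
                      gene_ids = I(list()), gaps = I(list()),
                      stringsAsFactors = FALSE))
  }
  data.frame(chromosome = vapply(out, `[[`, character(1), "chromosome"),
             n_genes = vapply(out, function(x) length(x$gene_ids),
                              integer(1)),
             gene_ids = I(lapply(out, `[[`, "gene_ids")),
             gaps = I(lapply(out, `[[`, "gaps")),
             stringsAsFactors = FALSE)
}

#' Per-chromosome target density (genes per Mb)
#'
#' Density is `count / length_mb`, reported rounded half-up to two
#' decimals, with an aggregate `autosomes` entry pooling all non-X
#' chromosomes.  Full precision is kept in `density_raw`.
#'
#' @param counts Named integer vector of target counts per chromosome.
#' @param lengths_mb Named numeric vector of chromosome lengths in Mb.
#' @return Data frame: `chromosome`, `n_targets`, `length_mb`,
#'   `density_raw`, `density`.
#' @export
chromosome_density <- function(counts, lengths_mb) {
  miss <- setdiff(names(counts), names(lengths_mb))
  if (length(miss))
    stop("missing length for chromosome(s): ", paste(miss, collapse = ", "))
  if (any(lengths_mb[names(counts)] <= 0))
    stop("chromosome lengths must be positive")
  chroms <- names(counts)
  n <- as.numeric(counts)
  len <- as.numeric(lengths_mb[chroms])
  auto <- chroms != "X"
  out <- data.frame(
    chromosome = c(chroms, "autosomes"),
    n_targets = c(n, sum(n[auto])),
    length_mb = c(len, sum(len[auto])),
    stringsAsFactors = FALSE)
  out$density_raw <- out$n_targets / out$length_mb
  out$density <- round_half_up(out$density_raw, 2)
  out
}

#' Chi-square goodness-of-fit test for the chromosomal distribution
#'
#' Pearson goodness-of-fit of observed target counts against expected
#' counts proportional to chromosome length (`length_proportional`) or
#' equal across classes (`uniform`), per chromosome or with all autosomes
#' pooled against the X.
#'
#' @param observed Named integer vector of target counts per chromosome.
#' @param lengths_mb Named numeric vector of chromosome lengths in Mb.
#' @param expectation `"length_proportional"` or `"uniform"`.
#' @param grouping `"per_chromosome"` or `"x_vs_autosomes"`.
#' @return List: `statistic`, `df`, `p`, `observed`, `expected`.
#' @export
chisq_distribution_test <- function(observed, lengths_mb,
                                    expectation = c("length_proportional",
                                                    "uniform"),
                                    grouping = c("per_chromosome",
                                                 "x_vs_autosomes")) {
  expectation <- match.arg(expectation)
  grouping <- match.arg(grouping)
  miss <- setdiff(names(observed), names(lengths_mb))
  if (length(miss))
    stop("missing length for chromosome(s): ", paste(miss, collapse = ", "))
  obs <- as.numeric(observed)
  len <- as.numeric(lengths_mb[names(observed)])
  if (grouping == "x_vs_autosomes") {
    is_x <- names(observed) == "X"
    if (!any(is_x) || all(is_x))
      stop("x_vs_autosomes grouping needs an X and at least one autosome")
    obs <- c(X = sum(obs[is_x]), autosomes = sum(obs[!is_x]))
    len <- c(X = sum(len[is_x]), autosomes = sum(len[!is_x]))
  }
  if (length(obs) < 2L) stop("need >= 2 classes after grouping")
  prop <- if (expectation == "length_proportional") len / sum(len) else
    rep(1 / length(obs), length(obs))
  expected <- sum(obs) * prop
  if (any(expected <= 0)) stop("degenerate expectation: expected count of 0")
  ct <- suppressWarnings(stats::chisq.test(obs, p = prop))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), observed = obs, expected = expected)
}
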