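# Ground-truth simulators for every pipeline stage.
#
# Generative model for allele-specific counts: a per-gene baseline mean mu,
# a cis effect c and a trans effect t.  Cis effects act on one allele only;
# trans effects act on whichever alleles sit in the affected cellular
# environment, so in the parents the pse/bog expression ratio is c*t while
# in a hybrid both alleles share one trans environment and the allelic
# ratio is c alone.  Class totals are negative-binomial, the allele split
# binomial — matching the binomial tests applied downstream.

# Per-gene substream: derived seeds stay below 2^31 - 1 and depend only on
# the gene index, so per-gene draws are stable under reordering.
.gene_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647L)
}

#' Build and validate a simulation configuration
#'
#' @param n_genes Number of genes to simulate.
#' @param category_proportions Named fractions over the six regulatory
#'   categories (must sum to 1); genes are allocated deterministically by
#'   largest remainder so the realized composition matches exactly.
#' @param cis_fold_range,trans_fold_range Fold-change magnitude ranges
#'   (>= 1) from which |effects| are drawn log-uniformly; the direction
#'   (>1 vs <1) is chosen with probability 1/2 per gene.
#' @param base_mean_range Range for the per-gene baseline mean mu
#'   (expected reads per allele class), drawn log-uniformly.
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`).
#' @param n_replicates Replicates per class, summed by the ASE stage.
#' @param library_depth_factors Per-replicate depth multipliers.
#' @param seed Integer seed; the single source of randomness.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes,
                              category_proportions = c(
                                conserved = 1/6, cis_only = 1/6,
                                trans_only = 1/6, cis_and_trans = 1/6,
                                compensatory = 1/6, ambiguous = 1/6),
                              cis_fold_range = c(4, 4),
                              trans_fold_range = c(4, 4),
                              base_mean_range = c(500, 500),
                              dispersion = 0.05,
                              n_replicates = 3,
                              library_depth_factors = rep(1, n_replicates),
                              seed = 1L) {
  if (n_genes < 0 || n_genes != round(n_genes))
    stop("n_genes must be a non-negative integer")
  props <- category_proportions[category_proportions > 0]
  if (!all(names(props) %in% REG_CATEGORIES))
    stop("unknown category in proportions: ",
         paste(setdiff(names(props), REG_CATEGORIES), collapse = ", "))
  if (abs(sum(category_proportions) - 1) > 1e-9)
    stop("category_proportions must sum to 1")
  for (rng in list(cis_fold_range, trans_fold_range, base_mean_range)) {
    if (length(rng) != 2L || any(!is.finite(rng)) || any(rng <= 0) ||
        rng[1] > rng[2])
      stop("ranges must be positive with lower <= upper")
  }
  if (any(c(cis_fold_range, trans_fold_range) < 1))
    stop("fold ranges give |effect| magnitudes and must be >= 1")
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("dispersion must be > 0")
  if (n_replicates < 1 || n_replicates != round(n_replicates))
    stop("n_replicates must be a positive integer")
  if (length(library_depth_factors) != n_replicates ||
      any(library_depth_factors <= 0))
    stop("library_depth_factors must be ", n_replicates, " positive values")
  structure(list(n_genes = as.integer(n_genes),
                 category_proportions = category_proportions,
                 cis_fold_range = cis_fold_range,
                 trans_fold_range = trans_fold_range,
                 base_mean_range = base_mean_range,
                 dispersion = dispersion,
                 n_replicates = as.integer(n_replicates),
                 library_depth_factors = library_depth_factors,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder allocation of n items to the named proportions
.allocate_categories <- function(n, proportions) {
  props <- proportions[proportions > 0]
  raw <- n * props
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  rep(names(k), times = k)
}

.runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

# draw (c, t) consistent with a category's definition
.effects_for_category <- function(category, cis_fold_range, trans_fold_range) {
  flip <- function(f) if (stats::runif(1) < 0.5) f else 1 / f
  c_eff <- t_eff <- 1
  if (category %in% c("cis_only", "cis_and_trans", "compensatory"))
    c_eff <- flip(.runif_log(1, cis_fold_range))
  if (category %in% c("trans_only", "cis_and_trans"))
    t_eff <- flip(.runif_log(1, trans_fold_range))
  if (category == "compensatory") t_eff <- 1 / c_eff
  if (category == "cis_and_trans" && isTRUE(all.equal(t_eff, 1 / c_eff)))
    t_eff <- 1 / t_eff    # avoid collapsing onto the compensatory manifold
  c(c = c_eff, t = t_eff)
}

.rnbinom_mean <- function(n, mu, dispersion) {
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate parent-of-origin allele counts with known regulatory truth
#'
#' Per gene: baseline mean `mu`, cis effect `c` and trans effect `t` drawn
#' per the gene's category.  For each replicate the parental class total is
#' negative-binomial with mean `mu * (1 + c*t) * depth`, split binomially
#' with pse probability `c*t / (1 + c*t)`; the hybrid total has mean
#' `mu * (1 + c) * depth` and pse-allele probability `c / (1 + c)`.
#' Replicates are summed into one `GeneAlleleCounts` row per gene.
#'
#' Genes of truth category "ambiguous" are given the cis_and_trans effect
#' structure but no defined flag pattern of their own; they exist so
#' classifier error on boundary patterns can be exercised.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (gene_id, P_pse, P_bog, H_pse, H_bog,
#'   raw_total, n_snps) and `truth` (gene_id, true_category, c, t, mu).
#' @export
simulate_regulatory_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must come from simulation_config()")
  cats <- .allocate_categories(config$n_genes, config$category_proportions)
  n <- length(cats)
  counts <- data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
                       P_pse = 0, P_bog = 0, H_pse = 0, H_bog = 0,
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = counts$gene_id,
                      true_category = cats, c = 1, t = 1, mu = 0,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    set.seed(.gene_seed(config$seed, i))
    mu <- .runif_log(1, config$base_mean_range)
    eff_cat <- if (cats[i] == "ambiguous") "cis_and_trans" else cats[i]
    eff <- .effects_for_category(eff_cat, config$cis_fold_range,
                                 config$trans_fold_range)
    truth$c[i] <- eff["c"]; truth$t[i] <- eff["t"]; truth$mu[i] <- mu
    ct <- eff["c"] * eff["t"]
    p_par <- ct / (1 + ct)
    p_hyb <- eff["c"] / (1 + eff["c"])
    for (r in seq_len(config$n_replicates)) {
      depth <- config$library_depth_factors[r]
      tot_p <- .rnbinom_mean(1, mu * (1 + ct) * depth, config$dispersion)
      tot_h <- .rnbinom_mean(1, mu * (1 + eff["c"]) * depth,
                             config$dispersion)
      pse_p <- stats::rbinom(1, tot_p, p_par)
      pse_h <- stats::rbinom(1, tot_h, p_hyb)
      counts$P_pse[i] <- counts$P_pse[i] + pse_p
      counts$P_bog[i] <- counts$P_bog[i] + (tot_p - pse_p)
      counts$H_pse[i] <- counts$H_pse[i] + pse_h
      counts$H_bog[i] <- counts$H_bog[i] + (tot_h - pse_h)
    }
  }
  counts$raw_total <- counts$P_pse + counts$P_bog
  counts$n_snps <- NA_integer_
  list(counts = counts, truth = truth)
}

#' Simulate non-overlapping gene loci with optional planted clusters
#'
#' Background loci are spread over the chromosomes proportionally to
#' length, with inter-gene gaps of at least 20 kb so no background pair
#' forms a sub-threshold cluster.  Each planted cluster adds one adjacent
#' gene pair whose closest-edge gap equals the requested gap exactly.
#'
#' @param n_genes Number of background loci (planted pairs are additional).
#' @param chromosome_lengths Named vector of chromosome lengths in bp.
#' @param planted_clusters List of `list(chromosome =, gap_bp =)` entries.
#' @param seed Integer seed.
#' @return Locus data frame: `gene_id`, `chromosome`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
simulate_gene_annotation <- function(n_genes, chromosome_lengths,
                                     planted_clusters = list(),
                                     seed = 1L) {
  if (n_genes < 0 || n_genes != round(n_genes))
    stop("n_genes must be a non-negative integer")
  if (length(chromosome_lengths) == 0 || any(chromosome_lengths <= 0))
    stop("chromosome lengths must be positive")
  for (pc in planted_clusters) {
    if (!pc$chromosome %in% names(chromosome_lengths))
      stop("planted cluster names unknown chromosome ", pc$chromosome)
    if (pc$gap_bp < 0) stop("planted gaps must be >= 0")
  }
  if (n_genes == 0 && length(planted_clusters) == 0) {
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  chroms <- names(chromosome_lengths)
  n_per <- .allocate_categories(
    n_genes, chromosome_lengths / sum(chromosome_lengths))
  rows <- list()
  gid <- 0
  for (ch in chroms) {
    n_ch <- sum(n_per == ch)
    planted <- Filter(function(p) p$chromosome == ch, planted_clusters)
    pos <- 1
    emit <- function(len) {
      gid <<- gid + 1
      r <- data.frame(gene_id = sprintf("locus%04d", gid), chromosome = ch,
                      start = pos, end = pos + len - 1,
                      strand = sample(c("+", "-"), 1),
                      stringsAsFactors = FALSE)
      pos <<- pos + len
      r
    }
    advance <- function(gap) pos <<- pos + gap
    for (p in planted) {
      advance(sample(20000:80000, 1))
      rows[[length(rows) + 1]] <- emit(sample(500:5000, 1))
      # pos already sits one base past the previous end, so the next
      # start lands exactly gap_bp after it
      advance(p$gap_bp - 1L)
      rows[[length(rows) + 1]] <- emit(sample(500:5000, 1))
    }
    for (k in seq_len(n_ch)) {
      advance(sample(20000:80000, 1))
      rows[[length(rows) + 1]] <- emit(sample(500:5000, 1))
    }
    if (pos - 1 > chromosome_lengths[[ch]])
      stop("requested loci exceed the capacity of chromosome ", ch,
           " (need ", pos - 1, " bp, have ", chromosome_lengths[[ch]], ")")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a two-subspecies alignment panel with planted sites
#'
#' Starts from one random master sequence shared by all strains, then
#' plants `n_fixed` columns where the subspecies carry disjoint single
#' residues, `n_poly_a` columns segregating among the pse strains only and
#' `n_poly_b` among the bog strains only, at distinct positions.
#'
#' @param n_strains_a,n_strains_b Strains per subspecies (pse / bog).
#' @param length Alignment length in columns.
#' @param n_fixed,n_poly_a,n_poly_b Numbers of planted site columns.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param seed Integer seed.
#' @return List with `panel` (an [alignment_panel()]) and `truth`
#'   (`fixed`, `poly_a`, `poly_b` planted column positions, sorted).
#' @export
simulate_alignment_panel <- function(n_strains_a, n_strains_b, length,
                                     n_fixed = 0, n_poly_a = 0, n_poly_b = 0,
                                     alphabet = c("nucleotide", "protein"),
                                     seed = 1L) {
  alphabet <- match.arg(alphabet)
  if (n_strains_a < 1 || n_strains_b < 1)
    stop("need at least one strain per subspecies")
  if (n_poly_a > 0 && n_strains_a < 2)
    stop("polymorphism within pse needs >= 2 pse strains")
  if (n_poly_b > 0 && n_strains_b < 2)
    stop("polymorphism within bog needs >= 2 bog strains")
  n_sites <- n_fixed + n_poly_a + n_poly_b
  if (n_sites > length)
    stop("site budget (", n_sites, ") exceeds alignment length (", length, ")")
  letters_ <- if (alphabet == "nucleotide") c("A", "C", "G", "T") else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(as.integer(seed))
  master <- sample(letters_, length, replace = TRUE)
  n_strain <- n_strains_a + n_strains_b
  mat <- matrix(rep(master, each = n_strain), nrow = n_strain)
  subsp <- c(rep("pse", n_strains_a), rep("bog", n_strains_b))
  idx_a <- which(subsp == "pse")
  idx_b <- which(subsp == "bog")
  sites <- sample(length, n_sites)
  fixed <- sort(sites[seq_len(n_fixed)])
  poly_a <- sort(sites[n_fixed + seq_len(n_poly_a)])
  poly_b <- sort(sites[n_fixed + n_poly_a + seq_len(n_poly_b)])
  for (col in fixed) {
    two <- sample(letters_, 2)
    mat[idx_a, col] <- two[1]
    mat[idx_b, col] <- two[2]
  }
  plant_poly <- function(col, idx_seg, idx_mono) {
    two <- sample(letters_, 2)
    split_at <- sample(seq_len(base::length(idx_seg) - 1), 1)
    mat[idx_seg, col] <<- c(rep(two[1], split_at),
                            rep(two[2], base::length(idx_seg) - split_at))
    mat[idx_mono, col] <<- two[1]   # monomorphic, shared with one allele
  }
  for (col in poly_a) plant_poly(col, idx_a, idx_b)
  for (col in poly_b) plant_poly(col, idx_b, idx_a)
  strains <- c(sprintf("pse_%02d", seq_len(n_strains_a)),
               sprintf("bog_%02d", seq_len(n_strains_b)))
  rownames(mat) <- strains
  panel <- alignment_panel(mat, subsp, alphabet = alphabet)
  list(panel = panel,
       truth = list(fixed = fixed, poly_a = poly_a, poly_b = poly_b))
}

INHERITANCE_MODES <- c("transgressive_up", "transgressive_down", "additive",
                       "non_differential")

#' Simulate replicate count matrices with known inheritance modes
#'
#' Means by mode (baseline `depth`): non_differential — all three groups at
#' `depth`; additive — parents at `depth * fold` and `depth`, hybrid at
#' their midpoint; transgressive_up — parents at `depth`, hybrid at
#' `depth * fold` (= fold times the larger parental mean);
#' transgressive_down — parents at `depth`, hybrid at `depth / fold`.
#' Counts are negative-binomial per replicate.
#'
#' @param n_genes Number of genes.
#' @param mode_proportions Named fractions over the four modes (sum to 1).
#' @param fold Fold separation (>= 1) used by the non-null modes.
#' @param depth Baseline mean count.
#' @param dispersion Negative-binomial overdispersion.
#' @param n_replicates Replicates per group.
#' @param seed Integer seed.
#' @return List with matrices `parent_a`, `parent_b`, `hybrid` (genes x
#'   replicates) and `truth` (gene_id, true_mode).
#' @export
simulate_inheritance_counts <- function(n_genes, mode_proportions = c(
                                          transgressive_up = 0.25,
                                          transgressive_down = 0.25,
                                          additive = 0.25,
                                          non_differential = 0.25),
                                        fold = 4, depth = 500,
                                        dispersion = 0.05,
                                        n_replicates = 3, seed = 1L) {
  if (!all(names(mode_proportions) %in% INHERITANCE_MODES))
    stop("unknown inheritance mode in proportions")
  if (abs(sum(mode_proportions) - 1) > 1e-9)
    stop("mode_proportions must sum to 1")
  if (fold < 1) stop("fold must be >= 1")
  modes <- .allocate_categories(n_genes, mode_proportions)
  n <- length(modes)
  pa <- pb <- hy <- matrix(0, nrow = n, ncol = n_replicates,
                           dimnames = list(sprintf("gene%05d", seq_len(n)),
                                           sprintf("rep%d", seq_len(n_replicates))))
  for (i in seq_len(n)) {
    set.seed(.gene_seed(seed, i))
    mu <- switch(modes[i],
      non_differential  = c(a = depth, b = depth, h = depth),
      additive          = c(a = depth * fold, b = depth,
                            h = depth * (1 + fold) / 2),
      transgressive_up  = c(a = depth, b = depth, h = depth * fold),
      transgressive_down = c(a = depth, b = depth, h = depth / fold))
    pa[i, ] <- .rnbinom_mean(n_replicates, mu["a"], dispersion)
    pb[i, ] <- .rnbinom_mean(n_replicates, mu["b"], dispersion)
    hy[i, ] <- .rnbinom_mean(n_replicates, mu["h"], dispersion)
  }
  list(parent_a = pa, parent_b = pb, hybrid = hy,
       truth = data.frame(gene_id = rownames(pa), true_mode = modes,
                          stringsAsFactors = FALSE))
}

#' Split simulated gene counts into per-SNP site tables
#'
#' Plants `snps_per_gene` diagnostic SNP positions inside each gene locus
#' and distributes the gene's four class totals multinomially across its
#' SNPs, yielding (i) parental variant observations suitable for
#' [call_fixed_snps()] and (ii) per-site class counts suitable for
#' [aggregate_gene_counts()], which recover the input totals exactly.
#'
#' @param counts Gene allele-count table (from
#'   [simulate_regulatory_counts()]).
#' @param loci Locus table covering the same gene_ids.
#' @param snps_per_gene SNPs planted per gene (default 2).
#' @param seed Integer seed.
#' @return List with `observations`, `site_counts` and `snps` (the planted
#'   truth: chromosome, position, allele_pse, allele_bog, gene_id).
#' @export
simulate_snp_tables <- function(counts, loci, snps_per_gene = 2, seed = 1L) {
  stopifnot_cols(counts, c("gene_id", ALLELE_CLASSES), "counts")
  stopifnot_cols(loci, c("gene_id", "chromosome", "start", "end"), "loci")
  if (!all(counts$gene_id %in% loci$gene_id))
    stop("every gene in counts needs a locus")
  obs <- list(); site <- list(); snps <- list()
  for (i in seq_len(nrow(counts))) {
    g <- counts$gene_id[i]
    loc <- loci[loci$gene_id == g, ][1, ]
    set.seed(.gene_seed(seed, i))
    span <- loc$end - loc$start + 1
    k <- min(snps_per_gene, span)
    positions <- sort(sample(loc$start:loc$end, k))
    alleles <- replicate(k, sample(c("A", "C", "G", "T"), 2),
                         simplify = FALSE)
    share <- stats::rmultinom(1, 1000, rep(1 / k, k))[, 1] / 1000
    for (cl in ALLELE_CLASSES) {
      tot <- counts[[cl]][i]
      per_site <- if (k == 1) tot else
        stats::rmultinom(1, tot, share)[, 1]
      site[[length(site) + 1]] <- data.frame(
        chromosome = loc$chromosome, position = positions,
        class = cl, count = as.numeric(per_site),
        stringsAsFactors = FALSE)
    }
    for (j in seq_len(k)) {
      snps[[length(snps) + 1]] <- data.frame(
        chromosome = loc$chromosome, position = positions[j],
        allele_pse = alleles[[j]][1], allele_bog = alleles[[j]][2],
        gene_id = g, stringsAsFactors = FALSE)
    }
  }
  site_counts <- do.call(rbind, site)
  snps <- do.call(rbind, snps)
  # parental observations: each subspecies reports its own allele with the
  # corresponding parental class count at that site
  par_rows <- site_counts[site_counts$class %in% c("P_pse", "P_bog"), ]
  key <- paste(par_rows$chromosome, par_rows$position, sep = "\r")
  snp_key <- paste(snps$chromosome, snps$position, sep = "\r")
  m <- match(key, snp_key)
  observations <- data.frame(
    chromosome = par_rows$chromosome,
    position = par_rows$position,
    sample = ifelse(par_rows$class == "P_pse", "parent_pse", "parent_bog"),
    subspecies = ifelse(par_rows$class == "P_pse", "pse", "bog"),
    allele = ifelse(par_rows$class == "P_pse",
                    snps$allele_pse[m], snps$allele_bog[m]),
    count = par_rows$count,
    stringsAsFactors = FALSE)
  list(observations = observations, site_counts = site_counts, snps = snps)
}
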