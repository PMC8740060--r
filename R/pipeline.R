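# End-to-end orchestration over the synthetic generators and analysis
# stages, with a machine-readable run manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all result tables.
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Character vector of stages to run, in dependency order
#'   from `simulate`, `ase`, `classify`, `inherit`, `distribution`,
#'   `noncoding`, `protein`.
#' @param n_genes Genes for the regulatory simulation.
#' @param alpha Classification q-value cutoff (default 0.005).
#' @param de_alpha,lfc_threshold Inheritance stand-in test parameters.
#' @param min_support,min_reads ASE filter thresholds.
#' @param max_gap Cluster chaining threshold in bp.
#' @param upstream_ladder Upstream window extents for the noncoding screen.
#' @param chromosome_lengths Named bp lengths for the simulated genome.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 42L,
                            stages = c("simulate", "ase", "classify",
                                       "inherit", "distribution",
                                       "noncoding", "protein"),
                            n_genes = 120L,
                            alpha = 0.005,
                            de_alpha = 0.05,
                            lfc_threshold = 1,
                            min_support = 3,
                            min_reads = 20,
                            max_gap = 5500,
                            upstream_ladder = c(500, 1000, 2000, 3000),
                            chromosome_lengths = c(X = 4.95e7, `2` = 3.08e7,
                                                   `3` = 1.98e7,
                                                   `4` = 2.72e7)) {
  known <- c("simulate", "ase", "classify", "inherit", "distribution",
             "noncoding", "protein")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (any(c(alpha, de_alpha, lfc_threshold, min_support, min_reads,
            max_gap) <= 0))
    stop("thresholds must be positive")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = intersect(known, stages), n_genes = n_genes,
                 alpha = alpha, de_alpha = de_alpha,
                 lfc_threshold = lfc_threshold,
                 min_support = min_support, min_reads = min_reads,
                 max_gap = max_gap, upstream_ladder = upstream_ladder,
                 chromosome_lengths = chromosome_lengths),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (is.null(y$out_dir)) stop(path, ": config must set out_dir")
  if (!is.null(y$chromosome_lengths))
    y$chromosome_lengths <- unlist(y$chromosome_lengths)
  do.call(pipeline_config, y)
}

.log_stage <- function(stage, ...) {
  message("[cistrans] ", stage, ": ", ...)
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order on synthetic inputs
#' generated under the configured seed, writes every result table as TSV
#' into `config$out_dir`, and returns (and writes) a run manifest with
#' parameters and per-file MD5 digests.  The same config and seed yield
#' identical manifest digests.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list: parameters, files, digests).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must come from pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  need <- function(stage, file) {
    if (!file.exists(path(file)))
      stop("stage '", stage, "' needs missing upstream output '", file,
           "'; enable the producing stage or provide the file")
  }
  stages <- config$stages

  if ("simulate" %in% stages) {
    sim <- simulate_regulatory_counts(simulation_config(
      n_genes = config$n_genes, seed = config$seed))
    loci <- simulate_gene_annotation(
      config$n_genes,
      config$chromosome_lengths,
      planted_clusters = list(list(chromosome = "X", gap_bp = 1251),
                              list(chromosome = "2", gap_bp = 5202)),
      seed = config$seed)
    sim_loci <- loci[seq_len(nrow(sim$counts)), , drop = FALSE]
    sim_loci$gene_id <- sim$counts$gene_id
    snp_tabs <- simulate_snp_tables(sim$counts, sim_loci,
                                    seed = config$seed)
    write_tsv_table(sim$counts, path("sim_gene_allele_counts.tsv"))
    write_tsv_table(sim$truth, path("sim_truth.tsv"))
    write_loci_bed(loci, path("sim_loci.bed.tsv"))
    write_loci_bed(sim_loci, path("sim_gene_loci.bed.tsv"))
    write_tsv_table(snp_tabs$observations, path("sim_variant_obs.tsv"))
    write_tsv_table(snp_tabs$site_counts, path("sim_site_counts.tsv"))
    write_tsv_table(snp_tabs$snps, path("sim_snps_truth.tsv"))
    inh <- simulate_inheritance_counts(config$n_genes, seed = config$seed)
    for (nm in c("parent_a", "parent_b", "hybrid")) {
      m <- as.data.frame(inh[[nm]])
      m <- cbind(gene_id = rownames(inh[[nm]]), m)
      write_tsv_table(m, path(paste0("sim_counts_", nm, ".tsv")))
    }
    write_tsv_table(inh$truth, path("sim_inheritance_truth.tsv"))
    pan_nt <- simulate_alignment_panel(31, 5, 3200, n_fixed = 6,
                                       n_poly_a = 4, n_poly_b = 2,
                                       alphabet = "nucleotide",
                                       seed = config$seed)
    write_alignment_panel(pan_nt$panel, path("sim_panel_upstream.fasta"))
    pan_aa <- simulate_alignment_panel(31, 5, 199, n_fixed = 7,
                                       n_poly_a = 3, n_poly_b = 1,
                                       alphabet = "protein",
                                       seed = config$seed + 1L)
    write_alignment_panel(pan_aa$panel, path("sim_panel_protein.fasta"))
    .log_stage("simulate", nrow(sim$counts), " genes, ",
               nrow(loci), " loci, 2 panels")
  }

  if ("ase" %in% stages) {
    need("ase", "sim_variant_obs.tsv")
    obs <- read_tsv_table(path("sim_variant_obs.tsv"),
                          required = c("chromosome", "position", "sample",
                                       "subspecies", "allele", "count"),
                          numeric_cols = c("position", "count"))
    site_counts <- read_tsv_table(path("sim_site_counts.tsv"),
                                  required = c("chromosome", "position",
                                               "class", "count"),
                                  numeric_cols = c("position", "count"))
    gene_loci <- read_loci_bed(path("sim_gene_loci.bed.tsv"))
    snps <- call_fixed_snps(obs, min_support = config$min_support)
    counts <- aggregate_gene_counts(snps, site_counts, gene_loci,
                                    min_reads = config$min_reads)
    # simulated libraries are sequenced to equal depth, so the adjustment
    # is an identity rescale (plus the 0 -> 1 substitution); real runs
    # should pass the per-class library totals here
    totals <- stats::setNames(rep(1e6, 4), ALLELE_CLASSES)
    adjusted <- adjust_depth(counts, totals)
    write_tsv_table(snps, path("ase_fixed_snps.tsv"))
    write_tsv_table(adjusted, path("ase_gene_counts.tsv"))
    .log_stage("ase", nrow(snps), " fixed SNPs -> ", nrow(adjusted),
               " genes retained")
  }

  if ("classify" %in% stages) {
    need("classify", "ase_gene_counts.tsv")
    counts <- read_tsv_table(path("ase_gene_counts.tsv"),
                             required = c("gene_id", ALLELE_CLASSES),
                             numeric_cols = ALLELE_CLASSES)
    res <- classify_regulatory_divergence(counts, alpha = config$alpha)
    merged <- merge(res$tests, res$calls, by = "gene_id", sort = FALSE)
    write_tsv_table(merged, path("classify_results.tsv"))
    summ <- summarize_cis_effects(res$calls)
    write_tsv_table(
      data.frame(category = names(summ$counts),
                 n = as.integer(summ$counts),
                 stringsAsFactors = FALSE),
      path("classify_summary.tsv"))
    .log_stage("classify", nrow(merged), " genes, cis-effect fraction ",
               sprintf("%.3f", summ$cis_effect_fraction))
  }

  if ("inherit" %in% stages) {
    need("inherit", "sim_counts_hybrid.tsv")
    mats <- lapply(c("parent_a", "parent_b", "hybrid"), function(nm) {
      df <- read_tsv_table(path(paste0("sim_counts_", nm, ".tsv")),
                           required = "gene_id")
      m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
      storage.mode(m) <- "numeric"
      rownames(m) <- df$gene_id
      m
    })
    calls <- classify_inheritance_matrix(mats[[1]], mats[[2]], mats[[3]],
                                         alpha = config$de_alpha,
                                         lfc_threshold = config$lfc_threshold)
    write_tsv_table(calls, path("inheritance_calls.tsv"))
    .log_stage("inherit", nrow(calls), " genes classified")
  }

  if ("distribution" %in% stages) {
    need("distribution", "sim_loci.bed.tsv")
    loci <- read_loci_bed(path("sim_loci.bed.tsv"))
    counts <- table(loci$chromosome)
    lengths_mb <- config$chromosome_lengths / 1e6
    dens <- chromosome_density(
      stats::setNames(as.integer(counts), names(counts)), lengths_mb)
    chisq <- chisq_distribution_test(
      stats::setNames(as.integer(counts), names(counts)), lengths_mb)
    clusters <- detect_clusters(loci, max_gap = config$max_gap)
    write_tsv_table(dens, path("distribution_density.tsv"))
    write_tsv_table(
      data.frame(statistic = chisq$statistic, df = chisq$df, p = chisq$p),
      path("distribution_chisq.tsv"))
    write_tsv_table(clusters, path("distribution_clusters.tsv"))
    .log_stage("distribution", nrow(dens) - 1L, " chromosomes, ",
               nrow(clusters), " clusters")
  }

  if ("noncoding" %in% stages) {
    need("noncoding", "sim_panel_upstream.fasta")
    panel <- read_alignment_panel(path("sim_panel_upstream.fasta"),
                                  "nucleotide")
    tss_col <- ncol(panel$mat) - 200L + 1L
    ladder <- window_ladder_counts(panel, tss_col,
                                   upstream_ladder = config$upstream_ladder)
    full <- extract_window(panel, tss_col,
                           max(config$upstream_ladder), 200)
    sites <- data.frame(site_id = c("adf1_site1", "adf1_site2"),
                        start = c(-450L, -120L), end = c(-436L, -106L),
                        stringsAsFactors = FALSE)
    motif <- motif_site_divergence(full, sites)
    write_tsv_table(ladder, path("noncoding_window_counts.tsv"))
    write_tsv_table(motif, path("noncoding_motif_sites.tsv"))
    .log_stage("noncoding", "window ladder ",
               paste(ladder$fixed, collapse = "/"), " fixed changes")
  }

  if ("protein" %in% stages) {
    need("protein", "sim_panel_protein.fasta")
    panel <- read_alignment_panel(path("sim_panel_protein.fasta"), "protein")
    subs <- find_fixed_aa_substitutions(panel)
    domains <- data.frame(domain = "MADF", start = 20L, end = 95L,
                          stringsAsFactors = FALSE)
    annotated <- substitutions_in_domains(subs, domains,
                                          protein_length = ncol(panel$mat))
    haps <- diagnostic_haplotypes(panel)
    write_tsv_table(annotated$substitutions, path("protein_substitutions.tsv"))
    write_tsv_table(
      data.frame(separating = haps$separating,
                 positions = paste(haps$positions, collapse = ",")),
      path("protein_haplotypes.tsv"))
    .log_stage("protein", nrow(subs), " fixed substitutions, separating = ",
               haps$separating)
  }

  files <- sort(list.files(config$out_dir, full.names = FALSE))
  files <- setdiff(files, "run_manifest.json")
  digests <- tools::md5sum(file.path(config$out_dir, files))
  names(digests) <- files
  manifest <- list(
    parameters = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    r_version = as.character(getRversion()),
    files = as.list(digests))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
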