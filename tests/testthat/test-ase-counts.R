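obs_row <- function(pos, sample, sub, allele, count, chrom = "chr1") {
  data.frame(chromosome = chrom, position = pos, sample = sample,
             subspecies = sub, allele = allele, count = count,
             stringsAsFactors = FALSE)
}

test_that("fixed SNP calling applies the single-allele and support rules", {
  obs <- rbind(
    obs_row(100, "p1", "pse", "A", 5), obs_row(100, "b1", "bog", "G", 4),
    obs_row(200, "p1", "pse", "A", 5), obs_row(200, "b1", "bog", "A", 9),
    obs_row(300, "p1", "pse", "A", 2), obs_row(300, "b1", "bog", "G", 4),
    obs_row(400, "p1", "pse", "A", 6), obs_row(400, "p2", "pse", "C", 3),
    obs_row(400, "b1", "bog", "G", 8))
  snps <- call_fixed_snps(obs)
  # only site 100 passes: 200 shares the allele, 300 lacks support,
  # 400 is polymorphic within pse
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$position, 100)
  expect_equal(snps$allele_pse, "A")
  expect_equal(snps$allele_bog, "G")
})

test_that("support is summed across a subspecies' samples", {
  obs <- rbind(obs_row(10, "p1", "pse", "A", 2), obs_row(10, "p2", "pse", "A", 1),
               obs_row(10, "b1", "bog", "T", 3))
  expect_equal(nrow(call_fixed_snps(obs)), 1L)
  expect_equal(call_fixed_snps(obs)$support_pse, 3)
  expect_equal(nrow(call_fixed_snps(obs, min_support = 4)), 0L)
})

test_that("duplicate observation records are an input error", {
  obs <- rbind(obs_row(10, "p1", "pse", "A", 2), obs_row(10, "p1", "pse", "A", 5),
               obs_row(10, "b1", "bog", "T", 3))
  expect_error(call_fixed_snps(obs), "duplicate")
})

test_that("raising min_support never increases the SNP count", {
  set.seed(5)
  obs <- do.call(rbind, lapply(1:40, function(i) {
    rbind(obs_row(i * 10, "p1", "pse", sample(c("A", "C"), 1), rpois(1, 4)),
          obs_row(i * 10, "b1", "bog", sample(c("G", "T"), 1), rpois(1, 4)))
  }))
  n_prev <- Inf
  for (ms in 1:6) {
    n <- nrow(call_fixed_snps(obs, min_support = ms))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("gene aggregation sums sites and applies the >= 20 read filter", {
  loci <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
                     start = c(1, 1000), end = c(500, 1500),
                     stringsAsFactors = FALSE)
  snps <- data.frame(chromosome = "chr1", position = c(100, 200, 1200),
                     stringsAsFactors = FALSE)
  site <- function(pos, class, count)
    data.frame(chromosome = "chr1", position = pos, class = class,
               count = count, stringsAsFactors = FALSE)
  sc <- rbind(site(100, "H_pse", 7), site(200, "H_pse", 8),
              site(100, "P_pse", 12), site(200, "P_pse", 5),
              site(100, "P_bog", 3),
              site(1200, "P_pse", 10), site(1200, "P_bog", 9),
              site(1200, "H_bog", 30))
  res <- aggregate_gene_counts(snps, sc, loci)
  # g1: parental sum 20 retained, hybrid pse 7 + 8 = 15
  # g2: parental sum 19 dropped at the boundary
  expect_equal(res$gene_id, "g1")
  expect_equal(res$H_pse, 15)
  expect_equal(res$raw_total, 20)
  res19 <- aggregate_gene_counts(snps, sc, loci, min_reads = 19)
  expect_setequal(res19$gene_id, c("g1", "g2"))
})

test_that("a SNP inside two loci is an ambiguity error naming the loci", {
  loci <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
                     start = c(1, 50), end = c(100, 150),
                     stringsAsFactors = FALSE)
  snps <- data.frame(chromosome = "chr1", position = 75,
                     stringsAsFactors = FALSE)
  sc <- data.frame(chromosome = "chr1", position = 75, class = "P_pse",
                   count = 30, stringsAsFactors = FALSE)
  expect_error(aggregate_gene_counts(snps, sc, loci), "g1, g2")
})

test_that("counts are conserved through aggregation before adjustment", {
  cfg <- simulation_config(30, seed = 9, base_mean_range = c(50, 200))
  sim <- simulate_regulatory_counts(cfg)
  loci <- data.frame(gene_id = sim$counts$gene_id, chromosome = "chrS",
                     start = (seq_len(30) - 1) * 10000 + 1,
                     end = (seq_len(30) - 1) * 10000 + 2000,
                     stringsAsFactors = FALSE)
  tabs <- simulate_snp_tables(sim$counts, loci, seed = 9)
  agg <- aggregate_gene_counts(tabs$snps, tabs$site_counts, loci,
                               min_reads = 0)
  agg <- agg[match(sim$counts$gene_id, agg$gene_id), ]
  for (cl in c("P_pse", "P_bog", "H_pse", "H_bog"))
    expect_equal(agg[[cl]], sim$counts[[cl]])
  # and the planted SNP set is recovered exactly from the observations
  called <- call_fixed_snps(tabs$observations)
  called_key <- paste(called$chromosome, called$position)
  truth_key <- paste(tabs$snps$chromosome, tabs$snps$position)
  support_ok <- tapply(tabs$observations$count,
                       paste(tabs$observations$chromosome,
                             tabs$observations$position,
                             tabs$observations$subspecies), sum)
  recoverable <- vapply(truth_key, function(k) {
    all(support_ok[paste(k, c("pse", "bog"))] >= 3)
  }, logical(1))
  expect_setequal(called_key, truth_key[recoverable])
})

test_that("depth adjustment rescales to the smallest class and maps 0 to 1", {
  counts <- data.frame(gene_id = c("g1", "g2"),
                       P_pse = c(100, 40), P_bog = c(80, 0),
                       H_pse = c(60, 10), H_bog = c(0, 55),
                       stringsAsFactors = FALSE)
  equal <- adjust_depth(counts, c(P_pse = 1e6, P_bog = 1e6,
                                  H_pse = 1e6, H_bog = 1e6))
  expect_equal(equal$P_pse, c(100, 40))
  expect_equal(equal$H_bog, c(1, 55))   # only the zero changes
  scaled <- adjust_depth(counts, c(P_pse = 2e6, P_bog = 1e6,
                                   H_pse = 1e6, H_bog = 1e6))
  expect_equal(scaled$P_pse, c(50, 20))
  expect_equal(scaled$P_bog, c(80, 1))
  expect_error(adjust_depth(counts, c(P_pse = 0, P_bog = 1, H_pse = 1,
                                      H_bog = 1)), "positive")
})
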