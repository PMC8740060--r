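test_that("configuration invariants are enforced", {
  expect_error(simulation_config(10, category_proportions = c(conserved = 0.9)),
               "sum to 1")
  expect_error(simulation_config(10, dispersion = -1), "dispersion")
  expect_error(simulation_config(10, cis_fold_range = c(4, 2)), "lower")
  expect_error(simulation_config(10, base_mean_range = c(-5, 5)), "positive")
  expect_error(simulate_regulatory_counts(list(n_genes = 5)),
               "simulation_config")
})

test_that("planted effects respect the category constraints", {
  cfg <- simulation_config(300, seed = 4, cis_fold_range = c(2, 8),
                           trans_fold_range = c(2, 8))
  truth <- simulate_regulatory_counts(cfg)$truth
  with_cat <- function(cat) truth[truth$true_category == cat, ]
  expect_true(all(with_cat("conserved")$c == 1 & with_cat("conserved")$t == 1))
  expect_true(all(with_cat("cis_only")$c != 1 & with_cat("cis_only")$t == 1))
  expect_true(all(with_cat("trans_only")$c == 1 &
                    with_cat("trans_only")$t != 1))
  ct <- with_cat("cis_and_trans")
  expect_true(all(ct$c != 1 & ct$t != 1 & abs(ct$t - 1 / ct$c) > 1e-9))
  comp <- with_cat("compensatory")
  expect_true(all(comp$c != 1))
  expect_equal(comp$t, 1 / comp$c, tolerance = 1e-12)
})

test_that("simulation is deterministic and stable under config identity", {
  cfg <- simulation_config(50, seed = 77)
  s1 <- simulate_regulatory_counts(cfg)
  s2 <- simulate_regulatory_counts(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_regulatory_counts(simulation_config(50, seed = 78))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("allele fractions match their binomial expectations", {
  # null symmetry: conserved genes center on 1/2
  cfg0 <- simulation_config(500, category_proportions = c(conserved = 1),
                            seed = 21)
  s0 <- simulate_regulatory_counts(cfg0)
  frac <- s0$counts$P_pse / (s0$counts$P_pse + s0$counts$P_bog)
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)

  # cis-only with c = 4 forced high: hybrid fraction centers on 4/5
  cfg1 <- simulation_config(600, category_proportions = c(cis_only = 1),
                            cis_fold_range = c(4, 4), seed = 42)
  s1 <- simulate_regulatory_counts(cfg1)
  up <- s1$truth$c > 1
  hf <- s1$counts$H_pse / (s1$counts$H_pse + s1$counts$H_bog)
  se_h <- sd(hf[up]) / sqrt(sum(up))
  expect_lt(abs(mean(hf[up]) - 0.8), 3 * se_h)
  # and the parental fraction estimates c*t/(1+c*t) = 4/5 as well (t = 1)
  pf <- s1$counts$P_pse / (s1$counts$P_pse + s1$counts$P_bog)
  se_p <- sd(pf[up]) / sqrt(sum(up))
  expect_lt(abs(mean(pf[up]) - 0.8), 3 * se_p)

  # compensatory: parental fraction ~ 1/2 while hybrid fraction ~ c/(1+c)
  cfg2 <- simulation_config(500, category_proportions = c(compensatory = 1),
                            cis_fold_range = c(4, 4), seed = 8)
  s2 <- simulate_regulatory_counts(cfg2)
  up2 <- s2$truth$c > 1
  pf2 <- s2$counts$P_pse / (s2$counts$P_pse + s2$counts$P_bog)
  hf2 <- s2$counts$H_pse / (s2$counts$H_pse + s2$counts$H_bog)
  expect_lt(abs(mean(pf2) - 0.5), 3 * sd(pf2) / sqrt(length(pf2)))
  expect_lt(abs(mean(hf2[up2]) - 0.8), 3 * sd(hf2[up2]) / sqrt(sum(up2)))
})

test_that("gene annotation plants exact cluster gaps and stays in bounds", {
  loci <- simulate_gene_annotation(
    20, c(chrA = 5e6, chrB = 5e6),
    planted_clusters = list(list(chromosome = "chrA", gap_bp = 1251)),
    seed = 3)
  expect_equal(nrow(loci), 22L)
  # non-overlapping within chromosomes
  for (ch in unique(loci$chromosome)) {
    p <- loci[loci$chromosome == ch, ]
    p <- p[order(p$start), ]
    expect_true(all(p$start[-1] > p$end[-nrow(p)]))
  }
  cl <- detect_clusters(loci, max_gap = 5500)
  expect_equal(nrow(cl), 1L)
  expect_equal(unlist(cl$gaps), 1251)
  # determinism and degenerate input
  expect_identical(loci, simulate_gene_annotation(
    20, c(chrA = 5e6, chrB = 5e6),
    planted_clusters = list(list(chromosome = "chrA", gap_bp = 1251)),
    seed = 3))
  expect_equal(nrow(simulate_gene_annotation(0, c(chrA = 1e6))), 0L)
  expect_error(simulate_gene_annotation(1000, c(chrA = 1e5)), "capacity")
})

test_that("alignment simulator plants recoverable fixed and polymorphic sites", {
  sim <- simulate_alignment_panel(31, 5, 800, n_fixed = 7, n_poly_a = 3,
                                  n_poly_b = 2, seed = 10)
  fixed <- count_fixed_differences(sim$panel)
  expect_equal(fixed$count, 7)
  expect_equal(fixed$positions, sim$truth$fixed)
  expect_equal(count_polymorphisms(sim$panel, "pse"), 3)
  expect_equal(count_polymorphisms(sim$panel, "bog"), 2)
  none <- simulate_alignment_panel(5, 5, 200, n_fixed = 0, n_poly_a = 3,
                                   seed = 2)
  expect_equal(count_fixed_differences(none$panel)$count, 0)
  expect_error(simulate_alignment_panel(3, 3, 10, n_fixed = 8, n_poly_a = 5),
               "budget")
})

test_that("inheritance simulator means follow the mode definitions", {
  sim <- simulate_inheritance_counts(400, fold = 4, depth = 500,
                                     dispersion = 0.01, n_replicates = 20,
                                     seed = 13)
  mean_by_mode <- function(mat, mode)
    mean(rowMeans(mat[sim$truth$true_mode == mode, , drop = FALSE]))
  expect_equal(mean_by_mode(sim$hybrid, "transgressive_up") /
                 mean_by_mode(sim$parent_a, "transgressive_up"),
               4, tolerance = 0.1)
  expect_equal(mean_by_mode(sim$hybrid, "additive"),
               (mean_by_mode(sim$parent_a, "additive") +
                  mean_by_mode(sim$parent_b, "additive")) / 2,
               tolerance = 0.1)
  nd <- sim$truth$true_mode == "non_differential"
  expect_equal(mean(sim$hybrid[nd, ]) / mean(sim$parent_a[nd, ]), 1,
               tolerance = 0.05)
  expect_identical(sim, simulate_inheritance_counts(
    400, fold = 4, depth = 500, dispersion = 0.01, n_replicates = 20,
    seed = 13))
})
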