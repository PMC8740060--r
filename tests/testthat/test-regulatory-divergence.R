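counts_table <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(gene_id = paste0("g", i), P_pse = r[1], P_bog = r[2],
               H_pse = r[3], H_bog = r[4], stringsAsFactors = FALSE)
  }))
  df
}

test_that("canonical count patterns map to their regulatory categories", {
  # several genes share each pattern so BH correction cannot rescue a
  # single outlying p-value
  tab <- counts_table(
    c(150, 150, 150, 150), c(151, 149, 150, 150),   # conserved
    c(300, 100, 300, 100), c(310, 95, 295, 105),    # cis_only
    c(300, 100, 200, 200), c(295, 102, 201, 199),   # trans_only
    c(800, 100, 300, 100), c(790, 105, 310, 95),    # cis_and_trans
    c(200, 200, 300, 100), c(201, 199, 295, 105))   # compensatory
  res <- classify_regulatory_divergence(tab, alpha = 0.005)
  got <- as.character(res$calls$category)
  expect_equal(got, rep(c("conserved", "cis_only", "trans_only",
                          "cis_and_trans", "compensatory"), each = 2))
  expect_equal(res$calls$cis_effect,
               rep(c(FALSE, TRUE, FALSE, TRUE, TRUE), each = 2))
  # q-values never fall below their p-values
  expect_true(all(res$tests$q_parent >= res$tests$p_parent))
  expect_true(all(res$tests$q_hybrid >= res$tests$p_hybrid))
  expect_true(all(res$tests$q_ratio >= res$tests$p_ratio))
})

test_that("flag-to-category map is exhaustive with three ambiguous combos", {
  combos <- expand.grid(p = c(FALSE, TRUE), h = c(FALSE, TRUE),
                        r = c(FALSE, TRUE))
  cats <- cistrans:::.category_from_flags(combos$p, combos$h, combos$r)
  expect_true(all(cats %in% c("conserved", "cis_only", "trans_only",
                              "cis_and_trans", "compensatory", "ambiguous")))
  expect_equal(sum(cats == "ambiguous"), 3L)
  expect_equal(anyDuplicated(paste(combos$p, combos$h, combos$r)), 0L)
})

test_that("classification is invariant to which subspecies is 'success'", {
  tab <- counts_table(c(300, 100, 300, 100), c(310, 90, 280, 110),
                      c(150, 150, 150, 150), c(200, 200, 300, 100),
                      c(190, 210, 310, 95))
  swapped <- tab
  swapped$P_pse <- tab$P_bog; swapped$P_bog <- tab$P_pse
  swapped$H_pse <- tab$H_bog; swapped$H_bog <- tab$H_pse
  r1 <- classify_regulatory_divergence(tab)
  r2 <- classify_regulatory_divergence(swapped)
  expect_equal(as.character(r1$calls$category),
               as.character(r2$calls$category))
})

test_that("raising alpha only turns flags on, never off", {
  cfg <- simulation_config(120, seed = 15, cis_fold_range = c(2, 2),
                           trans_fold_range = c(2, 2),
                           base_mean_range = c(100, 400))
  sim <- simulate_regulatory_counts(cfg)
  strict <- classify_regulatory_divergence(sim$counts, alpha = 0.005)
  loose <- classify_regulatory_divergence(sim$counts, alpha = 0.05)
  for (flag in c("sig_parent", "sig_hybrid", "sig_ratio"))
    expect_true(all(loose$tests[[flag]] >= strict$tests[[flag]]))
  # consequence: no gene moves from cis_and_trans to conserved
  expect_false(any(strict$calls$category == "cis_and_trans" &
                     loose$calls$category == "conserved"))
})

test_that("cis-effect summary counts the broad cis group", {
  calls <- data.frame(gene_id = paste0("g", 1:4),
                      category = c("cis_only", "cis_only", "cis_only",
                                   "trans_only"),
                      stringsAsFactors = FALSE)
  s <- summarize_cis_effects(calls)
  expect_equal(s$cis_effect_fraction, 0.75)
  all_cons <- data.frame(gene_id = "g1", category = "conserved",
                         stringsAsFactors = FALSE)
  expect_equal(summarize_cis_effects(all_cons)$cis_effect_fraction, 0)
})

test_that("classifier recovers planted categories on the benchmark", {
  cfg <- simulation_config(600, seed = 42)
  sim <- simulate_regulatory_counts(cfg)
  res <- classify_regulatory_divergence(sim$counts, alpha = 0.005)
  got <- as.character(res$calls$category)
  expect_gte(mean(got == sim$truth$true_category), 0.80)
  cons <- sim$truth$true_category == "conserved"
  expect_gte(mean(got[cons] == "conserved"), 0.90)
  # cis-effect fraction tracks the planted cis-bearing fraction
  planted_cis <- mean(sim$truth$c != 1)
  expect_lt(abs(summarize_cis_effects(res$calls)$cis_effect_fraction -
                  planted_cis), 0.1)
})

test_that("empty input and bad alpha are rejected", {
  expect_error(classify_regulatory_divergence(
    counts_table(c(1, 1, 1, 1))[0, ]), "empty")
  expect_error(classify_regulatory_divergence(
    counts_table(c(10, 10, 10, 10)), alpha = 0), "alpha")
})
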