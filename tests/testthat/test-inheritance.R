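test_that("the stand-in pairwise test computes lfc and significance", {
  same <- simple_pairwise_test(c(100, 100, 100), c(100, 100, 100))
  expect_false(same$significant)
  expect_equal(same$lfc, 0)
  strong <- simple_pairwise_test(c(800, 810, 790), c(100, 105, 95))
  expect_true(strong$significant)
  expect_equal(strong$lfc, 3, tolerance = 0.05)
  weak <- simple_pairwise_test(c(100, 300), c(90, 310))
  expect_false(weak$significant)
  expect_error(simple_pairwise_test(c(1), c(2, 3)), "replicates")
})

test_that("inheritance classification covers every direction/significance combo", {
  mk <- function(sig, lfc) list(lfc = lfc, significant = sig)
  expect_equal(classify_inheritance(mk(TRUE, 2), mk(TRUE, 3)),
               "transgressive_up")
  expect_equal(classify_inheritance(mk(TRUE, -2), mk(TRUE, -3)),
               "transgressive_down")
  expect_equal(classify_inheritance(mk(FALSE, 0.1), mk(FALSE, -0.2)),
               "non_differential")
  expect_equal(classify_inheritance(mk(TRUE, -2), mk(TRUE, 3)), "additive")
  # exhaustive: every combination yields exactly one valid mode
  for (sa in c(TRUE, FALSE)) for (sb in c(TRUE, FALSE))
    for (la in c(-2, 2)) for (lb in c(-2, 2)) {
      mode <- classify_inheritance(mk(sa, la), mk(sb, lb))
      expect_true(mode %in% c("transgressive_up", "transgressive_down",
                              "additive", "non_differential"))
    }
  expect_error(classify_inheritance(c(mk(TRUE, 1), gene_id = "a"),
                                    c(mk(TRUE, 1), gene_id = "b")),
               "mismatch")
})

test_that("transgressive calls survive parental label swap", {
  mk <- function(sig, lfc) list(lfc = lfc, significant = sig)
  for (sa in c(TRUE, FALSE)) for (sb in c(TRUE, FALSE))
    for (la in c(-2, 2)) for (lb in c(-2, 2)) {
      m1 <- classify_inheritance(mk(sa, la), mk(sb, lb))
      m2 <- classify_inheritance(mk(sb, lb), mk(sa, la))
      expect_equal(m1 %in% c("transgressive_up", "transgressive_down"),
                   m2 %in% c("transgressive_up", "transgressive_down"))
    }
})

test_that("matrix classification recovers planted modes under strong signal", {
  sim <- simulate_inheritance_counts(200, mode_proportions = c(
    non_differential = 1), fold = 1, depth = 500, seed = 42)
  calls <- classify_inheritance_matrix(sim$parent_a, sim$parent_b,
                                       sim$hybrid)
  expect_gte(mean(calls$mode == "non_differential"), 0.9)
  sim2 <- simulate_inheritance_counts(200, fold = 8, depth = 500, seed = 5)
  calls2 <- classify_inheritance_matrix(sim2$parent_a, sim2$parent_b,
                                        sim2$hybrid)
  expect_gte(mean(calls2$mode == sim2$truth$true_mode), 0.8)
})

test_that("spectrum comparison reproduces the sterile-vs-fertile contrast", {
  sterile <- c(rep("transgressive_up", 21), rep("transgressive_down", 15),
               rep("additive", 10), rep("non_differential", 6))
  fertile <- c(rep("transgressive_down", 2), rep("additive", 13),
               rep("non_differential", 37))
  two_way <- compare_inheritance_spectra(sterile, fertile,
                                         "transgressive_vs_rest")
  expect_equal(unname(two_way$table["groupA", ]), c(36, 16))
  expect_equal(unname(two_way$table["groupB", ]), c(2, 50))
  expect_lt(two_way$p, 0.001)
  three_way <- compare_inheritance_spectra(sterile, fertile, "three_way")
  expect_equal(dim(three_way$table), c(2L, 3L))
  expect_lt(three_way$p, 0.001)
  same <- compare_inheritance_spectra(
    c(rep("additive", 10), rep("non_differential", 10)),
    c(rep("additive", 10), rep("non_differential", 10)))
  expect_equal(same$p, 1)
  expect_error(compare_inheritance_spectra(character(0), fertile),
               "non-empty")
})

test_that("type-I error of the spectrum test is controlled under the null", {
  set.seed(31)
  rejections <- 0L
  reps <- 400
  for (rep in seq_len(reps)) {
    draw <- function() sample(c("transgressive_up", "additive",
                                "non_differential"), 30, replace = TRUE,
                              prob = c(0.3, 0.3, 0.4))
    p <- compare_inheritance_spectra(draw(), draw(), "three_way")$p
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / reps, 0.08)
})
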