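# Independent brute-force oracles for the exact tests, built from
# factorial/choose primitives rather than the d*() densities the package
# uses, plus small fixture builders.

TIE <- 1 + 1e-7

# two-sided binomial by full outcome enumeration
oracle_binomial <- function(x, n, p0 = 0.5) {
  k <- 0:n
  probs <- choose(n, k) * p0^k * (1 - p0)^(n - k)
  min(1, sum(probs[probs <= probs[x + 1] * TIE]))
}

# hypergeometric table probability from the closed-form factorial ratio
.table_prob_2x2 <- function(a, b, c, d) {
  exp(lfactorial(a + b) + lfactorial(c + d) + lfactorial(a + c) +
        lfactorial(b + d) - lfactorial(a + b + c + d) -
        lfactorial(a) - lfactorial(b) - lfactorial(c) - lfactorial(d))
}

# two-sided Fisher 2x2 by full enumeration over the margin-fixed support
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- vapply(lo:hi, function(x) {
    .table_prob_2x2(x, r1 - x, c1 - x, r2 - (c1 - x))
  }, numeric(1))
  obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= obs * TIE]))
}

# Freeman-Halton 2x3 by full enumeration of margin-preserving tables
oracle_fisher_2x3 <- function(tab) {
  cs <- colSums(tab); r1 <- sum(tab[1, ]); N <- sum(tab)
  lprob <- function(row) {
    row2 <- cs - row
    sum(lfactorial(c(r1, N - r1, cs))) - lfactorial(N) -
      sum(lfactorial(c(row, row2)))
  }
  obs <- lprob(tab[1, ])
  total <- 0
  for (x1 in 0:min(r1, cs[1])) {
    for (x2 in 0:min(r1 - x1, cs[2])) {
      x3 <- r1 - x1 - x2
      if (x3 > cs[3]) next
      lp <- lprob(c(x1, x2, x3))
      if (lp <= obs + log(TIE)) total <- total + exp(lp)
    }
  }
  min(1, total)
}

# panel from aligned sequence strings
make_panel <- function(seqs, subspecies, alphabet = "nucleotide") {
  names(seqs) <- names(seqs) %||%
    sprintf("%s_%02d", subspecies, seq_along(seqs))
  cistrans::alignment_panel(seqs, subspecies, alphabet = alphabet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# four-gene-pair loci from the printed chromosome/coordinate pairs
table3b_loci <- function() {
  data.frame(
    gene_id = c("GA20266", "GA12467", "GA30092", "GA30093",
                "GA32028", "GA32735", "GA12058", "GA12057"),
    chromosome = c("XR_gr6", "XR_gr6", "2", "2", "3", "3", "4_gr3", "4_gr3"),
    start = c(11006949, 11012793, 2654310, 2658297,
              17507910, 17511839, 433681, 441275),
    end = c(11001889, 11008200, 2653746, 2657180,
            17507170, 17511279, 433000, 438883),
    strand = "-",
    stringsAsFactors = FALSE)
}
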