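# Two-subspecies alignment panels: a character matrix (strains x columns)
# plus a pse/bog label per strain.  All fixed-difference / polymorphism
# logic operates on this container for both nucleotide and protein panels.

GAP_RESIDUES <- c("-", ".")

# ambiguity codes treated as missing data, by alphabet: N is missing for
# nucleotides but is asparagine in proteins, where X is the unknown code
missing_residues <- function(alphabet) {
  if (alphabet == "nucleotide") c("N", "X", "?") else c("X", "?", "*")
}

#' Construct an alignment panel
#'
#' @param sequences Either a character matrix (strains x alignment columns,
#'   one residue per cell, rownames = strain ids) or a named character
#'   vector of equal-length aligned sequences.
#' @param subspecies Character vector of `"pse"`/`"bog"` labels, one per
#'   strain, in strain order.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param positions Optional integer labels for the columns (e.g. a
#'   TSS-anchored axis); defaults to `1:ncol`.
#' @return An object of class `alignment_panel`.
#' @export
alignment_panel <- function(sequences, subspecies,
                            alphabet = c("nucleotide", "protein"),
                            positions = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (length(unique(nchar(sequences))) != 1L)
      stop("aligned sequences must all have the same length")
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(mat) <- names(sequences)
  }
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop("empty alignment panel")
  if (length(subspecies) != nrow(mat))
    stop("need one subspecies label per strain")
  if (!all(subspecies %in% c("pse", "bog")))
    stop("subspecies labels must be 'pse' or 'bog'")
  if (!all(c("pse", "bog") %in% subspecies))
    stop("panel needs at least one strain of each subspecies")
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("strain%02d", seq_len(nrow(mat)))
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  if (length(positions) != ncol(mat))
    stop("positions must label every alignment column")
  structure(list(mat = mat, subspecies = subspecies,
                 alphabet = alphabet, positions = as.integer(positions)),
            class = "alignment_panel")
}

#' @export
print.alignment_panel <- function(x, ...) {
  cat("alignment_panel:", nrow(x$mat), "strains (",
      sum(x$subspecies == "pse"), "pse /", sum(x$subspecies == "bog"),
      "bog ) x", ncol(x$mat), x$alphabet, "columns\n")
  invisible(x)
}

#' @export
dim.alignment_panel <- function(x) dim(x$mat)

# per-column summary: residues carried by each subspecies (missing data
# dropped), and whether the column contains any gap character
.column_profiles <- function(panel) {
  mat <- panel$mat
  is_pse <- panel$subspecies == "pse"
  missing <- missing_residues(panel$alphabet)
  lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    has_gap <- any(col %in% GAP_RESIDUES)
    keep <- !(col %in% c(missing, GAP_RESIDUES))
    list(has_gap = has_gap,
         pse = unique(col[keep & is_pse]),
         bog = unique(col[keep & !is_pse]))
  })
}

#' Count fixed differences between the two subspecies
#'
#' A column is a fixed difference iff, among non-missing residues, each
#' subspecies carries exactly one residue and the two residues differ.
#' Columns containing a gap in any strain are skipped entirely; ambiguity
#' codes (N, X, ?) are treated as missing data, not alleles.
#'
#' @param panel An [alignment_panel()].
#' @return List with `count` and `positions` (column labels on the panel's
#'   position axis, sorted).
#' @export
count_fixed_differences <- function(panel) {
  stopifnot(inherits(panel, "alignment_panel"))
  prof <- .column_profiles(panel)
  fixed <- vapply(prof, function(p) {
    !p$has_gap && length(p$pse) == 1L && length(p$bog) == 1L &&
      p$pse != p$bog
  }, logical(1))
  list(count = sum(fixed), positions = panel$positions[fixed])
}

#' Count columns polymorphic within a subspecies
#'
#' A column counts as polymorphic for a subspecies iff it segregates
#' (>= 2 residues among non-missing data) within that subspecies' strains.
#' `"both"` counts columns segregating within either subspecies.  Gap
#' columns are skipped, as in [count_fixed_differences()].
#'
#' @param panel An [alignment_panel()].
#' @param subspecies `"pse"`, `"bog"` or `"both"`.
#' @return Number of polymorphic columns.
#' @export
count_polymorphisms <- function(panel, subspecies = c("pse", "bog", "both")) {
  stopifnot(inherits(panel, "alignment_panel"))
  subspecies <- match.arg(subspecies)
  checked <- if (subspecies == "both") c("pse", "bog") else subspecies
  for (sub in checked) {
    if (sum(panel$subspecies == sub) < 2L)
      stop("polymorphism within '", sub, "' needs >= 2 strains")
  }
  prof <- .column_profiles(panel)
  seg <- vapply(prof, function(p) {
    if (p$has_gap) return(FALSE)
    switch(subspecies,
           pse = length(p$pse) >= 2L,
           bog = length(p$bog) >= 2L,
           both = length(p$pse) >= 2L || length(p$bog) >= 2L)
  }, logical(1))
  sum(seg)
}

# strains x variable-columns haplotype strings per subspecies; strains with
# missing/gap data over the chosen columns are dropped
.haplotypes_by_subspecies <- function(panel, cols) {
  mat <- panel$mat[, cols, drop = FALSE]
  missing <- missing_residues(panel$alphabet)
  ok <- apply(mat, 1, function(r)
    !any(r %in% c(missing, GAP_RESIDUES)))
  haps <- apply(mat[ok, , drop = FALSE], 1, paste, collapse = "")
  split(haps, panel$subspecies[ok])
}

# TRUE iff no haplotype over `cols` is shared between the subspecies
.separates <- function(panel, cols) {
  if (length(cols) == 0L) return(FALSE)
  h <- .haplotypes_by_subspecies(panel, cols)
  if (is.null(h$pse) || is.null(h$bog)) return(FALSE)
  length(intersect(unique(h$pse), unique(h$bog))) == 0L
}

# variable columns: >= 2 residues among non-missing data across ALL strains
.variable_columns <- function(panel) {
  prof <- .column_profiles(panel)
  which(vapply(prof, function(p) {
    length(unique(c(p$pse, p$bog))) >= 2L
  }, logical(1)))
}

#' Subspecies-diagnostic haplotypes
#'
#' Tests whether the joint residue pattern over all variable columns
#' separates the two subspecies: `separating` is `TRUE` iff no full-length
#' haplotype is shared between them, which can hold even with no single
#' fixed column.  Also reports a small distinguishing column set found
#' greedily: columns are added leftmost-first until the set separates,
#' then a single right-to-left pruning pass removes redundant columns.
#' The greedy set always separates when `separating` is `TRUE`, but exact
#' minimality is not guaranteed.
#'
#' @param panel An [alignment_panel()].
#' @return List with `separating` (logical) and `positions` (labels of the
#'   distinguishing columns; empty when not separating).
#' @export
diagnostic_haplotypes <- function(panel) {
  stopifnot(inherits(panel, "alignment_panel"))
  vc <- .variable_columns(panel)
  if (length(vc) == 0L || !.separates(panel, vc))
    return(list(separating = FALSE, positions = integer(0)))
  chosen <- integer(0)
  for (col in vc) {
    chosen <- c(chosen, col)
    if (.separates(panel, chosen)) break
  }
  for (col in rev(chosen)) {
    reduced <- setdiff(chosen, col)
    if (length(reduced) && .separates(panel, reduced)) chosen <- reduced
  }
  list(separating = TRUE, positions = panel$positions[sort(chosen)])
}
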