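# TSS-anchored upstream-window screens on nucleotide alignment panels.
#
# Coordinates use a TSS-anchored axis with no position 0: -1 is the column
# immediately 5' of the TSS and +1 is the TSS column itself.  Minus-strand
# genes are expected to be reverse-complemented upstream of panel
# construction so "upstream" is always 5' of the transcript.

# TSS-axis labels for a window (-upstream .. +downstream), skipping 0
.tss_axis <- function(upstream, downstream) {
  c(if (upstream > 0) seq(-upstream, -1L) else integer(0),
    if (downstream > 0) seq(1L, downstream) else integer(0))
}

#' Extract a TSS-anchored window from an alignment panel
#'
#' Returns the sub-panel covering positions `-upstream .. +downstream`
#' around `tss_column` (the column labelled +1).  Windows reaching past
#' either end of the alignment are truncated with a warning.
#'
#' @param panel An [alignment_panel()].
#' @param tss_column Alignment column of the TSS (position +1).
#' @param upstream Extent in bp before the TSS (positive).
#' @param downstream Extent in bp from the TSS onward (non-negative).
#' @return An [alignment_panel()] whose `positions` carry the TSS axis.
#' @export
extract_window <- function(panel, tss_column, upstream, downstream = 200) {
  stopifnot(inherits(panel, "alignment_panel"))
  if (tss_column < 1 || tss_column > ncol(panel$mat))
    stop("tss_column outside the alignment")
  if (upstream < 0 || downstream < 0)
    stop("window extents must be non-negative")
  if (upstream + downstream == 0)
    stop("degenerate window: zero extent on both sides of the TSS")
  first <- tss_column - upstream
  last <- tss_column + downstream - 1
  if (first < 1 || last > ncol(panel$mat)) {
    warning("window truncated to the alignment bounds")
    first <- max(1, first)
    last <- min(ncol(panel$mat), last)
  }
  cols <- first:last
  axis <- (cols - tss_column) + as.integer(cols >= tss_column)
  alignment_panel(panel$mat[, cols, drop = FALSE], panel$subspecies,
                  alphabet = panel$alphabet, positions = axis)
}

#' Fixed-difference counts over a ladder of upstream windows
#'
#' Convenience wrapper reporting, for each upstream extent, the number of
#' fixed differences in the `(-extent, +downstream)` window — mirroring
#' per-gene promoter-divergence tables.
#'
#' @param panel An [alignment_panel()] with the TSS at `tss_column`.
#' @param tss_column Alignment column of the TSS.
#' @param upstream_ladder Upstream extents, default `c(500, 1000, 2000, 3000)`.
#' @param downstream Downstream extent, default 200.
#' @return Data frame: `upstream`, `downstream`, `fixed`.
#' @export
window_ladder_counts <- function(panel, tss_column,
                                 upstream_ladder = c(500, 1000, 2000, 3000),
                                 downstream = 200) {
  fixed <- vapply(upstream_ladder, function(u) {
    count_fixed_differences(
      extract_window(panel, tss_column, u, downstream))$count
  }, numeric(1))
  data.frame(upstream = upstream_ladder, downstream = downstream,
             fixed = fixed)
}

#' Fixed changes and diagnostic polymorphism inside motif sites
#'
#' For each motif-site interval on the TSS axis, reports the number of
#' fixed-difference columns inside the interval and whether the joint
#' residue pattern over the interval's variable columns separates the
#' subspecies (no shared haplotype) — a fixed difference inside the site
#' trivially separates.
#'
#' @param panel An [alignment_panel()] whose `positions` are on the TSS
#'   axis (e.g. from [extract_window()]).
#' @param sites Data frame of motif sites: `gene_id` (or `site_id`),
#'   `start`, `end` — inclusive TSS-axis coordinates.
#' @return `sites` with `fixed_count` and `diagnostic_polymorphism` added.
#' @export
motif_site_divergence <- function(panel, sites) {
  stopifnot(inherits(panel, "alignment_panel"))
  stopifnot_cols(sites, c("start", "end"), "sites")
  fixed_pos <- count_fixed_differences(panel)$positions
  var_cols <- .variable_columns(panel)
  sites$fixed_count <- NA_integer_
  sites$diagnostic_polymorphism <- NA
  for (i in seq_len(nrow(sites))) {
    lo <- sites$start[i]; hi <- sites$end[i]
    in_site <- panel$positions >= lo & panel$positions <= hi
    if (!any(in_site))
      stop("motif site ", lo, "..", hi, " lies outside the window")
    sites$fixed_count[i] <- sum(fixed_pos >= lo & fixed_pos <= hi)
    cols <- intersect(var_cols, which(in_site))
    sites$diagnostic_polymorphism[i] <-
      length(cols) > 0 && .separates(panel, cols)
  }
  sites
}
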