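# Fixed amino-acid substitution and domain screens on protein panels.
#
# Positions are reported in the ungapped coordinates of the reference
# protein — the first pse strain of the panel — since single-protein
# substitution nomenclature (e.g. R24K) uses one sequence's numbering.

#' Find fixed amino-acid substitutions between subspecies
#'
#' Applies the same fixed-column rule as [count_fixed_differences()]
#' (each subspecies monomorphic for a different residue among non-missing
#' data; gap columns skipped) and reports each substitution with its
#' residue identities and its position in the ungapped reference (first
#' pse strain) numbering.
#'
#' @param panel A protein [alignment_panel()].
#' @return Data frame: `position` (ungapped reference residue index),
#'   `column` (alignment column), `residue_pse`, `residue_bog`,
#'   `in_domain` (initialized `FALSE`).  Positions strictly increasing.
#' @export
find_fixed_aa_substitutions <- function(panel) {
  stopifnot(inherits(panel, "alignment_panel"))
  if (panel$alphabet != "protein")
    stop("panel must use the protein alphabet")
  ref_row <- which(panel$subspecies == "pse")[1]
  ref <- panel$mat[ref_row, ]
  ref_pos <- cumsum(!(ref %in% GAP_RESIDUES))
  fixed <- count_fixed_differences(panel)
  cols <- match(fixed$positions, panel$positions)
  if (length(cols) == 0L) {
    return(data.frame(position = integer(), column = integer(),
                      residue_pse = character(), residue_bog = character(),
                      in_domain = logical(), stringsAsFactors = FALSE))
  }
  is_pse <- panel$subspecies == "pse"
  data.frame(position = ref_pos[cols],
             column = cols,
             residue_pse = panel$mat[which(is_pse)[1], cols],
             residue_bog = panel$mat[which(!is_pse)[1], cols],
             in_domain = FALSE,
             stringsAsFactors = FALSE)
}

#' Annotate substitutions with binding-domain membership
#'
#' @param subs Substitution table from [find_fixed_aa_substitutions()]
#'   (columns `position`, `in_domain`).
#' @param domains Data frame of domain intervals: `domain`, `start`, `end`
#'   (1-based inclusive residue positions).
#' @param protein_length Optional protein length; positions beyond it are
#'   an error.
#' @return List with `substitutions` (the table with `in_domain` set) and
#'   `per_domain` (named substitution counts per domain).
#' @export
substitutions_in_domains <- function(subs, domains = NULL,
                                     protein_length = NULL) {
  stopifnot_cols(subs, c("position"), "subs")
  if (!is.null(protein_length) && nrow(subs) &&
      any(subs$position > protein_length))
    stop("substitution position beyond protein length ", protein_length)
  if (is.null(domains) || nrow(domains) == 0L) {
    subs$in_domain <- FALSE
    return(list(substitutions = subs,
                per_domain = integer(0)))
  }
  stopifnot_cols(domains, c("domain", "start", "end"), "domains")
  if (any(domains$start > domains$end) || any(domains$start < 1))
    stop("domain intervals must satisfy 1 <= start <= end")
  per_domain <- integer(nrow(domains))
  names(per_domain) <- domains$domain
  in_dom <- rep(FALSE, nrow(subs))
  for (d in seq_len(nrow(domains))) {
    hit <- subs$position >= domains$start[d] & subs$position <= domains$end[d]
    per_domain[d] <- sum(hit)
    in_dom <- in_dom | hit
  }
  subs$in_domain <- in_dom
  list(substitutions = subs, per_domain = per_domain)
}
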