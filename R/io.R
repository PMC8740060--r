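# Table and FASTA input/output.  TSV (tab-delimited, header, UTF-8, "." for
# missing) is the interchange dialect; BED-like loci are 0-based half-open
# on disk and 1-based inclusive in memory.

#' Write a data frame as TSV
#'
#' @param df Data frame (list columns are collapsed with commas).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
    if (is.factor(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  df[is.na(df)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table, checking required columns and numeric fields
#'
#' @param path Input file.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers; offending rows
#'   are reported with line numbers.
#' @return Data frame with `"."` read back as `NA`.
#' @export
read_tsv_table <- function(path, required = character(0),
                           numeric_cols = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": header mismatch, missing column(s): ",
         paste(miss, collapse = ", "))
  df[df == "."] <- NA
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(path, ": non-numeric value in column '", col, "' at line(s) ",
           paste(bad + 1L, collapse = ", "))
    df[[col]] <- v
  }
  df
}

#' Read BED-like gene loci (0-based half-open) into 1-based inclusive form
#'
#' Expects tab-separated columns `chrom`, `start`, `end`, `gene_id`,
#' `strand` with a header.  Empty (start == end) intervals are rejected.
#'
#' @param path BED-like TSV file.
#' @return Locus data frame: `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @export
read_loci_bed <- function(path) {
  df <- read_tsv_table(path, required = c("chrom", "start", "end", "gene_id"),
                       numeric_cols = c("start", "end"))
  if (any(df$start >= df$end))
    stop(path, ": empty or inverted 0-based interval at line(s) ",
         paste(which(df$start >= df$end) + 1L, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicated gene_id")
  data.frame(gene_id = df$gene_id, chromosome = df$chrom,
             start = as.integer(df$start) + 1L, end = as.integer(df$end),
             strand = if ("strand" %in% names(df)) df$strand else "unknown",
             stringsAsFactors = FALSE)
}

#' Write gene loci as BED-like TSV (0-based half-open)
#'
#' @param loci Locus data frame (1-based inclusive).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  stopifnot_cols(loci, c("gene_id", "chromosome", "start", "end"), "loci")
  write_tsv_table(
    data.frame(chrom = loci$chromosome, start = loci$start - 1L,
               end = loci$end, gene_id = loci$gene_id,
               strand = if ("strand" %in% names(loci)) loci$strand else ".",
               stringsAsFactors = FALSE),
    path)
}

#' Read an aligned FASTA panel with "strain|subspecies" headers
#'
#' @param path Aligned FASTA file; every record header must be
#'   `strain|subspecies` with subspecies `pse` or `bog`; all sequences
#'   must have equal length.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return An [alignment_panel()].
#' @export
read_alignment_panel <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  seqs <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(seqs))) > 1L)
    stop(path, ": aligned sequences must all have the same length")
  headers <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(headers) != 2L))
    stop(path, ": FASTA headers must be 'strain|subspecies'")
  sv <- as.character(seqs)
  names(sv) <- vapply(headers, `[`, character(1), 1L)
  alignment_panel(sv, vapply(headers, `[`, character(1), 2L),
                  alphabet = alphabet)
}

#' Write an alignment panel as aligned FASTA
#'
#' @param panel An [alignment_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_panel <- function(panel, path) {
  stopifnot(inherits(panel, "alignment_panel"))
  seqs <- apply(panel$mat, 1, paste, collapse = "")
  bs <- Biostrings::BStringSet(seqs)
  names(bs) <- paste(rownames(panel$mat), panel$subspecies, sep = "|")
  Biostrings::writeXStringSet(bs, path)
  invisible(path)
}

#' Read precomputed differential-expression calls
#'
#' Schema for externally produced (e.g. DESeq2/edgeR consensus) calls:
#' `gene_id`, `comparison`, `lfc`, `qvalue`.
#'
#' @param path TSV file.
#' @param alpha,lfc_threshold Significance rule applied to the table.
#' @return Data frame with a `significant` column added.
#' @export
read_de_calls <- function(path, alpha = 0.05, lfc_threshold = 1) {
  df <- read_tsv_table(path,
                       required = c("gene_id", "comparison", "lfc", "qvalue"),
                       numeric_cols = c("lfc", "qvalue"))
  df$significant <- df$qvalue < alpha & abs(df$lfc) > lfc_threshold
  df
}
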