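#' Protein multiple alignment helpers
#'
#' Alignments are represented as a named character vector of equal-length
#' gapped rows; the gap character is `"-"`.
#'
#' @param path Aligned FASTA file.
#' @return Named character vector of gapped rows.
#' @export
read_protein_alignment <- function(path) {
  rows <- read_fasta(path, type = "AA")
  check_alignment(rows)
  rows
}

check_alignment <- function(rows) {
  if (length(rows) == 0L) stop("alignment has no rows")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows differ in length (", paste(unique(widths),
         collapse = ", "), ")")
  }
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("alignment rows must have unique names")
  }
  invisible(rows)
}

ungap <- function(row) gsub("-", "", row, fixed = TRUE)

#' Alignment column of the n-th residue of a gapped row
#'
#' @param row Gapped amino-acid string.
#' @param protein_index 1-based residue index (counting non-gap characters).
#' @return 1-based column index.
#' @export
residue_to_column <- function(row, protein_index) {
  chars <- strsplit(row, "")[[1L]]
  nongap <- which(chars != "-")
  if (any(protein_index < 1L) || any(protein_index > length(nongap))) {
    stop("protein_index out of range: row has ", length(nongap),
         " residues")
  }
  nongap[protein_index]
}

#' Residue index at an alignment column (inverse of residue_to_column)
#'
#' @param row Gapped amino-acid string.
#' @param column 1-based column index.
#' @return 1-based residue index, or `NA` when the row is gapped there.
#' @export
column_to_residue_index <- function(row, column) {
  chars <- strsplit(row, "")[[1L]]
  if (column < 1L || column > length(chars)) stop("column out of range")
  if (chars[column] == "-") return(NA_integer_)
  sum(chars[seq_len(column)] != "-")
}

#' Project splice sites into alignment coordinates
#'
#' Lifts each protein's splice sites (residue index + frame) into the shared
#' alignment coordinate system: the site keeps its frame and is assigned the
#' alignment column of its residue. The residue recorded with each site is
#' cross-checked against the alignment row; a mismatch signals a wrong
#' alignment/protein pairing and is an error.
#'
#' @param alignment Named character vector of gapped rows.
#' @param sites Data frame of splice sites (as from
#'   [derive_coding_splice_sites()], possibly several genes row-bound); the
#'   `gene_id` column must name alignment rows.
#' @return Data frame of aligned site calls with columns `protein_id`,
#'   `column`, `frame`, `residue`, `protein_index`, `coding_offset`, ordered
#'   by protein (alignment row order) then `coding_offset`.
#' @export
project_sites <- function(alignment, sites) {
  check_alignment(alignment)
  unknown <- setdiff(unique(sites$gene_id), names(alignment))
  if (length(unknown) > 0L) {
    stop("sites refer to proteins missing from the alignment: ",
         paste(unknown, collapse = ", "))
  }
  out <- lapply(intersect(names(alignment), unique(sites$gene_id)),
                function(pid) {
    sub <- sites[sites$gene_id == pid, , drop = FALSE]
    sub <- sub[order(sub$coding_offset), , drop = FALSE]
    row <- alignment[[pid]]
    cols <- integer(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      idx <- sub$protein_index[i]
      if (idx > nchar(ungap(row))) {
        # boundary inside the terminal stop codon: no alignment column
        stop("protein '", pid, "': site at protein_index ", idx,
             " lies beyond the aligned protein (", nchar(ungap(row)),
             " residues)")
      }
      cols[i] <- residue_to_column(row, idx)
      aligned_res <- substr(row, cols[i], cols[i])
      if (aligned_res != sub$residue[i]) {
        stop("protein '", pid, "': residue mismatch at protein_index ", idx,
             " (site says '", sub$residue[i], "', alignment says '",
             aligned_res, "') - wrong alignment/protein pairing?")
      }
    }
    data.frame(protein_id = pid, column = cols, frame = sub$frame,
               residue = sub$residue, protein_index = sub$protein_index,
               coding_offset = sub$coding_offset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Unrolled nucleotide distance between two aligned splice-site calls
#'
#' Each alignment column spans three nucleotide slots on a codon grid; a
#' call at (column c, frame f) sits at slot `3 * (c - 1) + f`. Columns
#' gapped in *both* rows of the pair are deleted before computing the
#' distance, so that the distance reflects the two sequences' mutual
#' alignment rather than third-party gaps.
#'
#' @param a,b Single-row data frames (or lists) with `protein_id`, `column`,
#'   `frame`.
#' @param alignment The alignment both calls were projected from.
#' @return Non-negative integer nucleotide distance.
#' @export
aligned_nt_distance <- function(a, b, alignment) {
  row_a <- strsplit(alignment[[a$protein_id]], "")[[1L]]
  row_b <- strsplit(alignment[[b$protein_id]], "")[[1L]]
  keep <- !(row_a == "-" & row_b == "-")
  # rank of each original column among kept columns
  newcol <- cumsum(keep)
  ca <- newcol[a$column]
  cb <- newcol[b$column]
  abs((3L * (ca - 1L) + a$frame) - (3L * (cb - 1L) + b$frame))
}

#' Is a pair of calls a one-nucleotide intron shift?
#'
#' True when the unrolled nucleotide distance between the two exon
#' boundaries is exactly 1 (intron sliding by a single nucleotide); such
#' pairs are not counted as shared sites.
#'
#' @inheritParams aligned_nt_distance
#' @param window Maximum shift counted, in nucleotides (default 1).
#' @return Logical.
#' @export
detect_one_nt_shift <- function(a, b, alignment, window = 1L) {
  d <- aligned_nt_distance(a, b, alignment)
  d >= 1L && d <= window
}
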