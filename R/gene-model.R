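#' Construct a coding gene model
#'
#' A gene model is a strand-aware chain of coding exons on a named genomic
#' sequence. Intervals are stored in transcription order (5' to 3' of the
#' transcript), so for minus-strand genes the interval with the highest
#' genomic coordinates comes first. Coordinates are 1-based inclusive.
#'
#' @param gene_id Identifier for the gene/transcript.
#' @param seq_id Name of the genomic sequence the exons live on.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of exon start/end coordinates
#'   (1-based inclusive, `start <= end` for each exon). They may be given in
#'   any order; they are sorted into transcription order.
#' @param source_seq Optional genomic sequence (a single character string or
#'   a length-1 [Biostrings::DNAStringSet]) used to validate the coding
#'   sequence.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, starts, ends,
                       source_seq = NULL) {
  stopifnot(length(gene_id) == 1L, length(seq_id) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-', got '", strand, "'")
  }
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) != length(ends) || length(starts) == 0L) {
    stop("gene '", gene_id, "': starts and ends must be non-empty and of ",
         "equal length")
  }
  if (any(is.na(starts)) || any(is.na(ends)) ||
      any(starts < 1L) || any(ends < 1L)) {
    stop("gene '", gene_id, "': coordinates must be positive integers")
  }
  if (any(starts > ends)) {
    stop("gene '", gene_id, "': each interval needs start <= end")
  }
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  if (length(starts) > 1L &&
      any(starts[-1L] <= ends[-length(ends)])) {
    stop("gene '", gene_id, "': coding exons overlap")
  }
  if (strand == "-") {
    starts <- rev(starts)
    ends <- rev(ends)
  }
  model <- structure(
    list(gene_id = as.character(gene_id),
         seq_id = as.character(seq_id),
         strand = strand,
         intervals = data.frame(start = starts, end = ends),
         source_seq = source_seq_as_character(source_seq)),
    class = "gene_model")
  model
}

source_seq_as_character <- function(source_seq) {
  if (is.null(source_seq)) return(NULL)
  if (methods::is(source_seq, "DNAStringSet")) {
    stopifnot(length(source_seq) == 1L)
    return(as.character(source_seq[[1L]]))
  }
  if (methods::is(source_seq, "DNAString")) return(as.character(source_seq))
  stopifnot(is.character(source_seq), length(source_seq) == 1L)
  toupper(source_seq)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s), %d coding exon%s, %d coding nt\n",
              x$gene_id, x$seq_id, x$strand, n_exons(x),
              if (n_exons(x) == 1L) "" else "s", coding_length(x)))
  invisible(x)
}

n_exons <- function(model) nrow(model$intervals)

exon_lengths <- function(model) {
  model$intervals$end - model$intervals$start + 1L
}

#' Total coding length of a gene model in nucleotides
#' @param model A `gene_model`.
#' @return Integer number of coding nucleotides.
#' @export
coding_length <- function(model) sum(exon_lengths(model))

#' Extract the coding sequence of a gene model
#'
#' Concatenates the coding exons in transcription order; minus-strand
#' models are reverse-complemented so the result reads 5' to 3' of the
#' coding strand.
#'
#' @param model A `gene_model`.
#' @param genomic Genomic sequence; defaults to the model's `source_seq`.
#' @return The CDS as a single character string.
#' @export
coding_sequence <- function(model, genomic = model$source_seq) {
  if (is.null(genomic)) {
    stop("gene '", model$gene_id, "': no genomic sequence available")
  }
  genomic <- source_seq_as_character(genomic)
  if (max(model$intervals$end) > nchar(genomic)) {
    stop("gene '", model$gene_id, "': intervals extend past the end of the ",
         "genomic sequence")
  }
  pieces <- substring(genomic, model$intervals$start, model$intervals$end)
  if (model$strand == "-") {
    pieces <- vapply(pieces, revcomp, character(1L), USE.NAMES = FALSE)
  }
  paste(pieces, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Validate a gene model as a complete coding region
#'
#' Checks that the coding length is divisible by three and, when genomic
#' sequence is available, that the CDS starts with ATG, ends with a stop
#' codon and contains no internal stop codon.
#'
#' @param model A `gene_model`.
#' @param genomic Optional genomic sequence overriding the model's own.
#' @return The model, invisibly; errors describe the offending gene.
#' @export
validate_gene_model <- function(model, genomic = model$source_seq) {
  len <- coding_length(model)
  if (len %% 3L != 0L) {
    stop("gene '", model$gene_id, "': coding length ", len,
         " is not divisible by 3")
  }
  if (!is.null(genomic)) {
    cds <- coding_sequence(model, genomic)
    translate_cds(cds, gene_id = model$gene_id)  # errors on internal stop
    if (substr(cds, 1L, 3L) != "ATG") {
      stop("gene '", model$gene_id, "': CDS does not start with ATG ",
           "(complete start-to-stop models are required)")
    }
    last <- substr(cds, len - 2L, len)
    if (!last %in% STOP_CODONS) {
      stop("gene '", model$gene_id, "': CDS does not end with a stop codon ",
           "(complete start-to-stop models are required)")
    }
  }
  invisible(model)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a coding sequence
#'
#' Standard genetic code. A terminal stop codon is translated and stripped;
#' an internal stop codon is an error, as is a length not divisible by 3.
#'
#' @param cds Nucleotide sequence (character string or
#'   [Biostrings::DNAString]).
#' @param gene_id Optional identifier used in error messages.
#' @return Amino-acid sequence as a character string (no stop symbol).
#' @export
translate_cds <- function(cds, gene_id = NULL) {
  cds <- toupper(as.character(cds))
  who <- if (is.null(gene_id)) "CDS" else paste0("gene '", gene_id, "'")
  if (nchar(cds) %% 3L != 0L) {
    stop(who, ": length ", nchar(cds), " is not divisible by 3")
  }
  if (grepl("[^ACGT]", cds)) {
    stop(who, ": CDS contains characters other than A/C/G/T")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  stars <- gregexpr("*", aa, fixed = TRUE)[[1L]]
  if (stars[1L] != -1L) {
    internal <- stars[stars != nchar(aa)]
    if (length(internal) > 0L) {
      stop(who, ": internal stop codon at codon ", internal[1L])
    }
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  }
  aa
}
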