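#' Read sequences from a FASTA file
#'
#' @param path FASTA file (any line width).
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"DNA"` or `"AA"`.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA"), width = 70L) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse gene models from a GFF3 document
#'
#' Reads CDS features and assembles one `gene_model` per coding transcript.
#' CDS features are grouped by their `Parent` attribute (falling back to
#' `gene_id`/`ID` when no parent is given). When `mRNA` features tie several
#' transcripts to one gene, only the transcript with the longest CDS is
#' kept and the choice is reported with a message.
#'
#' @param x Path to a GFF3 file, or a character vector of GFF3 lines.
#' @param genome Optional named character vector (or `DNAStringSet`) of
#'   genomic sequences; when given, each model gets its `source_seq` and is
#'   validated as a complete CDS.
#' @return List of `gene_model` objects (empty list for an empty document).
#' @export
parse_gff3 <- function(x, genome = NULL) {
  path <- as_gff3_path(x)
  check_gff3_lines(readLines(path, warn = FALSE))
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[as.character(gr$type) == "CDS"]
  if (length(cds) == 0L) return(list())

  parents <- S4Vectors::mcols(cds)$Parent
  key <- if (!is.null(parents)) {
    vapply(as.list(parents), function(p) {
      if (length(p) >= 1L) p[[1L]] else NA_character_
    }, character(1L))
  } else rep(NA_character_, length(cds))
  for (alt in c("gene_id", "ID", "gene")) {
    v <- S4Vectors::mcols(cds)[[alt]]
    if (!is.null(v)) key[is.na(key)] <- as.character(v)[is.na(key)]
  }
  if (anyNA(key)) {
    stop("GFF3 parse error: CDS feature without Parent/gene_id/ID attribute")
  }

  models <- lapply(split(seq_along(cds), key), function(idx) {
    sub <- cds[idx]
    seq_ids <- unique(as.character(GenomicRanges::seqnames(sub)))
    strands <- unique(as.character(BiocGenerics::strand(sub)))
    gene_id <- key[idx][1L]
    if (length(seq_ids) != 1L || length(strands) != 1L) {
      stop("gene '", gene_id, "': CDS features span several sequences or ",
           "strands")
    }
    if (!strands %in% c("+", "-")) {
      stop("gene '", gene_id, "': CDS features need an explicit strand")
    }
    src <- NULL
    if (!is.null(genome)) {
      genome_chr <- if (methods::is(genome, "DNAStringSet"))
        as.character(genome) else genome
      if (!seq_ids %in% names(genome_chr)) {
        stop("gene '", gene_id, "': sequence '", seq_ids,
             "' not found in the supplied genome")
      }
      src <- genome_chr[[seq_ids]]
    }
    m <- gene_model(gene_id, seq_ids, strands,
                    BiocGenerics::start(sub), BiocGenerics::end(sub),
                    source_seq = src)
    validate_gene_model(m)
    m
  })
  names(models) <- NULL

  models <- keep_longest_transcript(models, gr)
  models
}

as_gff3_path <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) &&
      (file.exists(x) || grepl("\\.gff3?$", x))) {
    if (!file.exists(x)) stop("GFF3 file not found: ", x)
    return(x)
  }
  lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

check_gff3_lines <- function(lines) {
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  for (i in which(body)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop("GFF3 parse error at line ", i, ": expected 9 tab-separated ",
           "fields, found ", length(fields))
    }
    if (is.na(suppressWarnings(as.integer(fields[4L]))) ||
        is.na(suppressWarnings(as.integer(fields[5L])))) {
      stop("GFF3 parse error at line ", i, ": non-numeric coordinates")
    }
  }
  invisible(TRUE)
}

keep_longest_transcript <- function(models, gr) {
  mrna <- gr[as.character(gr$type) %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) return(models)
  parents <- S4Vectors::mcols(mrna)$Parent
  if (is.null(parents)) return(models)
  tx2gene <- vapply(as.list(parents), function(p) {
    if (length(p) >= 1L) p[[1L]] else NA_character_
  }, character(1L))
  names(tx2gene) <- as.character(S4Vectors::mcols(mrna)$ID)
  ids <- vapply(models, function(m) m$gene_id, character(1L))
  genes <- tx2gene[ids]
  keep <- rep(TRUE, length(models))
  for (g in unique(stats::na.omit(genes))) {
    idx <- which(!is.na(genes) & genes == g)
    if (length(idx) > 1L) {
      lens <- vapply(models[idx], coding_length, integer(1L))
      best <- idx[which.max(lens)]
      message("gene '", g, "': keeping longest CDS transcript '",
              ids[best], "' (", max(lens), " nt) out of ",
              length(idx), " transcripts")
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  models[keep]
}

#' Write gene models as GFF3
#'
#' Emits a `##gff-version 3` pragma and one CDS feature per coding exon,
#' with `ID` and `Parent` attributes naming the transcript.
#'
#' @param models List of `gene_model` objects (or a single model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    iv <- m$intervals  # transcription order
    # GFF3 phase: bases to trim from the feature's 5' end to hit a codon
    phase <- (3L - c(0L, cumsum(iv$end - iv$start + 1L)[-nrow(iv)]) %% 3L) %%
      3L
    data.frame(seq_id = m$seq_id, start = iv$start, end = iv$end,
               strand = m$strand, phase = phase,
               ID = sprintf("%s.cds%d", m$gene_id, seq_len(nrow(iv))),
               Parent = m$gene_id, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  ord <- order(rows$seq_id, rows$start)
  rows <- rows[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seq_id,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand,
    type = "CDS",
    source = "spliceshare",
    phase = rows$phase,
    ID = rows$ID,
    Parent = rows$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
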