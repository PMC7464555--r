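#' Derive coding splice sites from a gene model
#'
#' Each internal coding-exon boundary is labelled by the protein residue
#' whose codon contains the exon's last nucleotide, together with the codon
#' position (frame +1/+2/+3) of that nucleotide. A boundary whose last exon
#' nucleotide is the k-th nucleotide of the CDS therefore gets
#' `protein_index = ceiling(k / 3)` and `frame = k - 3 * (protein_index - 1)`,
#' so that `coding_offset = 3 * (protein_index - 1) + frame` always holds.
#' In intron-phase terms, phase-0/1/2 introns correspond to frames +3/+1/+2.
#'
#' @param model A `gene_model`.
#' @param cds_protein The translation of the model's CDS (terminal stop
#'   stripped). If `NULL` and the model carries genomic sequence, it is
#'   translated on the fly.
#' @return A data frame with one row per internal exon boundary, columns
#'   `gene_id`, `protein_index`, `residue`, `frame`, `coding_offset`,
#'   `label` (e.g. `"V217.frame+2"`), sorted by `coding_offset`. A boundary
#'   inside the terminal stop codon is legal and reported with
#'   `protein_index = protein length + 1` and residue `"*"`, with a warning.
#' @export
derive_coding_splice_sites <- function(model, cds_protein = NULL) {
  if (is.null(cds_protein)) {
    cds_protein <- translate_cds(coding_sequence(model),
                                 gene_id = model$gene_id)
  }
  len <- coding_length(model)
  if (len %% 3L != 0L) {
    stop("gene '", model$gene_id, "': coding length ", len,
         " is not divisible by 3")
  }
  n_res <- nchar(cds_protein)
  if (n_res != len %/% 3L - 1L && n_res != len %/% 3L) {
    stop("gene '", model$gene_id, "': protein length ", n_res,
         " does not match coding length ", len,
         " (expected ", len %/% 3L - 1L, " residues plus a stop codon)")
  }
  offsets <- cumsum(exon_lengths(model))
  offsets <- offsets[-length(offsets)]  # internal boundaries only
  sites_from_offsets(model$gene_id, offsets, cds_protein)
}

sites_from_offsets <- function(gene_id, offsets, protein) {
  offsets <- as.integer(offsets)
  protein_index <- as.integer(ceiling(offsets / 3))
  frame <- offsets - 3L * (protein_index - 1L)
  n_res <- nchar(protein)
  residue <- character(length(offsets))
  for (i in seq_along(offsets)) {
    if (protein_index[i] <= n_res) {
      residue[i] <- substr(protein, protein_index[i], protein_index[i])
    } else {
      warning("gene '", gene_id, "': exon boundary inside the terminal ",
              "stop codon (assigned protein_index ", protein_index[i], ")")
      residue[i] <- "*"
    }
  }
  out <- data.frame(
    gene_id = rep(as.character(gene_id), length(offsets)),
    protein_index = protein_index,
    residue = residue,
    frame = frame,
    coding_offset = offsets,
    stringsAsFactors = FALSE)
  out <- out[order(out$coding_offset), , drop = FALSE]
  rownames(out) <- NULL
  out$label <- sprintf("%s%d.frame+%d", out$residue, out$protein_index,
                       out$frame)
  out
}

#' Write / read a splice-site table
#'
#' Tab-delimited, columns `gene_id`, `protein_index`, `residue`, `frame`,
#' `coding_offset`, `label`.
#'
#' @param sites Data frame as returned by [derive_coding_splice_sites()].
#' @param path Output (or input) file path.
#' @return `write_site_table()` returns `path` invisibly;
#'   `read_site_table()` returns the data frame.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("gene_id", "protein_index", "residue", "frame", "coding_offset",
            "label")
  utils::write.table(sites[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character",
                                   residue = "character",
                                   label = "character"))
}
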