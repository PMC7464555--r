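#' Synthetic tunicate GH6 example family
#'
#' Builds a fully synthetic ten-gene family that mirrors the splice-site
#' annotations reported for tunicate GH6-1 proteins and one larvacean CesA
#' gene: three shared splice-site columns (frames +2, +1, +3), per-protein
#' "no splice site" absences with conserved or non-conserved residues, and
#' a CesA site that aligns with the third column but is shifted by one
#' nucleotide (frame +2 instead of +3). Everything here is constructed:
#' the scaffold alignment places the documented residue indices in common
#' columns, the protein sequences are random outside the documented
#' residues, and each gene's genomic sequence is emitted with GT..AG
#' introns at the implied coding offsets. It is an illustration and test
#' harness, not a reconstruction of any real alignment.
#'
#' @param seed Seed for the random filler residues and intron cores.
#' @param intron_length Length of the planted introns.
#' @return A list with `alignment` (named gapped rows), `proteins`,
#'   `models` (named list of `gene_model` with genomic `source_seq`),
#'   `site_spec` (data frame of the planted sites: `protein_id`,
#'   `protein_index`, `frame`, `anchor` 0/1/2/3 marking which shared column
#'   a site belongs to, 0 = private), `reference` (the reference protein
#'   id).
#' @export
synthetic_gh6_family <- function(seed = 42L, intron_length = 30L) {
  set.seed(seed)
  spec <- data.frame(
    protein_id = c("CinGH6-1", "CsaGH6-1", "SthGH6-1a", "SthGH6-1b",
                   "MoxGH6-1", "MocGH6-1", "BscGH6-1", "BleGH6-1",
                   "OdiGH6-1", "OdiCesA1"),
    i1 = c(217L, 223L, 229L, 230L, 222L, 222L, 335L, 229L, 244L, 1001L),
    i2 = c(256L, 262L, 268L, 269L, 260L, 260L, 373L, 285L, 282L, 1040L),
    i3 = c(316L, 322L, 328L, 329L, 320L, 320L, 433L, 345L, 343L, 1100L),
    r1 = c("V", "V", "E", "K", "R", "R", "K", "K", "N", "R"),
    r2 = c("G", "G", "G", "G", "G", "G", "G", "G", "G", "G"),
    r3 = c("K", "K", "P", "K", "A", "A", "A", "A", "K", "R"),
    m1 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    m2 = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    m3 = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    # CesA carries a +2 site in the third column: one nucleotide off
    shifted3 = c(rep(FALSE, 9L), TRUE),
    n_introns = c(3L, 3L, 6L, 5L, 3L, 2L, 5L, 4L, 6L, 8L),
    stringsAsFactors = FALSE)

  c1 <- max(spec$i1)
  c2 <- c1 + max(spec$i2 - spec$i1)
  c3 <- c2 + max(spec$i3 - spec$i2)
  tail_len <- 20L
  width <- c3 + tail_len

  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], character())
  proteins <- character(nrow(spec))
  rows <- character(nrow(spec))
  for (p in seq_len(nrow(spec))) {
    L <- spec$i3[p] + tail_len
    seq <- sample(aas, L, replace = TRUE)
    seq[1L] <- "M"
    seq[spec$i1[p]] <- spec$r1[p]
    seq[spec$i2[p]] <- spec$r2[p]
    seq[spec$i3[p]] <- spec$r3[p]
    proteins[p] <- paste(seq, collapse = "")
    rows[p] <- paste0(
      strrep("-", c1 - spec$i1[p]),
      paste(seq[1:spec$i1[p]], collapse = ""),
      strrep("-", (c2 - c1) - (spec$i2[p] - spec$i1[p])),
      paste(seq[(spec$i1[p] + 1L):spec$i2[p]], collapse = ""),
      strrep("-", (c3 - c2) - (spec$i3[p] - spec$i2[p])),
      paste(seq[(spec$i2[p] + 1L):spec$i3[p]], collapse = ""),
      paste(seq[(spec$i3[p] + 1L):L], collapse = ""))
    rows[p] <- paste0(rows[p], strrep("-", width - nchar(rows[p])))
  }
  names(rows) <- names(proteins) <- spec$protein_id

  # private (unshared) sites fill each protein up to its intron count; all
  # are placed at globally distinct alignment columns in the region left of
  # the first shared column, with frame +3, so none can collide with or sit
  # one nucleotide from a shared site
  used_cols <- c(c1, c2, c3)
  site_spec <- list()
  for (p in seq_len(nrow(spec))) {
    pid <- spec$protein_id[p]
    anchors <- data.frame(
      protein_id = pid,
      protein_index = c(spec$i1[p], spec$i2[p], spec$i3[p]),
      frame = c(2L, 1L, if (spec$shifted3[p]) 2L else 3L),
      anchor = 1:3,
      keep = c(spec$m1[p], spec$m2[p], spec$m3[p] | spec$shifted3[p]),
      stringsAsFactors = FALSE)
    anchors <- anchors[anchors$keep, setdiff(names(anchors), "keep")]
    n_extra <- spec$n_introns[p] - nrow(anchors)
    stopifnot(n_extra >= 0L)
    extras <- integer(0L)
    r <- 5L
    while (length(extras) < n_extra) {
      col <- c1 - spec$i1[p] + r
      if (!col %in% used_cols && r < spec$i1[p] - 2L) {
        extras <- c(extras, r)
        used_cols <- c(used_cols, col)
      }
      r <- r + 2L
      if (r >= spec$i1[p]) stop("ran out of room for private sites")
    }
    if (n_extra > 0L) {
      anchors <- rbind(anchors, data.frame(
        protein_id = pid, protein_index = extras,
        frame = 3L, anchor = 0L, stringsAsFactors = FALSE))
    }
    site_spec[[p]] <- anchors
  }
  site_spec <- do.call(rbind, site_spec)
  rownames(site_spec) <- NULL

  # emit one gene model per protein with introns at the implied offsets
  codon_of <- stats::setNames(
    c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT", "AAA", "CTT",
      "ATG", "AAT", "CCT", "CAA", "CGT", "TCT", "ACT", "GTT", "TGG", "TAT"),
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])
  models <- list()
  for (p in seq_len(nrow(spec))) {
    pid <- spec$protein_id[p]
    aa <- strsplit(proteins[[pid]], "")[[1L]]
    cds <- paste0(paste(codon_of[aa], collapse = ""), "TAA")
    offs <- site_spec[site_spec$protein_id == pid, ]
    offsets <- sort(3L * (offs$protein_index - 1L) + offs$frame)
    pieces <- character(0L)
    prev <- 0L
    pos <- 0L
    starts <- ends <- integer(length(offsets) + 1L)
    for (k in seq_along(offsets)) {
      exon <- substr(cds, prev + 1L, offsets[k])
      core <- paste(sample(c("A", "C", "G", "T"), intron_length - 4L,
                           replace = TRUE), collapse = "")
      starts[k] <- pos + 1L
      pos <- pos + nchar(exon)
      ends[k] <- pos
      pos <- pos + intron_length
      pieces <- c(pieces, exon, paste0("GT", core, "AG"))
      prev <- offsets[k]
    }
    exon <- substr(cds, prev + 1L, nchar(cds))
    starts[length(starts)] <- pos + 1L
    ends[length(ends)] <- pos + nchar(exon)
    genome <- paste(c(pieces, exon), collapse = "")
    models[[pid]] <- gene_model(pid, paste0("scaffold_", pid), "+",
                                starts, ends, source_seq = genome)
  }

  list(alignment = rows, proteins = proteins, models = models,
       site_spec = site_spec, reference = "CinGH6-1",
       shared_columns = c(c1, c2, c3))
}
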