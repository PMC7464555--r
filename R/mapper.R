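#' Map a coding sequence onto genomic sequence (exact-match spliced model)
#'
#' Finds the exon chain that reproduces `cds` exactly after excising zero or
#' more introns from `genomic`. Every intron must be at least `min_intron`
#' nucleotides long and flanked by an allowed donor..acceptor dinucleotide
#' pair (canonical GT..AG by default; GC..AG can be enabled). The genomic
#' sequence is taken to be the gene region itself in coding orientation:
#' the first exon starts at position 1 and the last exon ends at the last
#' position. This is deliberately an exact-match mapper for curated or
#' simulated input, not a spliced aligner for noisy data.
#'
#' When several exon chains are consistent, the chain that opens each intron
#' at the leftmost possible genomic position (and, for a tied start, uses
#' the shortest intron) is returned and the result is flagged ambiguous.
#'
#' @param cds Coding sequence (character string).
#' @param genomic Genomic sequence (character string), coding orientation.
#' @param min_intron Minimum intron length (>= 4).
#' @param allow_gc_donor Also accept GC..AG introns.
#' @param gene_id,seq_id Identifiers for the returned model.
#' @return A `gene_model` with an extra logical element `ambiguous`.
#' @export
map_cds_to_genome <- function(cds, genomic, min_intron = 30L,
                              allow_gc_donor = FALSE,
                              gene_id = "mapped", seq_id = "genomic") {
  cds <- toupper(as.character(cds))
  genomic <- toupper(as.character(genomic))
  stopifnot(min_intron >= 4L)
  cv <- strsplit(cds, "")[[1L]]
  gv <- strsplit(genomic, "")[[1L]]
  C <- length(cv)
  G <- length(gv)
  if (C == 0L) stop("mapping failed: empty CDS")
  if (G < C) stop("mapping failed: genomic sequence shorter than CDS")

  donors <- if (allow_gc_donor) c("GT", "GC") else "GT"
  # positions where an intron may start / end
  di <- paste0(gv[-G], gv[-1L])
  donor_pos <- which(di %in% donors)                 # intron start s
  acceptor_end <- which(di == "AG") + 1L             # intron end e
  is_donor <- logical(G); is_donor[donor_pos] <- TRUE

  memo <- new.env(hash = TRUE, parent = emptyenv())

  # number of consistent chains (capped at 2) from state (ci, gi):
  # cds[ci..C] remains to be produced from genomic[gi..G]
  count <- function(ci, gi) {
    key0 <- paste0(ci, ":", gi)
    hit <- memo[[key0]]
    if (!is.null(hit)) return(hit)
    ci0 <- ci; gi0 <- gi
    total <- 0L
    repeat {
      if (ci > C) { total <- if (gi == G + 1L) 1L else 0L; break }
      if (gi > G) { total <- 0L; break }
      if (ci >= 2L && is_donor[gi]) {
        # branch: open an intron here (boundary after cds position ci-1)
        ends <- acceptor_end[acceptor_end >= gi + min_intron - 1L &
                             acceptor_end <= G - (C - ci + 1L)]
        for (e in ends) {
          total <- total + count(ci, e + 1L)
          if (total >= 2L) break
        }
        if (total >= 2L) { total <- 2L; break }
      }
      if (gv[gi] == cv[ci]) { ci <- ci + 1L; gi <- gi + 1L }
      else break
    }
    total <- min(total, 2L)
    memo[[paste0(ci0, ":", gi0)]] <- total
    total
  }

  n_sol <- count(1L, 1L)
  if (n_sol == 0L) {
    stop("mapping failed: no exon chain reproduces the CDS with ",
         paste(donors, collapse = "/"), "..AG introns of length >= ",
         min_intron)
  }

  # reconstruct the preferred chain: at each branch point prefer the
  # leftmost intron start, then the shortest intron, then plain matching
  introns <- list()
  ci <- 1L; gi <- 1L
  repeat {
    if (ci > C) break
    placed <- FALSE
    if (ci >= 2L && is_donor[gi]) {
      ends <- acceptor_end[acceptor_end >= gi + min_intron - 1L &
                           acceptor_end <= G - (C - ci + 1L)]
      for (e in ends) {
        if (count(ci, e + 1L) > 0L) {
          introns[[length(introns) + 1L]] <- c(gi, e)
          gi <- e + 1L
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) { ci <- ci + 1L; gi <- gi + 1L }
  }

  if (length(introns) == 0L) {
    starts <- 1L; ends <- G
  } else {
    im <- do.call(rbind, introns)
    starts <- c(1L, im[, 2L] + 1L)
    ends <- c(im[, 1L] - 1L, G)
  }
  model <- gene_model(gene_id, seq_id, "+", starts, ends,
                      source_seq = genomic)
  model$ambiguous <- n_sol >= 2L
  if (model$ambiguous) {
    warning("gene '", gene_id, "': several exon chains are consistent; ",
            "returning the leftmost-intron-start chain (flagged ambiguous)")
  }
  stopifnot(coding_sequence(model) == cds)
  model
}
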