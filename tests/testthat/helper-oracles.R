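# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (nucleotide-by-nucleotide unrolling, exhaustive
# enumeration) and share no code with the implementation they check.

# --- splice-site labelling oracle: walk the CDS one nucleotide at a time,
# tracking codon position and residue count, and record each cumulative
# exon boundary.
oracle_sites <- function(exon_lengths, protein) {
  boundaries <- cumsum(exon_lengths)
  boundaries <- boundaries[-length(boundaries)]
  res_idx <- 0L
  codon_pos <- 0L
  out <- NULL
  for (nt in seq_len(sum(exon_lengths))) {
    codon_pos <- codon_pos + 1L
    if (codon_pos == 1L) res_idx <- res_idx + 1L
    if (nt %in% boundaries) {
      residue <- if (res_idx <= nchar(protein))
        substr(protein, res_idx, res_idx) else "*"
      out <- rbind(out, data.frame(protein_index = res_idx,
                                   residue = residue,
                                   frame = codon_pos,
                                   coding_offset = nt))
    }
    if (codon_pos == 3L) codon_pos <- 0L
  }
  out
}

# --- exact-match spliced mapping oracle: enumerate every way to excise
# 0, 1 or 2 introns from `genomic` so that the exons spell `cds`. Returns
# the list of solutions (each a matrix of intron start/end pairs), sorted
# in the mapper's documented preference order (leftmost intron start, then
# shortest intron). Only valid when 3 introns cannot fit (D < 3*min_intron).
oracle_map <- function(cds, genomic, min_intron, donors = "GT") {
  C <- nchar(cds); G <- nchar(genomic); D <- G - C
  stopifnot(D < 3L * min_intron)
  ok_intron <- function(s) {
    substr(s, 1L, 2L) %in% donors &&
      substr(s, nchar(s) - 1L, nchar(s)) == "AG"
  }
  sols <- list()
  if (D == 0L && cds == genomic) {
    sols[[1L]] <- matrix(integer(), ncol = 2L)
  }
  if (D >= min_intron) {
    for (s in 1:(C - 1L)) {
      rebuilt <- paste0(substr(cds, 1L, s),
                        substr(genomic, s + 1L, s + D),
                        substr(cds, s + 1L, C))
      if (rebuilt == genomic && ok_intron(substr(genomic, s + 1L, s + D))) {
        sols[[length(sols) + 1L]] <- matrix(c(s + 1L, s + D), ncol = 2L,
                                            byrow = TRUE)
      }
    }
  }
  if (D >= 2L * min_intron && C >= 3L) {
    for (s1 in 1:(C - 2L)) for (s2 in (s1 + 1L):(C - 1L)) {
      for (l1 in min_intron:(D - min_intron)) {
        l2 <- D - l1
        i1 <- substr(genomic, s1 + 1L, s1 + l1)
        i2_start <- s2 + l1 + 1L
        i2 <- substr(genomic, i2_start, i2_start + l2 - 1L)
        rebuilt <- paste0(substr(cds, 1L, s1), i1,
                          substr(cds, s1 + 1L, s2), i2,
                          substr(cds, s2 + 1L, C))
        if (rebuilt == genomic && ok_intron(i1) && ok_intron(i2)) {
          sols[[length(sols) + 1L]] <- matrix(
            c(s1 + 1L, s1 + l1, i2_start, i2_start + l2 - 1L),
            ncol = 2L, byrow = TRUE)
        }
      }
    }
  }
  if (length(sols) <= 1L) return(sols)
  keys <- vapply(sols, function(m) paste(sprintf("%06d", t(m)),
                                         collapse = ""), character(1L))
  sols[order(keys)]
}

# intron matrix -> exon start/end vectors on the genomic sequence
oracle_exons <- function(introns, G) {
  if (nrow(introns) == 0L) return(list(start = 1L, end = G))
  list(start = c(1L, introns[, 2L] + 1L),
       end = c(introns[, 1L] - 1L, G))
}

# --- PROSITE oracle: enumerate all repeat expansions of a parsed pattern,
# then test each expansion at each start by direct character comparison.
oracle_prosite_matches <- function(pattern, seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  el_ok <- function(el, ch) {
    if (el$type == "any") return(TRUE)
    if (el$type == "fixed") return(ch == el$residues)
    if (el$type == "class") return(ch %in% el$residues)
    ch != "X" && !(ch %in% el$residues)  # negated
  }
  # all repeat-count assignments
  counts <- lapply(pattern$elements, function(e) e$min:e$max)
  grids <- expand.grid(counts)
  out <- NULL
  for (start in seq_along(chars)) {
    best_len <- -1L
    for (g in seq_len(nrow(grids))) {
      flat <- unlist(lapply(seq_along(pattern$elements), function(i) {
        rep(list(pattern$elements[[i]]), grids[g, i])
      }), recursive = FALSE)
      L <- length(flat)
      if (start + L - 1L > length(chars)) next
      if (pattern$anchor_start && start != 1L) next
      if (pattern$anchor_end && start + L - 1L != length(chars)) next
      hit <- all(vapply(seq_len(L), function(i)
        el_ok(flat[[i]], chars[start + i - 1L]), logical(1L)))
      if (hit) best_len <- max(best_len, L)
    }
    if (best_len >= 0L) {
      out <- rbind(out, data.frame(start = start,
                                   end = start + best_len - 1L))
    }
  }
  if (is.null(out)) data.frame(start = integer(), end = integer()) else out
}

# random small PROSITE pattern over a reduced alphabet
random_prosite_pattern <- function() {
  alphabet <- c("A", "C", "D", "E", "G")
  n <- sample(1:5, 1L)
  toks <- vapply(seq_len(n), function(i) {
    type <- sample(c("fixed", "any", "class", "negated"), 1L)
    tok <- switch(type,
      fixed = sample(alphabet, 1L),
      any = "x",
      class = paste0("[", paste(sample(alphabet, sample(1:3, 1L)),
                                collapse = ""), "]"),
      negated = paste0("{", paste(sample(alphabet, sample(1:2, 1L)),
                                  collapse = ""), "}"))
    if (stats::runif(1) < 0.3) {
      lo <- sample(1:2, 1L)
      hi <- lo + sample(0:1, 1L)
      tok <- paste0(tok, if (lo == hi) sprintf("(%d)", lo) else
                    sprintf("(%d,%d)", lo, hi))
    }
    tok
  }, character(1L))
  paste(toks, collapse = "-")
}

# --- small builders ------------------------------------------------------

NTS <- c("A", "C", "G", "T")

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(spliceshare:::SENSE_CODONS, n_codons - 2L,
                      replace = TRUE), collapse = ""),
         "TAA")
}

random_intron <- function(len) {
  paste0("GT", paste(sample(NTS, len - 4L, replace = TRUE), collapse = ""),
         "AG")
}

# insert introns of the given lengths after the given coding offsets
insert_introns <- function(cds, offsets, lens) {
  ord <- order(offsets)
  offsets <- offsets[ord]; lens <- lens[ord]
  pieces <- character(0L)
  prev <- 0L
  for (k in seq_along(offsets)) {
    pieces <- c(pieces, substr(cds, prev + 1L, offsets[k]),
                random_intron(lens[k]))
    prev <- offsets[k]
  }
  paste(c(pieces, substr(cds, prev + 1L, nchar(cds))), collapse = "")
}

# run the whole pipeline on a simulated family and score against truth
recover_family <- function(fam, min_intron = 30L) {
  models <- lapply(names(fam$genomes), function(tx)
    map_cds_to_genome(fam$cds[[tx]], fam$genomes[[tx]],
                      min_intron = min_intron, gene_id = tx, seq_id = tx))
  names(models) <- names(fam$genomes)
  sites <- do.call(rbind, lapply(names(models), function(tx)
    derive_coding_splice_sites(models[[tx]], fam$proteins[[tx]])))
  al <- identity_alignment(fam$proteins)
  groups <- classify_site_groups(project_sites(al, sites), al)
  list(models = models, sites = sites, groups = groups,
       recovery = evaluate_recovery(fam, groups))
}

# classify the synthetic GH6 family end to end (models -> table)
classify_gh6_fixture <- function(fx) {
  sites <- do.call(rbind, lapply(names(fx$models), function(id)
    derive_coding_splice_sites(
      fx$models[[id]],
      translate_cds(coding_sequence(fx$models[[id]]), id))))
  calls <- project_sites(fx$alignment, sites)
  groups <- classify_site_groups(calls, fx$alignment,
                                 reference_protein = fx$reference)
  list(sites = sites, calls = calls, groups = groups,
       table = render_site_table(groups))
}
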