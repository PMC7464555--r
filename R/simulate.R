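#' Configuration for the gene-family simulator
#'
#' Defaults emulate a small family of orthologous genes on an 8-taxon
#' tunicate-like tree: a set of ancestral intron positions present at the
#' root, branch-specific intron gains and losses, and nucleotide
#' substitutions without indels, so that the true homology of every intron
#' position is known exactly and the proteins align as the identity
#' mapping.
#'
#' @param tree Newick string with branch lengths.
#' @param n_ancestral_introns Introns present in the root gene.
#' @param gain_rate,loss_rate Events per unit branch length (Poisson).
#' @param n_gains,n_losses Optional fixed event counts; when given they
#'   override the rates and exactly that many events are placed on branches
#'   drawn with probability proportional to branch length.
#' @param substitution_prob Per-site nucleotide substitution probability per
#'   unit branch length (applied as `1 - exp(-prob * length)` per branch).
#' @param intron_length Length range (min, max) for intron sequences; the
#'   minimum must be at least the mapper's `min_intron`.
#' @param cds_length_codons Number of sense codons in the gene (the protein
#'   length); the emitted CDS additionally carries a terminal stop codon.
#' @param min_intron Minimum intron length enforced when verifying that
#'   spliced mapping of the emitted genome is unambiguous.
#' @param seed Integer seed; the whole simulation is reproducible given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    tree = default_family_tree(),
    n_ancestral_introns = 5L,
    gain_rate = 0, loss_rate = 0,
    n_gains = NULL, n_losses = NULL,
    substitution_prob = 0.05,
    intron_length = c(40L, 80L),
    cds_length_codons = 300L,
    min_intron = 30L,
    seed = 1L) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, substitution_prob >= 0,
            cds_length_codons >= 10L,
            length(intron_length) == 2L,
            intron_length[1L] <= intron_length[2L],
            intron_length[1L] >= min_intron)
  structure(list(tree = tree,
                 n_ancestral_introns = as.integer(n_ancestral_introns),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 n_gains = n_gains, n_losses = n_losses,
                 substitution_prob = substitution_prob,
                 intron_length = as.integer(intron_length),
                 cds_length_codons = as.integer(cds_length_codons),
                 min_intron = as.integer(min_intron),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default 8-taxon tunicate-like species tree
#'
#' Two larvacean-like taxa branch first, then phlebobranch-, thaliacean-
#' and stolidobranch-like clades; branch lengths are in arbitrary
#' substitution-like units.
#'
#' @return Newick string.
#' @export
default_family_tree <- function() {
  paste0("((Odi:0.8,Olo:0.8):0.5,((Cin:0.3,Csa:0.3):0.35,",
         "(Sth:0.5,((Mox:0.3,Bsc:0.3):0.15,Ble:0.45):0.05):0.15):0.35);")
}

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("T", "C", "A", "G"),
                                  c("T", "C", "A", "G"), paste0)),
                  c("T", "C", "A", "G"),
                  function(ab, c) paste0(substr(ab, 1, 1), substr(ab, 2, 2),
                                         c))),
  c("TAA", "TAG", "TGA"))

#' Simulate an orthologous gene family with known intron history
#'
#' Generates a root coding sequence (ATG + random sense codons + stop),
#' places ancestral introns at distinct coding offsets (kept at least 4 nt
#' apart so no two homology classes can be confused with a one-nucleotide
#' shift), evolves the gene down the tree with intron gains, losses and
#' nucleotide substitutions (no indels), and emits per-taxon genomic
#' sequences with GT..AG introns. Each emitted genome is verified to map
#' back to its planted exon chain unambiguously; intron sequences are
#' resampled otherwise.
#'
#' Draw order (single seeded generator): root codons; ancestral offsets;
#' then for each branch in cladewise order: losses, gains, substitutions;
#' finally per-tip intron lengths and cores in offset order.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_family`: `genomes`, `cds`,
#'   `proteins` (named character vectors), `models` (named list of
#'   `gene_model`), `truth` (data frame: `class_id`, `taxon`,
#'   `coding_offset`), `events` (per-branch event log), `tree` (an
#'   [ape::read.tree] phylo), `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$tree)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  ntip <- length(tree$tip.label)
  L <- config$cds_length_codons
  cds_len <- 3L * (L + 1L)

  root_cds <- paste0("ATG",
                     paste(sample(SENSE_CODONS, L - 1L, replace = TRUE),
                           collapse = ""),
                     "TAA")

  # offsets where an intron may sit: internal coding boundaries clear of the
  # start codon and the stop codon
  offset_pool <- 3L:(3L * L - 2L)
  registry <- integer()  # every offset ever used, for the 4-nt exclusion
  draw_offset <- function() {
    ok <- offset_pool[!offset_pool %in% as.vector(outer(registry, -3L:3L,
                                                        "+"))]
    if (length(ok) == 0L) {
      stop("unsatisfiable configuration: no intron offsets left under the ",
           "4-nt separation rule")
    }
    off <- if (length(ok) == 1L) ok else sample(ok, 1L)
    registry <<- c(registry, off)
    off
  }

  if (config$n_ancestral_introns > length(offset_pool) %/% 4L) {
    stop("unsatisfiable configuration: too many ancestral introns for a ",
         L, "-codon gene")
  }
  anc <- vapply(seq_len(config$n_ancestral_introns), function(i)
    draw_offset(), integer(1L))
  root_introns <- data.frame(
    class_id = sprintf("anc%d", seq_along(anc)),
    offset = anc, stringsAsFactors = FALSE)

  edges <- tree$edge
  n_edges <- nrow(edges)
  scheduled_gains <- scheduled_losses <- integer(n_edges)
  if (!is.null(config$n_gains) && config$n_gains > 0L) {
    picks <- sample.int(n_edges, config$n_gains, replace = TRUE,
                        prob = tree$edge.length)
    scheduled_gains <- tabulate(picks, n_edges)
  }
  if (!is.null(config$n_losses) && config$n_losses > 0L) {
    picks <- sample.int(n_edges, config$n_losses, replace = TRUE,
                        prob = tree$edge.length)
    scheduled_losses <- tabulate(picks, n_edges)
  }

  states <- vector("list", max(edges))
  root_node <- ntip + 1L
  states[[root_node]] <- list(cds = root_cds, introns = root_introns)
  gain_counter <- 0L
  events <- list()

  for (i in seq_len(n_edges)) {  # ape "cladewise" order is preorder
    parent <- edges[i, 1L]; child <- edges[i, 2L]
    bl <- tree$edge.length[i]
    st <- states[[parent]]
    introns <- st$introns

    # losses
    n_lose <- if (!is.null(config$n_losses)) {
      min(scheduled_losses[i], nrow(introns))
    } else if (nrow(introns) > 0L) {
      sum(stats::runif(nrow(introns)) > exp(-config$loss_rate * bl))
    } else 0L
    if (n_lose > 0L) {
      drop <- sample.int(nrow(introns), n_lose)
      for (d in drop) {
        events[[length(events) + 1L]] <- data.frame(
          edge = i, type = "loss", class_id = introns$class_id[d],
          offset = introns$offset[d], stringsAsFactors = FALSE)
      }
      introns <- introns[-drop, , drop = FALSE]
    }

    # gains
    n_gain <- if (!is.null(config$n_gains)) scheduled_gains[i]
              else stats::rpois(1L, config$gain_rate * bl)
    for (g in seq_len(n_gain)) {
      gain_counter <- gain_counter + 1L
      off <- draw_offset()
      introns <- rbind(introns, data.frame(
        class_id = sprintf("gain%d", gain_counter), offset = off,
        stringsAsFactors = FALSE))
      events[[length(events) + 1L]] <- data.frame(
        edge = i, type = "gain",
        class_id = sprintf("gain%d", gain_counter), offset = off,
        stringsAsFactors = FALSE)
    }

    # substitutions (start and stop codons protected; no new internal stop)
    cds <- mutate_cds(st$cds, 1 - exp(-config$substitution_prob * bl))

    states[[child]] <- list(cds = cds,
                            introns = introns[order(introns$offset), ,
                                              drop = FALSE])
  }

  taxa <- tree$tip.label
  genomes <- cds_out <- proteins <- stats::setNames(character(length(taxa)),
                                                    taxa)
  models <- stats::setNames(vector("list", length(taxa)), taxa)
  truth <- list()
  for (t in seq_along(taxa)) {
    taxon <- taxa[t]
    st <- states[[t]]
    emitted <- emit_genome(st$cds, st$introns$offset, config)
    genomes[[taxon]] <- emitted$genome
    cds_out[[taxon]] <- st$cds
    proteins[[taxon]] <- translate_cds(st$cds, gene_id = taxon)
    model <- gene_model(taxon, taxon, "+", emitted$starts, emitted$ends,
                        source_seq = emitted$genome)
    models[[taxon]] <- model
    if (nrow(st$introns) > 0L) {
      truth[[length(truth) + 1L]] <- data.frame(
        class_id = st$introns$class_id, taxon = taxon,
        coding_offset = st$introns$offset, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(class_id = character(), taxon = character(),
               coding_offset = integer(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  events <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(edge = integer(), type = character(), class_id = character(),
               offset = integer(), stringsAsFactors = FALSE)

  structure(list(genomes = genomes, cds = cds_out, proteins = proteins,
                 models = models, truth = truth, events = events,
                 tree = tree, config = config),
            class = "simulated_family")
}

# per-site substitution keeping ATG, the stop codon, and no internal stops
mutate_cds <- function(cds, p) {
  if (p <= 0) return(cds)
  chars <- strsplit(cds, "")[[1L]]
  n <- length(chars)
  mutable <- 4L:(n - 3L)
  hit <- mutable[stats::runif(length(mutable)) < p]
  nts <- c("A", "C", "G", "T")
  for (i in hit) {
    codon_start <- 3L * ((i - 1L) %/% 3L) + 1L
    alts <- sample(setdiff(nts, chars[i]))
    for (alt in alts) {
      trial <- chars[codon_start:(codon_start + 2L)]
      trial[i - codon_start + 1L] <- alt
      if (!paste(trial, collapse = "") %in% STOP_CODONS) {
        chars[i] <- alt
        break
      }
    }
  }
  paste(chars, collapse = "")
}

# insert GT..AG introns after the given coding offsets; resample cores until
# the exact-match mapper recovers the planted chain unambiguously
emit_genome <- function(cds, offsets, config, max_tries = 25L) {
  offsets <- sort(as.integer(offsets))
  if (length(offsets) == 0L) {
    return(list(genome = cds, starts = 1L, ends = nchar(cds)))
  }
  for (try in seq_len(max_tries)) {
    lens <- sample(seq(config$intron_length[1L], config$intron_length[2L]),
                   length(offsets), replace = TRUE)
    introns <- vapply(lens, function(l) {
      paste0("GT", paste(sample(c("A", "C", "G", "T"), l - 4L,
                                replace = TRUE), collapse = ""), "AG")
    }, character(1L))
    pieces <- character(0L)
    prev <- 0L
    starts <- ends <- integer(length(offsets) + 1L)
    pos <- 0L
    for (k in seq_along(offsets)) {
      exon <- substr(cds, prev + 1L, offsets[k])
      starts[k] <- pos + 1L
      pos <- pos + nchar(exon)
      ends[k] <- pos
      pos <- pos + nchar(introns[k])
      pieces <- c(pieces, exon, introns[k])
      prev <- offsets[k]
    }
    exon <- substr(cds, prev + 1L, nchar(cds))
    starts[length(starts)] <- pos + 1L
    ends[length(ends)] <- pos + nchar(exon)
    genome <- paste(c(pieces, exon), collapse = "")

    mapped <- tryCatch(
      suppressWarnings(map_cds_to_genome(cds, genome,
                                         min_intron = config$min_intron)),
      error = function(e) NULL)
    if (!is.null(mapped) && !mapped$ambiguous &&
        identical(mapped$intervals$start, starts) &&
        identical(mapped$intervals$end, ends)) {
      return(list(genome = genome, starts = starts, ends = ends))
    }
  }
  stop("could not emit an unambiguously mappable genome after ", max_tries,
       " attempts")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf(paste0("<simulated_family> %d taxa, %d intron homology ",
                     "classes, %d-codon gene, seed %d\n"),
              length(x$genomes), length(unique(x$truth$class_id)),
              x$config$cds_length_codons, x$config$seed))
  invisible(x)
}

#' Score predicted shared-site groups against simulator truth
#'
#' Membership assignments are (taxon, intron-homology-class) pairs; a
#' predicted group is matched to a truth class by coding-offset identity
#' (exact in the no-indel regime). Precision is the fraction of predicted
#' assignments that are true, recall the fraction of true assignments
#' recovered. With an empty prediction, precision is reported as 1.0 and
#' flagged.
#'
#' @param truth Truth table of a `simulated_family` (data frame with
#'   `taxon`, `coding_offset`), or the family itself.
#' @param predicted A `shared_site_groups` object predicted from the
#'   family's proteins and sites.
#' @return List with `precision`, `recall`, `f1`, `n_true`, `n_predicted`,
#'   `empty_prediction`.
#' @export
evaluate_recovery <- function(truth, predicted) {
  if (inherits(truth, "simulated_family")) truth <- truth$truth
  stopifnot(inherits(predicted, "shared_site_groups"))
  true_pairs <- paste(truth$taxon, truth$coding_offset)
  pred_pairs <- unlist(lapply(predicted$groups, function(g)
    paste(g$members$protein_id, g$members$coding_offset)))
  n_hit <- length(intersect(pred_pairs, true_pairs))
  empty <- length(pred_pairs) == 0L
  precision <- if (empty) 1.0 else n_hit / length(pred_pairs)
  recall <- if (length(true_pairs) == 0L) 1.0 else
    n_hit / length(true_pairs)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_true = length(true_pairs), n_predicted = length(pred_pairs),
       empty_prediction = empty)
}
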