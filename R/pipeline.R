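#' Build the identity alignment of a set of equal-length proteins
#'
#' In the simulator's default no-indel regime every protein has the same
#' length and the true alignment is the identity mapping: each row is the
#' ungapped protein itself.
#'
#' @param proteins Named character vector of ungapped sequences.
#' @return Named character vector usable wherever an alignment is expected.
#' @export
identity_alignment <- function(proteins) {
  if (length(unique(nchar(proteins))) != 1L) {
    stop("identity alignment needs equal-length proteins; lengths: ",
         paste(unique(nchar(proteins)), collapse = ", "))
  }
  check_alignment(proteins)
  proteins
}

#' Genomic co-location check for two gene models
#'
#' @param models Named list of `gene_model` objects.
#' @param id_a,id_b Gene ids to compare.
#' @return List with `same_sequence` (logical) and `distance` (base pairs
#'   between the nearest interval ends, 0 when the genes overlap, `NA` when
#'   they lie on different sequences).
#' @export
colocation_check <- function(models, id_a, id_b) {
  ids <- vapply(models, function(m) m$gene_id, character(1L))
  names(models) <- ids
  for (id in c(id_a, id_b)) {
    if (!id %in% ids) stop("unknown gene id: ", id)
  }
  a <- models[[id_a]]; b <- models[[id_b]]
  if (a$seq_id != b$seq_id) {
    return(list(same_sequence = FALSE, distance = NA_integer_))
  }
  a_lo <- min(a$intervals$start); a_hi <- max(a$intervals$end)
  b_lo <- min(b$intervals$start); b_hi <- max(b$intervals$end)
  distance <- if (a_hi < b_lo) b_lo - a_hi - 1L
              else if (b_hi < a_lo) a_lo - b_hi - 1L
              else 0L
  list(same_sequence = TRUE, distance = as.integer(distance))
}

# small stable rolling hash so reports can embed a config fingerprint
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the splice-site conservation pipeline end to end
#'
#' Stages (each optional, toggled by presence in the config): `simulate` a
#' family, or load real inputs (`gff` + `genome`, or `cds` + `genome`
#' FASTAs for spliced mapping); derive splice sites; `project` them onto a
#' protein alignment and classify shared groups; score `signatures`; run
#' the `catalytic` residue check; run the `colocation` check. Writes
#' `sites.tsv`, `shared_sites.tsv`, `signatures.tsv`, `catalytic.tsv`, a
#' `summary.json` (embedding a config fingerprint) and `run.log` under
#' `out_dir`. The pipeline is a pure function of (inputs, config, seed).
#'
#' @param config A list, or path to a YAML file. Recognised top-level keys:
#'   `out_dir`, `seed`, `simulate` (a list of [simulation_config()]
#'   arguments, or `TRUE` for defaults), `gff`, `genome`, `cds`,
#'   `min_intron`, `project` (list: `alignment` path or `"identity"`,
#'   `reference_protein`, `shift_window`), `signatures` (list: `pattern`,
#'   `accession`, `anchor_id`, `anchor_index`), `catalytic` (list:
#'   `ref_id`, `ref_protein_index`, `expected`), `colocation` (list:
#'   `id_a`, `id_b`).
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir is required")
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    writeLines(msg, log_con)
    message(msg)
  }
  say("spliceshare ", as.character(utils::packageVersion("spliceshare")),
      " | config ", config_hash(config))

  results <- list()
  models <- NULL; proteins <- NULL; truth <- NULL

  if (!is.null(config$simulate)) {
    say("stage simulate")
    args <- if (isTRUE(config$simulate)) list() else config$simulate
    if (!is.null(config$seed)) args$seed <- config$seed
    fam <- do.call(simulation_config, args)
    fam <- simulate_family(fam)
    results$family <- fam
    models <- fam$models
    proteins <- fam$proteins
    truth <- fam$truth
    write_fasta(fam$genomes, file.path(out_dir, "genomes.fa"), "DNA")
    write_fasta(fam$cds, file.path(out_dir, "cds.fa"), "DNA")
    write_fasta(fam$proteins, file.path(out_dir, "proteins.fa"), "AA")
    write_gff3(fam$models, file.path(out_dir, "models.gff3"))
    ape::write.tree(fam$tree, file.path(out_dir, "tree.nwk"))
    utils::write.table(fam$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!is.null(config$gff)) {
    say("stage load: ", config$gff)
    genome <- if (!is.null(config$genome)) read_fasta(config$genome, "DNA")
    models <- parse_gff3(config$gff, genome = genome)
    names(models) <- vapply(models, function(m) m$gene_id, character(1L))
    proteins <- vapply(models, function(m)
      translate_cds(coding_sequence(m), m$gene_id), character(1L))
  } else if (!is.null(config$cds)) {
    say("stage map: ", config$cds, " onto ", config$genome)
    cds <- read_fasta(config$cds, "DNA")
    genome <- read_fasta(config$genome, "DNA")
    min_intron <- if (is.null(config$min_intron)) 30L else
      as.integer(config$min_intron)
    models <- lapply(names(cds), function(id) {
      map_cds_to_genome(cds[[id]], genome[[id]], min_intron = min_intron,
                        gene_id = id, seq_id = id)
    })
    names(models) <- names(cds)
    proteins <- vapply(models, function(m)
      translate_cds(coding_sequence(m), m$gene_id), character(1L))
    write_gff3(models, file.path(out_dir, "mapped.gff3"))
  }

  sites <- NULL
  if (!is.null(models)) {
    say("stage sites (", length(models), " gene models)")
    sites <- do.call(rbind, lapply(names(models), function(id) {
      derive_coding_splice_sites(models[[id]], proteins[[id]])
    }))
    results$sites <- sites
    write_site_table(sites, file.path(out_dir, "sites.tsv"))
  }

  if (!is.null(config$project)) {
    pj <- config$project
    alignment <- if (identical(pj$alignment, "identity")) {
      identity_alignment(proteins)
    } else read_protein_alignment(pj$alignment)
    say("stage project (", length(alignment), " rows)")
    calls <- project_sites(alignment, sites)
    ref <- if (is.null(pj$reference_protein)) names(alignment)[1L] else
      pj$reference_protein
    window <- if (is.null(pj$shift_window)) 1L else
      as.integer(pj$shift_window)
    groups <- classify_site_groups(calls, alignment,
                                   reference_protein = ref,
                                   shift_window = window)
    results$groups <- groups
    tab <- render_site_table(groups)
    write_site_group_table(tab, file.path(out_dir, "shared_sites.tsv"))
    if (!is.null(truth)) {
      results$recovery <- evaluate_recovery(truth, groups)
      say(sprintf("recovery vs simulated truth: precision %.3f recall %.3f F1 %.3f",
                  results$recovery$precision, results$recovery$recall,
                  results$recovery$f1))
    }
    results$alignment <- alignment
  }

  if (!is.null(config$signatures)) {
    sg <- config$signatures
    say("stage signatures (", sg$pattern, ")")
    pat <- parse_prosite_pattern(sg$pattern, accession = sg$accession)
    scores <- score_signature_window(pat, results$alignment,
                                     sg$anchor_id, sg$anchor_index)
    results$signature_scores <- scores
    utils::write.table(scores, file.path(out_dir, "signatures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$catalytic)) {
    ct <- config$catalytic
    say("stage catalytic (", ct$ref_id, ":", ct$ref_protein_index, ")")
    expected <- if (is.null(ct$expected)) "D" else ct$expected
    cat_res <- catalytic_residue_check(results$alignment, ct$ref_id,
                                       ct$ref_protein_index, expected)
    results$catalytic <- cat_res
    utils::write.table(cat_res, file.path(out_dir, "catalytic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$colocation)) {
    cl <- config$colocation
    say("stage colocation (", cl$id_a, " vs ", cl$id_b, ")")
    results$colocation <- colocation_check(models, cl$id_a, cl$id_b)
  }

  summary <- list(
    config_hash = config_hash(config),
    n_gene_models = length(models),
    n_sites = if (is.null(sites)) 0L else nrow(sites),
    n_shared_groups = if (is.null(results$groups)) NA_integer_ else
      sum(vapply(results$groups$groups, function(g) g$shared, logical(1L))),
    recovery = results$recovery,
    colocation = results$colocation)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  say("done")
  invisible(results)
}

validate_pipeline_config <- function(config) {
  inputs <- c(!is.null(config$simulate), !is.null(config$gff),
              !is.null(config$cds))
  if (sum(inputs) > 1L) {
    stop("config error: choose one input stage (simulate, gff or cds)")
  }
  if (!is.null(config$cds) && is.null(config$genome)) {
    stop("config error: cds mapping requires a genome FASTA")
  }
  for (key in c("gff", "genome", "cds")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("config error: ", key, " file not found: ", config[[key]])
    }
  }
  if (!is.null(config$project)) {
    if (sum(inputs) == 0L) {
      stop("config error: projection requires sites (an input stage)")
    }
    al <- config$project$alignment
    if (is.null(al)) {
      stop("config error: projection requires an alignment ",
           "(a path or 'identity')")
    }
    if (!identical(al, "identity") && !file.exists(al)) {
      stop("config error: alignment file not found: ", al)
    }
  }
  if ((!is.null(config$signatures) || !is.null(config$catalytic)) &&
      is.null(config$project)) {
    stop("config error: signature/catalytic stages need the projection ",
         "stage's alignment")
  }
  invisible(TRUE)
}
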