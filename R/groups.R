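#' Classify shared splice-site groups
#'
#' Partitions aligned splice-site calls into equivalence classes of
#' (alignment column, frame). Calls from different proteins that fall in
#' one class occupy the same alignment column with the same exon-boundary
#' frame and are interpreted as one ancestral intron position. For every
#' protein absent from a group a status is assigned:
#'
#' * `shifted_one_nt` - the protein has a site whose boundary is exactly one
#'   nucleotide away from the group site (intron sliding; not shared);
#' * `no_site_conserved_residue` - no site, but the protein's residue at the
#'   group column equals the majority residue of the group members;
#' * `no_site_nonconserved_residue` - no site and the residue differs (ties
#'   in the majority vote, and gaps, count as non-conserved).
#'
#' Groups are named after the reference protein's member when present
#' (three-letter prefix of the reference id + its residue index, e.g.
#' `Cin316`), otherwise after their first member. Singleton groups are kept
#' but flagged unshared.
#'
#' @param calls Aligned site calls from [project_sites()].
#' @param alignment The alignment the calls were projected from.
#' @param reference_protein Protein id used for group naming; default: the
#'   first alignment row.
#' @param shift_window Maximum nucleotide distance counted as a shift
#'   (default 1).
#' @param proteins Proteins to annotate; default: every protein with calls.
#' @return An object of class `shared_site_groups`: a list with elements
#'   `groups` (one list per group: `name`, `column`, `frame`, `members`,
#'   `non_members`, `n_members`, `n_species`, `shared`), `proteins`,
#'   `calls`, `reference_protein`.
#' @export
classify_site_groups <- function(calls, alignment,
                                 reference_protein = names(alignment)[1L],
                                 shift_window = 1L,
                                 proteins = unique(calls$protein_id)) {
  check_alignment(alignment)
  unknown <- setdiff(unique(calls$protein_id), names(alignment))
  if (length(unknown) > 0L) {
    stop("calls refer to unknown alignment rows: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(calls) > 0L && anyDuplicated(calls[, c("protein_id", "column",
                                                  "frame")])) {
    stop("duplicate calls: a protein appears twice at one (column, frame)")
  }

  keys <- paste(calls$column, calls$frame, sep = "/")
  ord <- order(calls$column, calls$frame)
  groups <- lapply(unique(keys[ord]), function(k) {
    members <- calls[keys == k, , drop = FALSE]
    rownames(members) <- NULL
    column <- members$column[1L]
    frame <- members$frame[1L]
    ref_row <- which(members$protein_id == reference_protein)
    namer <- if (length(ref_row) == 1L) members[ref_row, ] else members[1L, ]
    name <- paste0(substr(namer$protein_id, 1L, 3L), namer$protein_index)

    majority <- majority_residue(members$residue)
    absent <- setdiff(proteins, members$protein_id)
    nm <- lapply(absent, function(pid) {
      own <- calls[calls$protein_id == pid, , drop = FALSE]
      shifted <- NULL
      for (i in seq_len(nrow(own))) {
        d <- aligned_nt_distance(own[i, ], members[1L, ], alignment)
        if (d >= 1L && d <= shift_window) { shifted <- own[i, ]; break }
      }
      if (!is.null(shifted)) {
        data.frame(protein_id = pid, status = "shifted_one_nt",
                   residue = shifted$residue,
                   protein_index = shifted$protein_index,
                   shifted_frame = shifted$frame, stringsAsFactors = FALSE)
      } else {
        res <- substr(alignment[[pid]], column, column)
        idx <- column_to_residue_index(alignment[[pid]], column)
        status <- if (res == "-") "no_site_nonconserved_residue"
                  else if (!is.na(majority) && res == majority)
                    "no_site_conserved_residue"
                  else "no_site_nonconserved_residue"
        data.frame(protein_id = pid, status = status, residue = res,
                   protein_index = if (is.na(idx)) NA_integer_ else idx,
                   shifted_frame = NA_integer_, stringsAsFactors = FALSE)
      }
    })
    nm <- if (length(nm) > 0L) do.call(rbind, nm) else
      data.frame(protein_id = character(), status = character(),
                 residue = character(), protein_index = integer(),
                 shifted_frame = integer(), stringsAsFactors = FALSE)
    list(name = name, column = column, frame = frame, members = members,
         non_members = nm, n_members = nrow(members),
         n_species = length(unique(substr(members$protein_id, 1L, 3L))),
         shared = nrow(members) >= 2L)
  })

  structure(list(groups = groups, proteins = proteins, calls = calls,
                 reference_protein = reference_protein),
            class = "shared_site_groups")
}

majority_residue <- function(residues) {
  if (length(residues) == 0L) return(NA_character_)
  tab <- sort(table(residues), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return(NA_character_)  # tie
  names(tab)[1L]
}

#' @export
print.shared_site_groups <- function(x, ...) {
  shared <- Filter(function(g) g$shared, x$groups)
  cat(sprintf("<shared_site_groups> %d proteins, %d site groups (%d shared)\n",
              length(x$proteins), length(x$groups), length(shared)))
  for (g in shared) {
    cat(sprintf("  %s: column %d, frame +%d, %d members (%d species)\n",
                g$name, g$column, g$frame, g$n_members, g$n_species))
  }
  invisible(x)
}

#' Render a shared-site table
#'
#' One row per protein, one column per shared group (ordered by alignment
#' column), plus a per-protein count of introns within the coding region.
#' Member cells read `"V217, +2"`; absent sites read `"n.s. (G285)"`;
#' one-nucleotide shifts read `"shifted (+2)"`.
#'
#' @param groups A `shared_site_groups` object.
#' @param proteins Row order; default: the classifier's protein set.
#' @param shared_only Drop singleton (unshared) groups (default `TRUE`).
#' @return A data frame, one row per protein.
#' @export
render_site_table <- function(groups, proteins = groups$proteins,
                              shared_only = TRUE) {
  gs <- groups$groups
  if (shared_only) gs <- Filter(function(g) g$shared, gs)
  counts <- vapply(proteins, function(p)
    sum(groups$calls$protein_id == p), integer(1L))
  out <- data.frame(protein = proteins, introns_in_cds = counts,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (g in gs) {
    cells <- vapply(proteins, function(p) {
      m <- g$members[g$members$protein_id == p, , drop = FALSE]
      if (nrow(m) == 1L) {
        return(sprintf("%s%d, +%d", m$residue, m$protein_index, m$frame))
      }
      nm <- g$non_members[g$non_members$protein_id == p, , drop = FALSE]
      if (nrow(nm) == 0L) return("")
      if (nm$status == "shifted_one_nt") {
        return(sprintf("shifted (+%d)", nm$shifted_frame))
      }
      if (nm$residue == "-") return("n.s. (-)")
      sprintf("n.s. (%s%d)", nm$residue, nm$protein_index)
    }, character(1L))
    out[[g$name]] <- unname(cells)
  }
  rownames(out) <- NULL
  out
}

#' Write a shared-site table as TSV
#'
#' @param table Data frame from [render_site_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_group_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
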