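test_that("residue/column conversion skips gaps in both directions", {
  expect_equal(residue_to_column("MKVD", 3), 3L)
  expect_equal(residue_to_column("M-KV", 2), 3L)
  expect_error(residue_to_column("--M", 2), "out of range")
  expect_equal(column_to_residue_index("M-KV", 3), 2L)
  expect_true(is.na(column_to_residue_index("M-KV", 2)))
  # round trip over random gapped rows
  set.seed(41)
  for (rep in 1:50) {
    chars <- sample(c(LETTERS[1:6], "-"), 30, replace = TRUE,
                    prob = c(rep(1, 6), 2))
    if (!any(chars != "-")) chars[1] <- "A"
    row <- paste(chars, collapse = "")
    n_res <- sum(chars != "-")
    idx <- sample(n_res, 1)
    col <- residue_to_column(row, idx)
    expect_equal(column_to_residue_index(row, col), idx)
  }
})

test_that("projection lifts sites to columns and cross-checks residues", {
  al <- c(p1 = "MKVDEAGHIL", p2 = "MKVDEAGHIL")
  sites <- data.frame(gene_id = c("p1", "p2"), protein_index = 10L,
                      residue = "L", frame = 3L, coding_offset = 30L)
  calls <- project_sites(al, sites)
  expect_equal(calls$column, c(10L, 10L))
  expect_equal(calls$frame, c(3L, 3L))

  # gapped rows: residue 316 of one protein and 322 of another share a column
  al2 <- c(CinGH6 = paste0(strrep("-", 6), strrep("A", 315), "K"),
           CsaGH6 = paste0(strrep("A", 321), "K"))
  s2 <- data.frame(gene_id = c("CinGH6", "CsaGH6"),
                   protein_index = c(316L, 322L), residue = "K",
                   frame = 3L, coding_offset = c(948L, 966L))
  c2 <- project_sites(al2, s2)
  expect_equal(c2$column, c(322L, 322L))

  bad <- data.frame(gene_id = "p1", protein_index = 1L, residue = "Q",
                    frame = 1L, coding_offset = 1L)
  expect_error(project_sites(al, bad), "mismatch")
})

test_that("projected calls agree with a row-walking oracle", {
  set.seed(42)
  for (rep in 1:30) {
    n_rows <- sample(2:5, 1)
    rows <- vapply(seq_len(n_rows), function(i) {
      chars <- sample(c(LETTERS[1:10], "-"), 40, replace = TRUE)
      chars[sample(40, 1)] <- "A"  # at least one residue
      paste(chars, collapse = "")
    }, character(1))
    names(rows) <- paste0("p", seq_len(n_rows))
    sites <- do.call(rbind, lapply(names(rows), function(pid) {
      n_res <- nchar(gsub("-", "", rows[[pid]]))
      idx <- sort(sample(n_res, min(3, n_res)))
      chars <- strsplit(rows[[pid]], "")[[1]]
      data.frame(gene_id = pid, protein_index = idx,
                 residue = chars[chars != "-"][idx],
                 frame = sample(1:3, length(idx), replace = TRUE),
                 coding_offset = 3L * (idx - 1L) +
                   sample(1:3, length(idx), replace = TRUE))
    }))
    calls <- project_sites(rows, sites)
    # oracle: walk the row character by character counting residues
    for (i in seq_len(nrow(calls))) {
      chars <- strsplit(rows[[calls$protein_id[i]]], "")[[1]]
      seen <- 0L; col <- NA_integer_
      for (j in seq_along(chars)) {
        if (chars[j] != "-") {
          seen <- seen + 1L
          if (seen == calls$protein_index[i]) { col <- j; break }
        }
      }
      expect_equal(calls$column[i], col)
    }
  }
})

test_that("one-nucleotide shifts follow the unrolled codon grid", {
  al <- c(a = "MKVDE", b = "MKVDE")
  call_at <- function(id, col, fr) {
    data.frame(protein_id = id, column = col, frame = fr,
               residue = substr(al[[id]], col, col), protein_index = col,
               coding_offset = 3L * (col - 1L) + fr)
  }
  # same column, frames 3 vs 2: boundary one nucleotide apart
  expect_true(detect_one_nt_shift(call_at("a", 3, 3), call_at("b", 3, 2), al))
  # identical calls: distance 0
  expect_false(detect_one_nt_shift(call_at("a", 3, 3), call_at("b", 3, 3), al))
  # column c frame 3 vs column c+1 frame 1: adjacent slots across columns
  expect_true(detect_one_nt_shift(call_at("a", 3, 3), call_at("b", 4, 1), al))
  # same column, frames 1 vs 3: two nucleotides
  expect_false(detect_one_nt_shift(call_at("a", 3, 1), call_at("b", 3, 3), al))
  # symmetry
  expect_equal(detect_one_nt_shift(call_at("a", 2, 3), call_at("b", 3, 1), al),
               detect_one_nt_shift(call_at("b", 3, 1), call_at("a", 2, 3), al))
})

test_that("columns gapped in both rows are deleted before the distance", {
  # rows a and b are both gapped in columns 4-5; a third row holds residues
  # there, but it must not contribute to the a/b distance
  al <- c(a = "MKV--DE", b = "MKV--DE", c = "MKVWWDE")
  a_call <- data.frame(protein_id = "a", column = 3L, frame = 3L,
                       residue = "V", protein_index = 3L, coding_offset = 9L)
  b_call <- data.frame(protein_id = "b", column = 6L, frame = 1L,
                       residue = "D", protein_index = 4L, coding_offset = 10L)
  expect_equal(aligned_nt_distance(a_call, b_call, al), 1L)
  expect_true(detect_one_nt_shift(a_call, b_call, al))
  # against row c the intervening residues count: distance is 7
  c_call <- data.frame(protein_id = "c", column = 6L, frame = 1L,
                       residue = "D", protein_index = 6L, coding_offset = 16L)
  expect_equal(aligned_nt_distance(a_call, c_call, al), 7L)
})

test_that("grouping is a partition keyed by (column, frame) only", {
  # five proteins share one site column with five different residues
  al <- c(p1 = "MAVAA", p2 = "MAEAA", p3 = "MAKAA", p4 = "MARAA",
          p5 = "MAAAA")
  sites <- data.frame(gene_id = names(al), protein_index = 3L,
                      residue = c("V", "E", "K", "R", "A"), frame = 2L,
                      coding_offset = 8L)
  calls <- project_sites(al, sites)
  g <- classify_site_groups(calls, al)
  expect_length(g$groups, 1L)
  expect_equal(g$groups[[1]]$n_members, 5L)  # residue identity irrelevant
  # every call lands in exactly one group
  total <- sum(vapply(g$groups, function(x) x$n_members, integer(1)))
  expect_equal(total, nrow(calls))

  # all-distinct (column, frame): all groups singletons, none shared
  sites2 <- data.frame(gene_id = names(al), protein_index = 1:5,
                       residue = substring(unname(al), 1:5, 1:5),
                       frame = c(1L, 2L, 3L, 1L, 2L),
                       coding_offset = 3L * (0:4) + c(1L, 2L, 3L, 1L, 2L))
  g2 <- classify_site_groups(project_sites(al, sites2), al)
  expect_length(g2$groups, 5L)
  expect_true(all(!vapply(g2$groups, function(x) x$shared, logical(1))))
})

test_that("group membership and names ignore input order and renaming", {
  fx <- synthetic_gh6_family(seed = 5)
  res <- classify_gh6_fixture(fx)
  sites <- res$sites
  set.seed(43)
  shuffled <- sites[sample(nrow(sites)), ]
  calls2 <- project_sites(fx$alignment, shuffled)
  g2 <- classify_site_groups(calls2, fx$alignment,
                             reference_protein = fx$reference)
  key <- function(g) {
    vapply(g$groups, function(x)
      paste(x$column, x$frame,
            paste(sort(x$members$protein_id), collapse = ",")),
      character(1))
  }
  expect_setequal(key(res$groups), key(g2))
})

test_that("the GH6 example family reproduces its documented site matrix", {
  fx <- synthetic_gh6_family()
  res <- classify_gh6_fixture(fx)
  shared <- Filter(function(g) g$shared, res$groups$groups)
  expect_length(shared, 3L)
  expect_equal(vapply(shared, function(g) g$name, character(1)),
               c("Cin217", "Cin256", "Cin316"))

  third <- shared[[3]]
  expect_equal(third$n_members, 8L)
  expect_equal(third$n_species, 7L)
  expect_equal(third$frame, 3L)

  nm <- third$non_members
  expect_equal(nm$status[nm$protein_id == "OdiCesA1"], "shifted_one_nt")
  expect_equal(nm$status[nm$protein_id == "OdiGH6-1"],
               "no_site_nonconserved_residue")

  # conserved-glycine absences in the second column
  second <- shared[[2]]
  nm2 <- second$non_members
  expect_equal(nm2$status[nm2$protein_id == "BleGH6-1"],
               "no_site_conserved_residue")
  expect_equal(nm2$status[nm2$protein_id == "OdiGH6-1"],
               "no_site_conserved_residue")

  # no shared group mixes the CesA gene with GH6-1 genes
  expect_false(any(vapply(shared, function(g)
    "OdiCesA1" %in% g$members$protein_id, logical(1))))
})

test_that("the rendered table matches the documented row layout", {
  fx <- synthetic_gh6_family()
  res <- classify_gh6_fixture(fx)
  tab <- res$table
  cin <- tab[tab$protein == "CinGH6-1", ]
  expect_equal(unname(unlist(cin[c("Cin217", "Cin256", "Cin316")])),
               c("V217, +2", "G256, +1", "K316, +3"))
  expect_equal(tab$introns_in_cds[tab$protein == "CinGH6-1"], 3L)
  expect_equal(tab$introns_in_cds[tab$protein == "OdiCesA1"], 8L)
  expect_equal(tab$Cin316[tab$protein == "OdiCesA1"], "shifted (+2)")
  expect_equal(tab$Cin217[tab$protein == "MocGH6-1"], "n.s. (R222)")
  expect_equal(tab$Cin256[tab$protein == "BleGH6-1"], "n.s. (G285)")

  # header-only output for an empty classification
  al <- c(a = "MK", b = "MK")
  empty <- classify_site_groups(
    data.frame(protein_id = character(), column = integer(),
               frame = integer(), residue = character(),
               protein_index = integer(), coding_offset = integer()),
    al, proteins = character())
  expect_equal(nrow(render_site_table(empty)), 0L)
})
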