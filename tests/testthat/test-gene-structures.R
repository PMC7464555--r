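test_that("translation follows the standard code and strips terminal stops", {
  expect_equal(translate_cds("ATG"), "M")
  expect_equal(translate_cds("ATGGATTAA"), "MD")
  expect_error(translate_cds("ATGTAAGAT"), "internal stop")
  expect_error(translate_cds("ATGA"), "divisible by 3")
})

test_that("gene_model enforces coordinate invariants", {
  expect_error(gene_model("g", "s", "*", 1, 9), "strand")
  expect_error(gene_model("g", "s", "+", 10, 5), "start <= end")
  expect_error(gene_model("g", "s", "+", c(1, 50), c(60, 90)), "overlap")
  m <- gene_model("g", "s", "-", c(1, 50), c(9, 60))
  # minus strand: transcription order puts the higher-coordinate exon first
  expect_equal(m$intervals$start, c(50L, 1L))
  expect_equal(coding_length(m), 20L)
})

test_that("minus-strand coding sequence is the reverse complement chain", {
  # 60-nt toy: plant a known CDS on the minus strand and read it back
  cds <- "ATGGATGAAGGT"
  genome_plus <- paste0("AAAA",
                        as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(substr(cds, 7, 12)))),
                        "TTTTTTTT",
                        as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(substr(cds, 1, 6)))),
                        "CCCC")
  m <- gene_model("g", "s", "-", c(5, 19), c(10, 24),
                  source_seq = genome_plus)
  expect_equal(coding_sequence(m), cds)
})

test_that("complete-CDS validation rejects partial models", {
  good <- gene_model("g", "s", "+", 1, 9, source_seq = "ATGGATTAA")
  expect_silent(validate_gene_model(good))
  no_start <- gene_model("g", "s", "+", 1, 9, source_seq = "TTGGATTAA")
  expect_error(validate_gene_model(no_start), "ATG")
  no_stop <- gene_model("g", "s", "+", 1, 9, source_seq = "ATGGATGAT")
  expect_error(validate_gene_model(no_stop), "stop codon")
  not_triplet <- gene_model("g", "s", "+", 1, 10)
  expect_error(validate_gene_model(not_triplet), "divisible by 3")
})

test_that("GFF3 parsing handles empty, plus- and minus-strand records", {
  expect_equal(parse_gff3("##gff-version 3"), list())

  gff <- c("##gff-version 3",
           "chr1\ttest\tCDS\t100\t250\t.\t+\t0\tID=cds1;Parent=t1",
           "chr1\ttest\tCDS\t301\t400\t.\t+\t2\tID=cds2;Parent=t1")
  # 151 + 100 = 251 nt: not a multiple of three, must be rejected by name
  expect_error(parse_gff3(paste(gff, collapse = "\n")),
               "t1.*not divisible by 3")

  gff[3] <- "chr1\ttest\tCDS\t301\t401\t.\t+\t2\tID=cds2;Parent=t1"
  models <- parse_gff3(paste(gff, collapse = "\n"))
  expect_length(models, 1L)
  expect_equal(models[[1]]$intervals,
               data.frame(start = c(100L, 301L), end = c(250L, 401L)))
  expect_equal(coding_length(models[[1]]), 252L)

  minus <- c("##gff-version 3",
             "chr1\ttest\tCDS\t10\t21\t.\t-\t0\tID=c1;Parent=tm",
             "chr1\ttest\tCDS\t40\t51\t.\t-\t0\tID=c2;Parent=tm")
  mm <- parse_gff3(paste(minus, collapse = "\n"))[[1]]
  expect_equal(mm$intervals$start, c(40L, 10L))  # transcript order
})

test_that("malformed GFF3 lines are reported with their line number", {
  bad <- c("##gff-version 3",
           "chr1\ttest\tCDS\t100\t250\t.\t+\t0\tID=c;Parent=t",
           "chr1\ttest\tCDS\t300")
  expect_error(parse_gff3(paste(bad, collapse = "\n")), "line 3")
  bad2 <- c("##gff-version 3",
            "chr1\ttest\tCDS\tabc\t250\t.\t+\t0\tID=c;Parent=t")
  expect_error(parse_gff3(paste(bad2, collapse = "\n")), "line 2")
})

test_that("GFF3 write/parse round trip preserves gene models", {
  set.seed(11)
  cds <- random_cds(40)
  genome <- insert_introns(cds, c(35, 80), c(30, 40))
  m1 <- map_cds_to_genome(cds, genome, min_intron = 20, gene_id = "gA",
                          seq_id = "sA")
  path <- tempfile(fileext = ".gff3")
  write_gff3(list(m1), path)
  expect_match(readLines(path)[1], "gff-version 3")
  back <- parse_gff3(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$intervals, m1$intervals)
  expect_equal(back[[1]]$strand, m1$strand)
  # a second round trip is byte-stable
  path2 <- tempfile(fileext = ".gff3")
  write_gff3(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("multiple transcripts of one gene collapse to the longest CDS", {
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t1\t500\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\ttest\tmRNA\t1\t500\t.\t+\t.\tID=t2;Parent=g1",
           "chr1\ttest\tCDS\t1\t90\t.\t+\t0\tID=c1;Parent=t1",
           "chr1\ttest\tCDS\t1\t60\t.\t+\t0\tID=c2;Parent=t2")
  expect_message(models <- parse_gff3(paste(gff, collapse = "\n")),
                 "longest CDS")
  expect_length(models, 1L)
  expect_equal(models[[1]]$gene_id, "t1")
})

test_that("splice sites carry the residue/frame labelling convention", {
  # single-exon gene: no internal boundary
  single <- gene_model("g", "s", "+", 1, 99)
  expect_equal(nrow(derive_coding_splice_sites(
    single, strrep("A", 32))), 0L)

  # a first exon of 650 coding nt ends at codon position 2 of residue 217
  m650 <- gene_model("g", "s", "+", c(1, 700), c(650, 1000))
  prot <- strrep("A", 316)
  substr(prot, 217, 217) <- "V"
  s <- derive_coding_splice_sites(m650, prot)
  expect_equal(s$protein_index, 217L)
  expect_equal(s$frame, 2L)
  expect_equal(s$label, "V217.frame+2")

  # a first exon of 948 coding nt ends at codon position 3 of residue 316
  m948 <- gene_model("g", "s", "+", c(1, 1000), c(948, 1053))
  prot2 <- strrep("A", 333)
  substr(prot2, 316, 316) <- "K"
  s2 <- derive_coding_splice_sites(m948, prot2)
  expect_equal(s2$protein_index, 316L)
  expect_equal(s2$frame, 3L)
  expect_equal(s2$label, "K316.frame+3")
})

test_that("derived sites equal the nucleotide-unrolling oracle", {
  set.seed(23)
  for (rep in 1:25) {
    n_exons <- 4L
    lens <- sample(10:120, n_exons)
    total <- sum(lens)
    lens[n_exons] <- lens[n_exons] + (3L - total %% 3L) %% 3L
    starts <- cumsum(c(1L, lens[-n_exons] + 50L))
    ends <- starts + lens - 1L
    m <- gene_model(sprintf("g%d", rep), "s", "+", starts, ends)
    protein <- paste(sample(LETTERS[1:20], sum(lens) %/% 3L - 1L,
                            replace = TRUE), collapse = "")
    got <- derive_coding_splice_sites(m, protein)
    want <- oracle_sites(lens, protein)
    expect_equal(got$protein_index, want$protein_index)
    expect_equal(got$frame, want$frame)
    expect_equal(got$coding_offset, want$coding_offset)
    expect_equal(got$residue, want$residue)
  }
})

test_that("a boundary inside the terminal stop codon is flagged", {
  # 12-nt CDS, boundary after nt 10 = first position of the stop codon
  m <- gene_model("g", "s", "+", c(1, 41), c(10, 42),
                  source_seq = paste0("ATGGATGAAT",
                                      random_intron(30), "AA"))
  expect_warning(s <- derive_coding_splice_sites(m), "stop codon")
  expect_equal(s$protein_index, 4L)  # protein has 3 residues
  expect_equal(s$residue, "*")
})

test_that("protein/CDS length mismatches are rejected", {
  m <- gene_model("g", "s", "+", c(1, 100), c(60, 159))
  expect_error(derive_coding_splice_sites(m, strrep("A", 10)),
               "does not match")
})
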