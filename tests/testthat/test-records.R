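test_that("record tables round-trip through TSV and JSON and reject bad rows", {
  recs <- splice_records(
    id = c("r1", "r2", "r3"), gene = "TOYGENE",
    site_kind = c("donor", "donor", "acceptor"),
    authentic_boundary = c(80L, 80L, 280L),
    aberrant_boundary = c(105L, 60L, 250L),
    mut_pos = c(81L, 78L, 251L),
    ref_base = c("C", "G", "T"), alt_base = c("T", "A", "G"),
    location = c("intron", "exon", "intron"))
  for (dialect in c("tsv", "json")) {
    tf <- withr::local_tempfile()
    write_splice_records(recs, tf, dialect)
    back <- read_splice_records(tf, dialect)
    expect_identical(as.data.frame(back), as.data.frame(recs))
  }

  # empty table with a valid header parses to an empty set
  tf <- withr::local_tempfile()
  write_splice_records(recs[0, ], tf)
  expect_identical(nrow(read_splice_records(tf)), 0L)

  # ref == alt is a row-level validation error naming the row
  expect_error(splice_records(id = "bad", gene = "G", site_kind = "donor",
                              authentic_boundary = 10L, aberrant_boundary = 20L,
                              mut_pos = 11L, ref_base = "A", alt_base = "A"),
               "ref_base must differ")

  # missing mandatory column is a schema error naming the column
  tf2 <- withr::local_tempfile()
  df <- as.data.frame(recs); df$ref_base <- NULL
  utils::write.table(df, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_splice_records(tf2), "ref_base")

  # unparseable coordinate reported with its line
  tf3 <- withr::local_tempfile()
  df2 <- as.data.frame(recs); df2$mut_pos <- as.character(df2$mut_pos + 1L)
  df2$mut_pos[2] <- "not_a_number"
  utils::write.table(df2, tf3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_splice_records(tf3), "mut_pos.*2")
})

test_that("reference validation checks alleles and post-mutation dinucleotides", {
  genome <- toy_genome()
  gm <- toy_gene_model()
  seq <- genome[["toy_contig"]]
  models <- list(TOYGENE = gm)

  # a de novo donor whose GT is created by the mutation: plant G A at an
  # intronic position, mutation A>T at +2 completes the dinucleotide
  b <- 150L
  substr(seq, b + 1L, b + 2L) <- "GA"
  genome2 <- c(toy_contig = seq)
  rec <- splice_records(id = "dn", gene = "TOYGENE", site_kind = "donor",
                        authentic_boundary = 80L, aberrant_boundary = b,
                        mut_pos = b + 1L, ref_base = "A", alt_base = "T")
  rep <- validate_against_reference(rec, genome2, models)
  expect_true(rep$pass)
  expect_identical(rep$dinucleotide, "GT")

  # hand-trace of the 9-mer before/after the substitution
  before <- window_from_sequence(seq, b, "donor")
  expect_identical(substr(before, 4, 5), "GA")
  mutated <- seq; substr(mutated, b + 2L, b + 2L) <- "T"
  expect_identical(substr(window_from_sequence(mutated, b, "donor"), 4, 5),
                   "GT")

  # swapped ref/alt fails the reference check
  rec_sw <- splice_records(id = "sw", gene = "TOYGENE", site_kind = "donor",
                           authentic_boundary = 80L, aberrant_boundary = b,
                           mut_pos = b + 1L, ref_base = "T", alt_base = "A")
  rep_sw <- validate_against_reference(rec_sw, genome2, models)
  expect_false(rep_sw$pass)
  expect_match(rep_sw$reason, "reference mismatch")

  # a GC donor is legal; an AA boundary is not
  seq3 <- seq; substr(seq3, b + 1L, b + 2L) <- "GC"
  rec_gc <- splice_records(id = "gc", gene = "TOYGENE", site_kind = "donor",
                           authentic_boundary = 80L, aberrant_boundary = b,
                           mut_pos = 90L,
                           ref_base = substr(seq3, 91, 91),
                           alt_base = setdiff(c("A", "C", "G", "T"),
                                              substr(seq3, 91, 91))[1])
  expect_true(validate_against_reference(rec_gc, c(toy_contig = seq3),
                                         models)$dinuc_ok)

  # out-of-range coordinates fail with the documented reason
  rec_oor <- splice_records(id = "oor", gene = "TOYGENE", site_kind = "donor",
                            authentic_boundary = 80L, aberrant_boundary = 90L,
                            mut_pos = 9000L, ref_base = "A", alt_base = "G")
  expect_match(validate_against_reference(rec_oor, genome2, models)$reason,
               "out of range")
})

test_that("site windows follow the donor -3..+6 / acceptor -20..+3 footprints", {
  # donor consensus read-off
  s <- paste0(strrep("A", 20), "CAG", "GTAAGT", strrep("A", 20))
  expect_identical(window_from_sequence(s, 23L, "donor"), "CAGGTAAGT")

  # acceptor 23-mer: 20 intronic + 3 exonic positions
  s2 <- paste0("AAAA", strrep("T", 17), "CAG", "GCATT")
  expect_identical(window_from_sequence(s2, 24L, "acceptor"),
                   "TTTTTTTTTTTTTTTTTCAGGCA")

  # strand symmetry: a minus-strand gene over the reverse-complement contig
  # yields the identical window
  genome_plus <- toy_genome()
  gm_plus <- toy_gene_model()
  w_plus <- extract_site_window(genome_plus, gm_plus, 80L, "donor")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome_plus[["toy_contig"]])))
  gm_minus <- gene_model("TOYGENE", "toy_contig", "-", gm_plus$exons)
  w_minus <- extract_site_window(c(toy_contig = rc), gm_minus, 80L, "donor")
  expect_identical(w_plus, w_minus)

  # overruns are errors
  expect_error(window_from_sequence("ACGTACGT", 7L, "donor"), "overruns")
})
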