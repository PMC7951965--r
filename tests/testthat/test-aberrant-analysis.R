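test_that("cryptic/de novo classification partitions records by footprint", {
  mk <- function(kind, auth, mut)
    splice_records(id = "x", gene = "G", site_kind = kind,
                   authentic_boundary = auth, aberrant_boundary = auth + 40L,
                   mut_pos = mut, ref_base = "C", alt_base = "T")
  # donor footprint: exon -3 .. intron +6 relative to boundary b = first
  # intronic base, i.e. positions b-3 .. b+5
  expect_identical(classify_cryptic_de_novo(mk("donor", 100L, 100L)), "cryptic")
  expect_identical(classify_cryptic_de_novo(mk("donor", 100L, 97L)), "cryptic")
  expect_identical(classify_cryptic_de_novo(mk("donor", 100L, 105L)), "cryptic")
  expect_identical(classify_cryptic_de_novo(mk("donor", 100L, 96L)), "de_novo")
  expect_identical(classify_cryptic_de_novo(mk("donor", 100L, 106L)), "de_novo")
  # the composite-pseudoexon case: a substitution hundreds of nt into the
  # intron creating a new donor is de novo
  expect_identical(classify_cryptic_de_novo(mk("donor", 100L, 630L)), "de_novo")
  # acceptor footprint: intron -3 .. exon +1 (b = first exonic base)
  expect_identical(classify_cryptic_de_novo(mk("acceptor", 200L, 197L)), "cryptic")
  expect_identical(classify_cryptic_de_novo(mk("acceptor", 200L, 200L)), "cryptic")
  expect_identical(classify_cryptic_de_novo(mk("acceptor", 200L, 201L)), "de_novo")
  expect_identical(classify_cryptic_de_novo(mk("acceptor", 200L, 196L)), "de_novo")

  # property: every record receives exactly one of the two labels
  set.seed(5)
  recs <- splice_records(id = sprintf("r%d", 1:200), gene = "G",
                         site_kind = sample(c("donor", "acceptor"), 200, TRUE),
                         authentic_boundary = sample(50:500, 200, TRUE),
                         aberrant_boundary = 1000L,
                         mut_pos = sample(1:900, 200, TRUE),
                         ref_base = "A", alt_base = "G")
  cls <- classify_cryptic_de_novo(recs)
  expect_true(all(cls %in% c("cryptic", "de_novo")))
  expect_length(cls, 200)

  recs$authentic_boundary[1] <- NA_integer_
  expect_error(classify_cryptic_de_novo(recs), "unset")
})

test_that("multiplicity fractions use both event and record denominators", {
  rs <- gen_record_set(693, 90, 0.13, seed = 2)
  fm <- fraction_multiple(rs$records)
  expect_identical(fm$n_multi_records, 90L)
  expect_equal(fm$record_fraction, 90 / 693)

  singles <- data.frame(multiplicity_group = sprintf("m%d", 1:10))
  expect_equal(fraction_multiple(singles)$record_fraction, 0)
  expect_equal(fraction_multiple(singles)$event_fraction, 0)

  doubles <- data.frame(multiplicity_group = rep(c("a", "b"), each = 2))
  fm2 <- fraction_multiple(doubles)
  expect_equal(fm2$record_fraction, 1)
  expect_equal(fm2$event_fraction, 1)
})

test_that("strong-cryptic pairs require strict inequality and one model family", {
  df <- data.frame(id = c("a", "b", "c"), site_kind = "donor",
                   location = "intron", auth_score = c(6.5, 5, 5),
                   cryp_score = c(8.0, 5, 4.9), model_id = "m1")
  pairs <- find_strong_weak_pairs(df)
  expect_identical(pairs$id, "a")
  expect_equal(pairs$delta, 1.5)

  df$model_id <- c("m1", "m1", "m2")
  expect_error(find_strong_weak_pairs(df), "mixed model families")

  # planted stronger-cryptic fraction is recovered exactly
  rs <- gen_record_set(381, 49, 0.19, site_kind = "acceptor", seed = 3)
  got <- nrow(find_strong_weak_pairs(rs$records))
  expect_identical(got, as.integer(rs$truth$n_strong))
  expect_lt(abs(got / 381 - 0.19), 0.005)
})

test_that("relevant flanks and residual introns follow the site geometry", {
  gm <- toy_gene_model()  # exons 0-80, 280-380, 530-600
  # intronic cryptic 5'ss in intron 1: upstream exon (80 nt), residual runs
  # to the authentic acceptor at 280
  fl <- compute_relevant_flank("donor", "intron", 120L, gm)
  expect_identical(fl, list(flank_kind = "exon", flank_size = 80L,
                            residual_intron = 160L))
  # the published short-residual example: a cryptic donor leaving 35 nt of
  # intron falls below the ~70 nt minimum
  fl35 <- compute_relevant_flank("donor", "intron", 245L, gm)
  expect_identical(fl35$residual_intron, 35L)
  expect_lt(fl35$residual_intron, 70)
  # intronic cryptic 3'ss: downstream exon, residual is the 5' piece
  fl3 <- compute_relevant_flank("acceptor", "intron", 150L, gm)
  expect_identical(fl3, list(flank_kind = "exon", flank_size = 100L,
                             residual_intron = 70L))
  # exonic cryptic 3'ss: upstream intron (intron 2 = 150 nt), no residual
  fle <- compute_relevant_flank("acceptor", "exon", 560L, gm)
  expect_identical(fle$flank_kind, "intron")
  expect_identical(fle$flank_size, 150L)
  expect_true(is.na(fle$residual_intron))
  # exonic cryptic 5'ss: downstream intron
  fld <- compute_relevant_flank("donor", "exon", 300L, gm)
  expect_identical(fld$flank_size, 150L)

  expect_error(compute_relevant_flank("donor", "intron", 9999L, gm),
               "outside gene span")
})

test_that("quadrant summaries apply inclusive thresholds and ignore order", {
  pairs <- data.frame(site_kind = "donor", location = "intron",
                      flank_kind = "exon", flank_size = c(90L, 100L, 101L))
  qs <- quadrant_summary(pairs, exon_thr = 100)
  row <- qs[qs$site_kind == "donor" & qs$location == "intron", ]
  expect_identical(row$n_small, 2L)
  expect_equal(row$fraction, 2 / 3)

  qs_rev <- quadrant_summary(pairs[3:1, ], exon_thr = 100)
  expect_identical(qs_rev, qs)

  empty <- quadrant_summary(pairs[0, ])
  expect_true(all(empty$N == 0L))
  expect_true(all(is.na(empty$fraction)))
})

test_that("the statistics suite matches base R and full enumeration", {
  expect_equal(median_value(c(1, 2, 3, 4)), 2.5)
  expect_error(median_value(numeric(0)), "empty")

  # the published small-exon contrast: p = 0.02 scale Fisher example
  f <- fisher_exact_2x2(matrix(c(1, 9, 11, 3), 2, 2, byrow = TRUE))
  expect_equal(f$p_value, 0.00276, tolerance = 1e-3)

  # agreement with the independent implementation over many margins <= 30
  set.seed(9)
  for (rep in 1:40) {
    tab <- matrix(sample(0:8, 4, TRUE), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }

  ch <- chi2_2x2(matrix(c(30, 12, 20, 25), 2, 2))
  ref <- stats::chisq.test(matrix(c(30, 12, 20, 25), 2, 2), correct = FALSE)
  expect_equal(ch$statistic, unname(ref$statistic))
  expect_equal(ch$p_value, ref$p.value)

  a <- c(5.1, 6.2, 5.9, 7.3); b <- c(4.0, 4.8, 5.2, 4.4)
  tt <- t_unpaired(a, b)
  ref_t <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tt$t, unname(ref_t$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, ref_t$p.value, tolerance = 1e-12)
  expect_equal(t_unpaired(a, a)$t, 0)
  expect_error(t_unpaired(c(1, 1), c(2, 2)), "zero variance")
})
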