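test_that("secondary structures validate nesting, spacing and brackets", {
  expect_error(secondary_structure(rbind(c(1, 8), c(4, 12)), 12),
               "pseudoknot")
  expect_error(secondary_structure(rbind(c(2, 5)), 10), "at least 3")
  expect_error(secondary_structure(rbind(c(1, 8), c(1, 12)), 12),
               "more than one pair")
  s <- secondary_structure(rbind(c(1, 12), c(2, 11), c(3, 10)), 14)
  expect_identical(s$db, "(((......)))..")
  expect_identical(parse_dotbracket(s$db)$pairs, s$pairs)
  expect_error(parse_dotbracket("(()"), "unbalanced")

  tf <- withr::local_tempfile()
  write_ct(s, "GGGAAAAAACCCAA", tf, energy = -1.5)
  lines <- readLines(tf)
  expect_length(lines, 15L)
  expect_match(lines[1], "dG = -1.50")
  expect_identical(strsplit(lines[2], " ")[[1]][5], "12")
})

test_that("MFE folding matches the hand-summed energy model", {
  # no canonical pairs: open chain at energy 0
  res <- mfe_fold("AAAAAAA")
  expect_identical(nrow(res$structure$pairs), 0L)
  expect_identical(res$energy, 0)

  # GC stem with a 4-nt loop: three GC/GC stacks plus the hairpin penalty
  model <- energy_model()
  res2 <- mfe_fold("GGGGAAAACCCC", model)
  expect_identical(res2$structure$pairs,
                   matrix(c(1L, 2L, 3L, 4L, 12L, 11L, 10L, 9L), 4, 2))
  hand <- 3 * model$stack[3, 3] + model$hairpin[4]
  expect_equal(res2$energy, hand, tolerance = 1e-12)
  expect_equal(structure_energy(res2$structure, "GGGGAAAACCCC", model),
               res2$energy, tolerance = 1e-12)

  # deterministic output on repeated calls
  seq <- "GCGCGAAACGCGCAAAGGCC"
  expect_identical(mfe_fold(seq)$structure$db, mfe_fold(seq)$structure$db)
})

test_that("forced-unpaired constraints are honoured and never raise Z", {
  seq <- "GGGGAAAACCCC"
  res <- mfe_fold(seq, constraints = c(2L))
  expect_false(any(res$structure$pairs == 2L))
  Z <- partition_Z(seq)
  expect_gte(Z, 1)
  for (i in 1:12) expect_lte(partition_Z(seq, constraints = i), Z + 1e-12)
})

test_that("pair probabilities conserve and PU windows nest monotonically", {
  set.seed(13)
  for (rep in 1:3) {
    seq <- random_rna(30)
    pp <- partition(seq)
    expect_true(all(pp$p >= -1e-12 & pp$p <= 1 + 1e-12))
    for (i in c(1, 11, 30)) {
      paired <- sum(pp$p[i, ]) + sum(pp$p[, i])
      unpaired <- partition_Z(seq, constraints = i) / pp$Z
      expect_equal(paired + unpaired, 1, tolerance = 1e-9)
    }
  }

  # PU = 1 on an unpairable sequence; nesting w1 in w2 gives PU(w1) >= PU(w2)
  expect_equal(pu_value("AAAAAAAAAAAA", c(3, 6))$PU, 1)
  hp <- "GGGGGAAAACCCCC"
  expect_gte(pu_value(hp, c(2, 3))$PU, pu_value(hp, c(2, 5))$PU)
  pu <- pu_value(hp, c(2, 5))$PU
  expect_gt(pu, 0); expect_lte(pu, 1)
  expect_error(pu_value(hp, c(9, 2)), "start <= end")

  # width-1 profile equals single-position PU values
  prof <- pu_profile("GGGGAAAACCCC", width = 1L)
  expect_equal(prof$PU[5], pu_value("GGGGAAAACCCC", c(5, 5))$PU)
})

test_that("reactivity constraints remove probed stems monotonically", {
  seq <- "GGGGAAAACCCC"
  react0 <- rep(0, 12)
  free <- mfe_fold(seq)
  expect_identical(reactivity_constrained_fold(seq, react0)$structure$pairs,
                   free$structure$pairs)

  # high reactivity across one strand of the stem removes it
  react <- rep(0, 12); react[1:4] <- 2
  res <- reactivity_constrained_fold(seq, react)
  expect_identical(nrow(res$structure$pairs), 0L)

  # lowering the threshold never increases the pair count
  set.seed(17)
  seq2 <- random_rna(40, prob = c(.2, .3, .3, .2))
  react2 <- runif(40, 0, 2)
  counts <- vapply(c(2, 1.5, 1, 0.7, 0.4, 0.2), function(th)
    nrow(reactivity_constrained_fold(seq2, react2, th)$structure$pairs),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("base-pair distance is a metric on seeded structures", {
  s0 <- secondary_structure(NULL, 20)
  s1 <- secondary_structure(rbind(c(1, 20), c(2, 19), c(3, 18), c(4, 17)), 20)
  s2 <- secondary_structure(rbind(c(5, 16), c(6, 15), c(7, 14), c(8, 13)), 20)
  expect_identical(base_pair_distance(s1, s1), 0L)
  expect_identical(base_pair_distance(s1, s2), 8L)
  expect_error(base_pair_distance(s1, secondary_structure(NULL, 10)),
               "lengths")

  set.seed(23)
  for (rep in 1:10) {
    seqs <- replicate(3, random_rna(16, prob = c(.2, .3, .3, .2)))
    tri <- lapply(seqs, function(s) mfe_fold(s)$structure)
    if (length(unique(vapply(tri, function(x) x$length, integer(1)))) > 1) next
    d12 <- base_pair_distance(tri[[1]], tri[[2]])
    d23 <- base_pair_distance(tri[[2]], tri[[3]])
    d13 <- base_pair_distance(tri[[1]], tri[[3]])
    expect_lte(d13, d12 + d23)
  }
})

test_that("helices, hairpin caps and stem presence are annotated", {
  # 7-bp stem capped by a GAGG tetraloop (the high-inclusion cap motif)
  seq <- "GGCGGCCGAGGGGCCGCC"
  st <- secondary_structure(cbind(1:7, 18:12), 18)
  ann <- stems_and_loops(st, seq, min_stack = 3)
  expect_identical(nrow(ann$helices), 1L)
  expect_identical(ann$helices$length, 7L)
  expect_identical(ann$hairpins$loop_seq, "GAGG")
  expect_identical(ann$n_multiloops, 0L)

  empty <- stems_and_loops(secondary_structure(NULL, 18), seq)
  expect_identical(nrow(empty$helices), 0L)

  # reference stem with 1 of 5 pairs broken: presence 0.8
  ref <- cbind(1:5, 18:14)
  partial <- secondary_structure(cbind(1:4, 18:15), 18)
  expect_equal(stem_presence(ref, partial), 0.8)
})
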