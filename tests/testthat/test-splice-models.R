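test_that("Markov training reproduces transition counts and known chains", {
  # single sequence, no smoothing: all observed transitions get mass 1
  m1 <- train_markov("ACGT", pseudocount = 0)
  expect_equal(m1$p0[1], 1)
  expect_equal(m1$cond[[1]]["A", "C"], 1)
  expect_equal(m1$cond[[2]]["C", "G"], 1)

  # two sequences: P(pos2 = A | A) = 0.5
  m2 <- train_markov(c("AA", "AC"), pseudocount = 0)
  expect_equal(m2$cond[[1]]["A", "A"], 0.5)
  expect_equal(m2$cond[[1]]["A", "C"], 0.5)

  # seeded draws from a known chain recover the conditionals within 0.05
  set.seed(11)
  P <- matrix(c(.7, .1, .1, .1,
                .25, .25, .25, .25,
                .1, .2, .3, .4,
                .4, .3, .2, .1), 4, 4, byrow = TRUE)
  draws <- vapply(seq_len(4000), function(i) {
    b <- sample(1:4, 1, prob = c(.4, .2, .2, .2))
    s <- c("A", "C", "G", "T")[b]
    for (p in 2:4) {
      b <- sample(1:4, 1, prob = P[b, ])
      s <- paste0(s, c("A", "C", "G", "T")[b])
    }
    s
  }, character(1))
  mt <- train_markov(draws, pseudocount = 0)
  for (p in 1:3) expect_lt(max(abs(mt$cond[[p]] - P)), 0.05)

  # length mismatch names the offending sequence
  expect_error(train_markov(c("AAA", "AAAA")), "length 4")
})

test_that("log2-odds scoring matches hand arithmetic", {
  sig <- train_markov(c("A", "A", "C", "G"), pseudocount = 0)
  dec <- train_markov(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(score_log2odds(sig, dec, "A")$value, 1)  # log2(0.5/0.25)

  # identical models give 0 for any sequence
  m <- train_markov(c("ACGT", "TTAC", "GGGT"))
  for (s in c("ACGT", "AAAA", "TGCA"))
    expect_identical(score_log2odds(m, m, s)$value, 0)

  # 2-mer toy with hand-computed probabilities, to 1e-12
  s2 <- train_markov(c("AA", "AC", "CA"), pseudocount = 0)
  d2 <- train_markov(c("AA", "CC", "GG", "TT"), pseudocount = 0)
  # P_s(AA) = (2/3)(1/2); P_d(AA) = (1/4)(1)
  expect_equal(score_log2odds(s2, d2, "AA")$value,
               log2((2 / 3) * (1 / 2) / (1 / 4)), tolerance = 1e-12)

  # zero decoy probability advises smoothing
  expect_error(score_log2odds(s2, d2, "AC"), "pseudocount")
})

test_that("maximum-entropy fits satisfy their constraints and limits", {
  seqs <- c("AA", "AC", "AC", "GT", "GT", "GT", "CA", "AA", "AA", "TT")

  # single-position constraints: closed-form product of marginals
  me1 <- train_maxent(seqs, list(1L, 2L), tol = 1e-8)
  p1 <- table(factor(substr(seqs, 1, 1), levels = c("A", "C", "G", "T"))) / 10
  p2 <- table(factor(substr(seqs, 2, 2), levels = c("A", "C", "G", "T"))) / 10
  for (a in c("A", "C", "G", "T")) for (b in c("A", "C", "G", "T"))
    expect_equal(seq_prob(me1, paste0(a, b)), unname(p1[a] * p2[b]),
                 tolerance = 1e-6)

  # full pairwise constraint on 2-mers: exactly the empirical distribution
  me2 <- train_maxent(seqs, list(c(1L, 2L)), tol = 1e-10)
  kmers <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           function(a, b) paste0(a, b)))
  emp <- table(factor(seqs, levels = kmers)) / length(seqs)
  for (k in kmers) expect_equal(seq_prob(me2, k), unname(emp[k]),
                                tolerance = 1e-8)

  # uniform input stays uniform under any constraint set
  me3 <- train_maxent(kmers, list(1L, 2L, c(1L, 2L)))
  expect_lt(max(abs(me3$prob - 1 / 16)), 1e-6)

  # max-entropy property: entropy >= every other constraint-satisfier
  # (mixtures of the empirical distribution with the fit stay feasible)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  empv <- as.numeric(emp[kmers])
  fitv <- vapply(kmers, function(k) seq_prob(me1, k), numeric(1))
  for (lam in c(0, 0.3, 0.7, 1))
    expect_gte(H(fitv) + 1e-9, H(lam * empv + (1 - lam) * fitv))

  # scores are invariant to duplicating every training sequence
  me_dup <- train_maxent(rep(seqs, 2), list(c(1L, 2L)), tol = 1e-10)
  expect_equal(me_dup$prob, me2$prob, tolerance = 1e-7)

  # training-set consensus scores at least the training mean (Markov)
  set.seed(21)
  win <- replicate(150, {
    paste(vapply(1:5, function(p) {
      cons <- c("C", "A", "G", "G", "T")[p]
      if (runif(1) < 0.8) cons else sample(setdiff(c("A", "C", "G", "T"), cons), 1)
    }, character(1)), collapse = "")
  })
  sig <- train_markov(win)
  dec <- train_markov(replicate(150, random_rna(5, c("A", "C", "G", "T"))))
  sc <- vapply(win, function(s) score_log2odds(sig, dec, s)$value, numeric(1))
  expect_gte(score_log2odds(sig, dec, "CAGGT")$value, mean(sc))

  expect_error(train_maxent(c("AAAAAAAAAA"), list(1L)), "enumerable")
})

test_that("decomposed acceptor scoring equals the chain-rule factorization", {
  set.seed(3)
  train7 <- replicate(200, random_rna(7, c("A", "C", "G", "T"),
                                      prob = c(.4, .1, .3, .2)))
  m1s <- train_markov(substr(train7, 1, 4))
  m2s <- train_markov(substr(train7, 4, 7))
  m1d <- train_markov(replicate(200, random_rna(4, c("A", "C", "G", "T"))))
  m2d <- train_markov(replicate(200, random_rna(4, c("A", "C", "G", "T"))))
  fr <- list(list(start = 1, end = 4, signal = m1s, decoy = m1d),
             list(start = 4, end = 7, signal = m2s, decoy = m2d))
  sc <- score_acceptor_decomposed(fr, "ACGGTAC")
  manual <- log2(seq_prob(m1s, "ACGG") * seq_prob(m2s, "GTAC") /
                   prefix_prob(m2s, "G")) -
    log2(seq_prob(m1d, "ACGG") * seq_prob(m2d, "GTAC") / prefix_prob(m2d, "G"))
  expect_equal(sc$value, manual, tolerance = 1e-12)

  # identical signal/decoy fragment models give 0
  fr0 <- list(list(start = 1, end = 4, signal = m1s, decoy = m1s),
              list(start = 4, end = 7, signal = m2s, decoy = m2s))
  expect_equal(score_acceptor_decomposed(fr0, "ACGGTAC")$value, 0,
               tolerance = 1e-12)

  # one fragment covering 23 positions is rejected; gaps are config errors
  big <- list(list(start = 1, end = 23, signal = m1s, decoy = m1d))
  expect_error(score_acceptor_decomposed(big, strrep("A", 23)),
               "domain too large")
  gap <- list(list(start = 1, end = 3,
                   signal = train_markov(substr(train7, 1, 3)),
                   decoy = train_markov(substr(train7, 1, 3))),
              list(start = 5, end = 7,
                   signal = train_markov(substr(train7, 5, 7)),
                   decoy = train_markov(substr(train7, 5, 7))))
  expect_error(score_acceptor_decomposed(gap, "ACGGTAC"), "gap")
})

test_that("models serialize to versioned JSON and score tables import", {
  mm <- train_markov(c("ACGT", "TTAC", "GGGT", "ACGG"))
  me <- train_maxent(c("AC", "GT", "AA", "AC"), list(1L, 2L))
  for (model in list(mm, me)) {
    tf <- withr::local_tempfile(fileext = ".json")
    write_splice_model(model, tf)
    back <- read_splice_model(tf)
    probe <- if (model$k == 4) c("ACGT", "AAAA") else c("AC", "GT", "CC")
    for (s in probe)
      expect_equal(seq_prob(back, s), seq_prob(model, s), tolerance = 1e-9)
  }
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kmer\tscore", "CAGGTAAGT\t10.86", "AAAGTAAGA\t5.05"), tf)
  tab <- read_score_table(tf)
  expect_equal(score_table_lookup(tab, "AAAGTAAGA")$value, 5.05)
  expect_error(score_table_lookup(tab, "CCCCCCCCC"), "not present")
})
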