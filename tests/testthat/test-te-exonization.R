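rm_fixture <- function() {
  c("   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end (left)  repeat  class/family  begin end (left)",
    "",
    "  463  1.3  0.6  1.7  chr1  10001  10468  (248945954)  +  SYNSINE1  SINE/Alu  1  463  (0)  1",
    " 239 29.4 10.0  1.6  chr1  10469  11447  (248944975)  C  SYNLTR1  LTR/ERVL  (399)  1712  483  2  *")
}

test_that("RepeatMasker .out rows parse, normalize and round-trip", {
  tf <- withr::local_tempfile()
  writeLines(rm_fixture(), tf)
  hits <- parse_repeatmasker(tf)
  expect_identical(nrow(hits), 2L)
  # '+' row: 1-based inclusive file coords become 0-based half-open
  expect_identical(hits$query_start[1], 10000L)
  expect_identical(hits$query_end[1], 10468L)
  expect_identical(hits$cons_begin[1], 1L)
  expect_identical(hits$te_class[1], "SINE")
  # 'C' row: consensus coordinates normalized, orientation retained,
  # parenthesized consensus-left parsed, trailing ID/* tolerated
  expect_identical(hits$orientation[2], "C")
  expect_identical(hits$cons_begin[2], 483L)
  expect_identical(hits$cons_end[2], 1712L)
  expect_identical(hits$cons_left[2], 399L)
  expect_equal(hits$divergence[2], 29.4)

  tf2 <- withr::local_tempfile()
  write_repeatmasker(hits, tf2)
  back <- parse_repeatmasker(tf2)
  for (col in c("query_start", "query_end", "orientation", "family",
                "cons_begin", "cons_end", "cons_left"))
    expect_identical(back[[col]], hits[[col]])

  # empty file after headers
  tf3 <- withr::local_tempfile()
  writeLines(rm_fixture()[1:3], tf3)
  expect_identical(nrow(parse_repeatmasker(tf3)), 0L)

  # malformed row reported with line number
  tf4 <- withr::local_tempfile()
  writeLines(c(rm_fixture()[1:4], "  12 1.0 chr1 broken"), tf4)
  expect_error(parse_repeatmasker(tf4), "line 5")
})

test_that("te_at picks the maximal-overlap hit", {
  hits <- composite_te_hits()
  expect_identical(te_at(c(1600, 1620), hits)$family, "AluJlike")
  expect_null(te_at(c(100, 200), hits))
  # 7 nt overlap beats 2 nt overlap across the 1500 junction
  expect_identical(te_at(c(1498, 1507), hits)$family, "AluJlike")
  expect_identical(te_at(c(1493, 1502), hits)$family, "LTR78like")
})

test_that("nested clusters are detected from split-insertion geometry", {
  hits <- composite_te_hits()
  cl <- detect_clusters(hits, gap_tol = 30)
  splits <- Filter(function(x) x$type == "split", cl)
  expect_length(splits, 1L)
  expect_identical(splits[[1]]$outer$family, c("LTR78like", "LTR78like"))
  expect_identical(splits[[1]]$inner$family, "AluJlike")
  expect_identical(splits[[1]]$resumption_gap, -6L)

  # invariant to input order
  cl_rev <- detect_clusters(hits[3:1, ], gap_tol = 30)
  expect_identical(clusters_table(cl_rev), clusters_table(cl))

  # isolated hit: no clusters
  expect_length(detect_clusters(hits[2, , drop = FALSE]), 0L)

  # consensus gap beyond the tolerance breaks the signature
  far <- hits; far$cons_begin[3] <- 800L; far$cons_end[3] <- 1000L
  expect_length(detect_clusters(far, gap_tol = 30), 0L)

  # containment of a different family inside one hit's span
  cont <- hits[1:2, ]
  cont$query_start <- c(1000L, 1100L); cont$query_end <- c(2000L, 1300L)
  got <- detect_clusters(cont, gap_tol = 30)
  expect_identical(got[[1]]$type, "containment")
  expect_identical(got[[1]]$outer$family, "LTR78like")
})

test_that("splice signals are attributed to the elements that host them", {
  hits <- composite_te_hits()
  # composite-pseudoexon arrangement: acceptor + branch point in the outer
  # LTR-like element, donor in the nested SINE-like element
  signals <- list(three_prime_ss = c(1450, 1470),
                  BPS = c(1420, 1427),
                  five_prime_ss = c(1700, 1709))
  att <- attribute_signals(signals, hits)
  expect_identical(att$family[att$signal == "three_prime_ss"], "LTR78like")
  expect_identical(att$family[att$signal == "BPS"], "LTR78like")
  expect_identical(att$family[att$signal == "five_prime_ss"], "AluJlike")
  expect_false(any(att$partial))

  # a pseudoexon fully outside the hits maps to nothing
  att0 <- attribute_signals(list(five_prime_ss = c(100, 109)), hits)
  expect_true(is.na(att0$family))

  # a motif straddling a hit boundary is flagged partial
  attp <- attribute_signals(list(BPS = c(2015, 2023)), hits)
  expect_true(attp$partial)
  expect_identical(attp$family, "LTR78like")
})

test_that("homologous decoy donors are found by anchored global alignment", {
  anchor <- "CCTGTAATCCCAGCACTTTGGGAGGCAAAGGCAGGTGGAT"
  off <- 26L  # 0-based first intronic base of the decoy donor
  expect_identical(substr(anchor, off + 1L, off + 2L), "AA") # context check

  res <- find_homologous_5ss(c(self = anchor), anchor, off)
  expect_true(res$matched)
  expect_equal(res$identity_9mer, 1)
  expect_identical(res$candidate_5ss_offset, off)

  # deleting the donor region abolishes the match
  gone <- paste0(substr(anchor, 1, off - 6), substr(anchor, off + 10, 40))
  res2 <- find_homologous_5ss(c(del = gone), anchor, off)
  expect_false(res2$matched)

  # five scattered substitutions away from the donor keep the match and
  # the hand-computed global identity
  cand <- anchor
  for (p in c(2L, 8L, 14L, 36L, 39L))
    substr(cand, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(cand, p, p))[1]
  res3 <- find_homologous_5ss(c(sub5 = cand), anchor, off)
  expect_true(res3$matched)
  expect_equal(res3$identity_9mer, 1)
  expect_equal(res3$identity_global, 35 / 40)

  expect_warning(out <- find_homologous_5ss(c(tiny = "ACGT"), anchor, off),
                 "shorter than 9")
  expect_null(out)
})
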