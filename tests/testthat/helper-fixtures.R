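# Shared fixtures, built in code at test time.

# A plus-strand toy gene: exon 0-80, intron 80-280, exon 280-380,
# intron 380-530, exon 530-600 (0-based half-open, sense coordinates).
toy_gene_model <- function() {
  gene_model("TOYGENE", "toy_contig", "+",
             data.frame(start = c(0, 280, 530), end = c(80, 380, 600)))
}

toy_genome <- function(seed = 401) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  # stamp canonical dinucleotides on the toy gene's authentic junctions
  substr(s, 81, 82) <- "GT"; substr(s, 279, 280) <- "AG"
  substr(s, 381, 382) <- "GT"; substr(s, 529, 530) <- "AG"
  c(toy_contig = s)
}

# RepeatMasker fixture mimicking a split LTR-like element interrupted by a
# younger SINE-like copy (the composite-pseudoexon geometry): outer
# fragments resume consensus 1-210 / 205-420.
composite_te_hits <- function() {
  h <- data.frame(
    query_chrom = "toy_contig",
    query_start = c(1000L, 1500L, 1810L),
    query_end = c(1500L, 1810L, 2020L),
    query_left = 0L,
    orientation = "+",
    family = c("LTR78like", "AluJlike", "LTR78like"),
    te_class = c("LTR", "SINE", "LTR"),
    cons_begin = c(1L, 1L, 205L),
    cons_end = c(210L, 310L, 420L),
    cons_left = c(210L, 0L, 0L),
    score = c(800, 900, 700), divergence = c(18, 12, 18),
    stringsAsFactors = FALSE)
  class(h) <- c("repeat_hits", "data.frame")
  h
}

random_rna <- function(n, bases = c("A", "C", "G", "U"), prob = NULL) {
  paste(sample(bases, n, TRUE, prob = prob), collapse = "")
}

# build a lane pair (plus/minus) with arbitrary values for property tests
random_lanes <- function(n = 40, seed = 7) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  list(plus = lane_profile(runif(n, 0, 5), full_length = 3.7, reagent = "NAI"),
       minus = lane_profile(runif(n, 0, 1), full_length = 4.1,
                            reagent = "none"))
}
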