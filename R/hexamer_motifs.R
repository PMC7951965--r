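#' Load an ESRseq hexamer score table
#'
#' Two-column TSV (hexamer, score). Keys are uppercased 6-mers over ACGT;
#' lookups of hexamers absent from the table return a score of 0
#' (Neutral). The package bundles a small synthetic-provenance fixture
#' table (`esr_hexamers_probe_fixture.tsv`) holding the published scores
#' of the hexamers around the probed adenines and the apical triloop; the
#' full genome-wide table can be supplied by the user in the same format.
#'
#' @param path TSV path; default is the bundled fixture.
#' @return named numeric vector of class `esr_table`.
#' @export
read_esr_table <- function(path = system.file("extdata",
                                              "esr_hexamers_probe_fixture.tsv",
                                              package = "crypticsplice")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  hx <- toupper(df[[1]])
  if (any(nchar(hx) != 6) || any(grepl("[^ACGT]", hx)))
    stop("ESR table keys must be 6-mers over ACGT")
  v <- as.numeric(df[[2]])
  names(v) <- hx
  class(v) <- "esr_table"
  v
}

#' Hexamer windows containing a position
#'
#' The six overlapping windows `[pos-5, pos] ... [pos, pos+5]` (0-based
#' starts), intersected with the sequence bounds, in 5'->3' order.
#' Internal positions (>= 5 from either end) yield exactly six windows.
#'
#' @param seq character sequence.
#' @param pos 0-based position of interest.
#' @return data.frame: start (0-based), hexamer.
#' @export
hexamers_containing <- function(seq, pos) {
  n <- nchar(seq)
  if (pos < 0 || pos >= n) stop("pos outside sequence")
  starts <- max(0L, pos - 5L):min(pos, n - 6L)
  starts <- starts[starts >= 0L & starts + 6L <= n]
  data.frame(start = starts,
             hexamer = substring(seq, starts + 1L, starts + 6L),
             stringsAsFactors = FALSE)
}

#' Hexamer windows fully containing a sub-range
#'
#' All 6-mer windows that contain the whole 0-based half-open range
#' `[start, start+width)`; a trinucleotide has exactly four such windows
#' when away from the sequence ends.
#' @param seq character sequence.
#' @param start 0-based range start.
#' @param width range width (<= 6).
#' @return data.frame: start, hexamer.
#' @export
hexamers_covering <- function(seq, start, width) {
  n <- nchar(seq)
  if (width > 6) stop("a 6-mer cannot contain a range wider than 6")
  if (start < 0 || start + width > n) stop("range outside sequence")
  s <- max(0L, start + width - 6L):min(start, n - 6L)
  s <- s[s >= 0L & s + 6L <= n]
  data.frame(start = s, hexamer = substring(seq, s + 1L, s + 6L),
             stringsAsFactors = FALSE)
}

#' Score hexamer windows and assign enhancer/silencer classes
#'
#' Assignment follows the score sign: > 0 Enhancer, < 0 Silencer, 0 (or
#' absent from the table) Neutral. Windows containing non-ACGT characters
#' are skipped with a warning.
#'
#' @param windows data.frame with a `hexamer` column (and optional
#'   `start`).
#' @param table `esr_table`.
#' @return data.frame: start, hexamer, score, assignment.
#' @export
score_windows <- function(windows, table) {
  hx <- toupper(windows$hexamer)
  ok <- !grepl("[^ACGT]", hx)
  if (any(!ok))
    warning("skipped ", sum(!ok), " window(s) with non-ACGT characters")
  windows <- windows[ok, , drop = FALSE]
  hx <- hx[ok]
  score <- unname(ifelse(hx %in% names(table), table[hx], 0))
  data.frame(start = if ("start" %in% names(windows)) windows$start else NA,
             hexamer = hx, score = score,
             assignment = ifelse(score > 0, "Enhancer",
                                 ifelse(score < 0, "Silencer", "Neutral")),
             stringsAsFactors = FALSE)
}

#' Summarize scored hexamer windows
#' @param scored output of [score_windows()], >= 1 row.
#' @return list(median_score, counts (named: Enhancer/Silencer/Neutral),
#'   n).
#' @export
motif_summary <- function(scored) {
  if (!nrow(scored)) stop("no scored windows to summarize")
  counts <- table(factor(scored$assignment,
                         levels = c("Enhancer", "Silencer", "Neutral")))
  list(median_score = median_value(scored$score),
       counts = counts, n = nrow(scored))
}
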