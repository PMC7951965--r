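#' Parse a RepeatMasker .out annotation file
#'
#' Reads the standard layout (3 header lines, whitespace-separated columns,
#' 'C' orientation rows carrying a parenthesized consensus-left field).
#' Query coordinates are converted to 0-based half-open; minus-strand
#' ('C') consensus coordinates are normalized so `cons_begin <= cons_end`
#' while the orientation flag is retained. Versions that append an ID
#' column and/or an asterisk overlap flag are tolerated by column-count
#' sniffing.
#'
#' @param path path to a `.out` file.
#' @return data.frame of class `repeat_hits`: query_chrom, query_start,
#'   query_end, query_left, orientation, family, te_class, cons_begin,
#'   cons_end, cons_left, score, divergence.
#' @export
parse_repeatmasker <- function(path) {
  lines <- readLines(path)
  # drop the banner: header lines contain no leading numeric score
  is_data <- grepl("^\\s*\\d", lines)
  data_lines <- lines[is_data]
  empty <- data.frame(query_chrom = character(0), query_start = integer(0),
                      query_end = integer(0), query_left = integer(0),
                      orientation = character(0), family = character(0),
                      te_class = character(0), cons_begin = integer(0),
                      cons_end = integer(0), cons_left = integer(0),
                      score = numeric(0), divergence = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(data_lines)) { class(empty) <- c("repeat_hits", "data.frame"); return(empty) }
  paren <- function(x) as.integer(gsub("[()]", "", x))
  rows <- vector("list", length(data_lines))
  lineno <- which(is_data)
  for (i in seq_along(data_lines)) {
    f <- strsplit(trimws(data_lines[i]), "\\s+")[[1]]
    if (tail(f, 1) == "*") f <- f[-length(f)]
    if (length(f) < 14L)
      stop(sprintf("malformed RepeatMasker row at line %d (%d fields)",
                   lineno[i], length(f)))
    orient <- f[9]
    if (!orient %in% c("+", "C"))
      stop(sprintf("bad orientation '%s' at line %d", orient, lineno[i]))
    if (orient == "+") {
      cb <- as.integer(f[12]); ce <- as.integer(f[13]); cl <- paren(f[14])
    } else {
      cl <- paren(f[12])
      a <- as.integer(f[13]); b <- as.integer(f[14])
      cb <- min(a, b); ce <- max(a, b)
    }
    if (anyNA(c(cb, ce, cl)) || cb > ce || cb < 1)
      stop(sprintf("bad consensus coordinates at line %d", lineno[i]))
    rows[[i]] <- data.frame(
      query_chrom = f[5],
      query_start = as.integer(f[6]) - 1L,   # file is 1-based inclusive
      query_end = as.integer(f[7]),
      query_left = paren(f[8]),
      orientation = orient,
      family = f[10],
      te_class = strsplit(f[11], "/")[[1]][1],
      cons_begin = cb, cons_end = ce, cons_left = cl,
      score = as.numeric(f[1]), divergence = as.numeric(f[2]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("repeat_hits", "data.frame")
  out
}

#' Write repeat hits back to .out layout
#'
#' Whitespace-normalized writer; `parse_repeatmasker` round-trips through
#' it field-for-field.
#' @param hits `repeat_hits`.
#' @param path output path.
#' @export
write_repeatmasker <- function(hits, path) {
  hdr <- c("   SW  perc perc perc  query     position in query     matching  repeat        position in repeat",
           "score  div. del. ins.  sequence  begin end      (left) repeat    class/family  begin end (left)",
           "")
  body <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    cons <- if (h$orientation == "+")
      sprintf("%d %d (%d)", h$cons_begin, h$cons_end, h$cons_left)
    else
      sprintf("(%d) %d %d", h$cons_left, h$cons_end, h$cons_begin)
    sprintf("%g %.1f 0.0 0.0 %s %d %d (%d) %s %s %s %s",
            h$score, h$divergence, h$query_chrom, h$query_start + 1L,
            h$query_end, h$query_left, h$orientation, h$family,
            paste0(h$te_class, "/", h$family), cons)
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Repeat hit with maximal overlap over an interval
#'
#' @param interval numeric length-2: 0-based half-open (start, end).
#' @param hits `repeat_hits`.
#' @return single-row data.frame, or NULL when nothing overlaps.
#' @export
te_at <- function(interval, hits) {
  if (!nrow(hits)) return(NULL)
  ov <- pmax(0L, pmin(hits$query_end, interval[2]) -
               pmax(hits$query_start, interval[1]))
  if (max(ov) == 0L) return(NULL)
  hits[which.max(ov), , drop = FALSE]
}

#' Detect nested transposed-element clusters
#'
#' Reports two signatures of a younger element inserted into an older one:
#' (a) *split insertions* -- two same-family, same-orientation fragments
#' adjacent in query order whose consensus coordinates resume within
#' `gap_tol` nt and that bracket at least one hit of a different family;
#' and (b) *containments* -- a hit of a different family lying entirely
#' inside another hit's query span. The interrupted (outer) element is the
#' older one by geometry; no subfamily age tables are consulted.
#'
#' @param hits `repeat_hits` from one contiguous region.
#' @param gap_tol tolerated consensus resumption gap in nt (default 30,
#'   the scale of target-site duplications plus edge truncation).
#' @return list of clusters; each is
#'   `list(type, outer (rows), inner (rows), resumption_gap)`.
#' @export
detect_clusters <- function(hits, gap_tol = 30) {
  out <- list()
  if (nrow(hits) < 2L) return(out)
  hits <- hits[order(hits$query_start, hits$query_end), , drop = FALSE]
  key <- paste(hits$family, hits$orientation)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    if (length(idx) < 2L) next
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b <- idx[j + 1L]
      between <- which(hits$query_start >= hits$query_end[a] &
                         hits$query_end <= hits$query_start[b] &
                         hits$family != hits$family[a])
      if (!length(between)) next
      gap <- if (hits$orientation[a] == "+")
        hits$cons_begin[b] - hits$cons_end[a] - 1L
      else
        hits$cons_begin[a] - hits$cons_end[b] - 1L
      if (abs(gap) <= gap_tol)
        out[[length(out) + 1L]] <- list(type = "split",
                                        outer = hits[c(a, b), , drop = FALSE],
                                        inner = hits[between, , drop = FALSE],
                                        resumption_gap = as.integer(gap))
    }
  }
  for (a in seq_len(nrow(hits))) for (b in seq_len(nrow(hits))) {
    if (a == b || hits$family[a] == hits$family[b]) next
    if (hits$query_start[b] > hits$query_start[a] &&
        hits$query_end[b] < hits$query_end[a])
      out[[length(out) + 1L]] <- list(type = "containment",
                                      outer = hits[a, , drop = FALSE],
                                      inner = hits[b, , drop = FALSE],
                                      resumption_gap = NA_integer_)
  }
  out
}

#' Summarize clusters as a BED-like table
#' @param clusters output of [detect_clusters()].
#' @return data.frame: chrom, start, end, outer_family, inner_family,
#'   resumption_gap, type.
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), outer_family = character(0),
                      inner_family = character(0),
                      resumption_gap = integer(0), type = character(0)))
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    chrom = cl$outer$query_chrom[1],
    start = min(cl$outer$query_start, cl$inner$query_start),
    end = max(cl$outer$query_end, cl$inner$query_end),
    outer_family = cl$outer$family[1],
    inner_family = paste(unique(cl$inner$family), collapse = ","),
    resumption_gap = cl$resumption_gap,
    type = cl$type, stringsAsFactors = FALSE)))
}

#' Attribute splice signals to transposed elements
#'
#' Maps each signal interval (5'ss, 3'ss, BPS, PPT, ...) to the repeat hit
#' with maximal overlap; signals straddling a hit boundary are flagged
#' `partial` (an element can contribute only part of a motif).
#'
#' @param signals named list of 0-based half-open `(start, end)` intervals.
#' @param hits `repeat_hits`.
#' @return data.frame: signal, family, te_class, overlap, width, partial.
#' @export
attribute_signals <- function(signals, hits) {
  rows <- lapply(names(signals), function(nm) {
    iv <- signals[[nm]]
    width <- iv[2] - iv[1]
    h <- te_at(iv, hits)
    if (is.null(h))
      return(data.frame(signal = nm, family = NA_character_,
                        te_class = NA_character_, overlap = 0L,
                        width = width, partial = FALSE,
                        stringsAsFactors = FALSE))
    ov <- min(h$query_end, iv[2]) - max(h$query_start, iv[1])
    data.frame(signal = nm, family = h$family, te_class = h$te_class,
               overlap = as.integer(ov), width = width,
               partial = ov < width, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Find candidate exons using a homologous decoy 5'ss
#'
#' Globally aligns each candidate exon (+flank) sequence to an anchor
#' sequence carrying a marked 5'ss boundary (match +1, mismatch -1, gap
#' open -5, gap extend -1 by default). A candidate matches when it aligns
#' a non-gap base onto the anchor's 5'ss column and the 9-mer footprint
#' around the boundary (anchor positions -3..+6) reaches at least
#' `min_identity` identity (gaps count as mismatches).
#'
#' @param candidates named character vector of candidate sequences.
#' @param anchor anchor sequence.
#' @param anchor_5ss_offset 0-based position in `anchor` of the first
#'   intronic base of the decoy 5'ss.
#' @param min_identity minimum 9-mer identity (default 0.8).
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @return data.frame: id, matched, identity_9mer, identity_global,
#'   candidate_5ss_offset (0-based, NA when the column is a gap).
#' @export
find_homologous_5ss <- function(candidates, anchor, anchor_5ss_offset,
                                min_identity = 0.8, match = 1, mismatch = -1,
                                gap_open = 5, gap_extend = 1) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch)
  rows <- lapply(seq_along(candidates), function(i) {
    id <- names(candidates)[i]
    cand <- toupper(candidates[[i]])
    if (nchar(cand) < 9) {
      warning("candidate '", id, "' shorter than 9 nt; skipped")
      return(NULL)
    }
    aln <- Biostrings::pairwiseAlignment(cand, toupper(anchor),
                                         type = "global",
                                         substitutionMatrix = submat,
                                         gapOpening = gap_open,
                                         gapExtension = gap_extend)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    sub_pos <- cumsum(sub != "-")       # 1-based anchor position per column
    cand_pos <- cumsum(pat != "-")
    col9 <- match((anchor_5ss_offset - 2L):(anchor_5ss_offset + 6L), sub_pos)
    boundary_col <- match(anchor_5ss_offset + 1L, sub_pos)
    id9 <- mean(pat[col9] == sub[col9] & pat[col9] != "-", na.rm = FALSE)
    if (anyNA(col9)) id9 <- NA_real_
    aligned_here <- !is.na(boundary_col) && pat[boundary_col] != "-"
    idg <- mean(pat == sub & pat != "-")
    data.frame(id = if (is.null(id)) as.character(i) else id,
               matched = isTRUE(aligned_here) && !is.na(id9) &&
                 id9 >= min_identity,
               identity_9mer = id9, identity_global = idg,
               candidate_5ss_offset = if (aligned_here)
                 cand_pos[boundary_col] - 1L else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
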