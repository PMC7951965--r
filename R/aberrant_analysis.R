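#' Classify an aberrant site as cryptic or de novo
#'
#' An aberrant site is *cryptic* when the activating mutation falls inside
#' the authentic site's consensus footprint -- for donors the 9-nt
#' MAG/GURAGU footprint (exon -3 .. intron +6), for acceptors the short
#' YAG/G footprint (intron -3 .. exon +1) -- and *de novo* when the
#' mutation lies outside it (e.g. deep-intronic substitutions creating a
#' pseudoexon donor). Boundaries follow the package convention: position of
#' the first intronic base (donor) / first exonic base (acceptor), 0-based.
#'
#' @param records `splice_records` (or any data.frame with `site_kind`,
#'   `authentic_boundary`, `mut_pos` columns).
#' @return character vector "cryptic"/"de_novo", one per record.
#' @export
classify_cryptic_de_novo <- function(records) {
  if (any(is.na(records$authentic_boundary)))
    stop("authentic boundary unset for record(s): ",
         paste(records$id[is.na(records$authentic_boundary)], collapse = ", "))
  b <- records$authentic_boundary
  m <- records$mut_pos
  donor <- records$site_kind == "donor"
  inside <- ifelse(donor,
                   m >= b - 3L & m <= b + 5L,   # exon -3..-1, intron +1..+6
                   m >= b - 3L & m <= b)        # intron -3..-1, exon +1
  ifelse(inside, "cryptic", "de_novo")
}

#' Multiplicity of aberrant sites per mutation
#'
#' Groups records by `multiplicity_group` (one mutation event) and reports
#' how often a single mutation activates more than one aberrant site, at
#' both the event level (multi-site events / events) and the record level
#' (records belonging to multi-site events / all records, the convention
#' behind the published 90/693 figure).
#'
#' @param records `splice_records`.
#' @return list: n_events, n_multi_events, event_fraction, n_records,
#'   n_multi_records, record_fraction.
#' @export
fraction_multiple <- function(records) {
  if (!nrow(records))
    return(list(n_events = 0L, n_multi_events = 0L, event_fraction = NA_real_,
                n_records = 0L, n_multi_records = 0L, record_fraction = NA_real_))
  sizes <- table(records$multiplicity_group)
  multi <- sizes[sizes >= 2L]
  list(n_events = length(sizes),
       n_multi_events = length(multi),
       event_fraction = length(multi) / length(sizes),
       n_records = nrow(records),
       n_multi_records = as.integer(sum(multi)),
       record_fraction = sum(multi) / nrow(records))
}

#' Find strong-cryptic / weak-authentic pairs
#'
#' Returns the subset of scored records whose cryptic (aberrant) site is
#' strictly stronger than its authentic counterpart; ties are excluded.
#' All scores in one call must come from the same model family.
#'
#' @param scored data.frame with columns `id`, `site_kind`, `location`,
#'   `auth_score`, `cryp_score`, `model_id` (plus any others carried along).
#' @return data.frame of class `strong_weak_pairs` with a `delta` column
#'   (cryptic minus authentic, bits).
#' @export
find_strong_weak_pairs <- function(scored) {
  if (nrow(scored) && length(unique(scored$model_id)) > 1L)
    stop("mixed model families in one comparison: ",
         paste(unique(scored$model_id), collapse = ", "))
  keep <- scored$cryp_score > scored$auth_score
  out <- scored[keep, , drop = FALSE]
  out$delta <- out$cryp_score - out$auth_score
  rownames(out) <- NULL
  class(out) <- c("strong_weak_pairs", "data.frame")
  out
}

#' Size of the flank relevant to a strong-cryptic site
#'
#' The exon or intron whose length constrains use of the aberrant site
#' depends on where the site sits: an intronic cryptic 3'ss is constrained
#' by the *downstream exon*, an intronic cryptic 5'ss by the *upstream
#' exon*, an exonic cryptic 3'ss by the *upstream intron* and an exonic
#' cryptic 5'ss by the *downstream intron*. For intronic sites the residual
#' intron -- what remains to be spliced out between the aberrant site and
#' the opposite authentic boundary -- is also returned (human introns below
#' ~70 nt splice poorly, so a short residual predicts failure).
#'
#' @param site_kind "donor" (5'ss) or "acceptor" (3'ss).
#' @param location "intron" or "exon" (where the aberrant site lies).
#' @param aberrant_boundary 0-based sense-strand boundary of the aberrant
#'   site.
#' @param model [gene_model()].
#' @return list(flank_kind, flank_size, residual_intron (NA when exonic)).
#' @export
compute_relevant_flank <- function(site_kind, location, aberrant_boundary,
                                   model) {
  ex <- model$exons
  intr <- gene_introns(model)
  b <- aberrant_boundary
  span <- c(min(ex$start), max(ex$end))
  if (b < span[1] || b > span[2]) stop("aberrant site outside gene span")
  if (location == "intron") {
    i <- which(intr$start <= b & b < intr$end)
    if (!length(i)) stop("aberrant boundary not inside any intron")
    i <- i[1]
    if (site_kind == "acceptor") {
      # new 3'ss in the intron: downstream exon is the constraint; the
      # residual intron is the 5' piece up to the new acceptor
      flank_kind <- "exon"
      flank_size <- ex$end[i + 1L] - ex$start[i + 1L]
      residual <- b - intr$start[i]
    } else {
      # new 5'ss in the intron: upstream exon; residual runs from the new
      # donor to the authentic acceptor
      flank_kind <- "exon"
      flank_size <- ex$end[i] - ex$start[i]
      residual <- intr$end[i] - b
    }
  } else if (location == "exon") {
    e <- which(ex$start <= b & b <= ex$end)
    if (!length(e)) stop("aberrant boundary not inside any exon")
    e <- e[1]
    if (site_kind == "acceptor") {
      if (e < 2L) stop("exonic acceptor in the first exon has no upstream intron")
      flank_kind <- "intron"
      flank_size <- intr$end[e - 1L] - intr$start[e - 1L]
    } else {
      if (e > nrow(intr)) stop("exonic donor in the last exon has no downstream intron")
      flank_kind <- "intron"
      flank_size <- intr$end[e] - intr$start[e]
    }
    residual <- NA_integer_
  } else stop("location must be 'intron' or 'exon'")
  list(flank_kind = flank_kind, flank_size = as.integer(flank_size),
       residual_intron = as.integer(residual))
}

#' Quadrant summary of size constraints
#'
#' Splits strong-weak pairs into the four site-kind x location quadrants
#' and reports, per quadrant, how many have a small relevant flank: exon
#' flanks are "small" at <= `exon_thr` nt, intron flanks at <=
#' `intron_thr` nt (both inclusive).
#'
#' @param pairs data.frame with `site_kind`, `location`, `flank_kind`,
#'   `flank_size` columns (see [compute_relevant_flank()]).
#' @param exon_thr small-exon threshold in nt (default 100).
#' @param intron_thr small-intron threshold in nt (default 200).
#' @return data.frame of class `quadrant_summary`: site_kind, location,
#'   flank_kind, N, n_small, fraction (NA when N = 0), threshold.
#' @export
quadrant_summary <- function(pairs, exon_thr = 100, intron_thr = 200) {
  quads <- expand.grid(site_kind = c("acceptor", "donor"),
                       location = c("intron", "exon"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(quads)), function(q) {
    sel <- pairs$site_kind == quads$site_kind[q] &
      pairs$location == quads$location[q]
    sub <- pairs[sel, , drop = FALSE]
    fk <- if (quads$location[q] == "intron") "exon" else "intron"
    thr <- if (fk == "exon") exon_thr else intron_thr
    n_small <- sum(sub$flank_size <= thr)
    data.frame(site_kind = quads$site_kind[q], location = quads$location[q],
               flank_kind = fk, N = nrow(sub), n_small = n_small,
               fraction = if (nrow(sub)) n_small / nrow(sub) else NA_real_,
               threshold = thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quadrant_summary", "data.frame")
  out
}

#' Two-sided Fisher exact test for a 2x2 table, by enumeration
#'
#' Sums the hypergeometric probabilities of every table with the observed
#' margins whose probability does not exceed the observed table's (the
#' classic two-sided convention). A small numerical slack absorbs ties.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list(p_value, odds_ratio_sample).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integers")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio_sample = or)
}

#' Chi-square test for a 2x2 table
#'
#' Thin wrapper over [stats::chisq.test()] without continuity correction.
#' @param tab 2x2 matrix of counts.
#' @return list(statistic, p_value, df).
#' @export
chi2_2x2 <- function(tab) {
  res <- stats::chisq.test(as.matrix(tab), correct = FALSE)
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter))
}

#' Unpaired two-sample t test with pooled variance
#'
#' Equal-variance (Student) t statistic: the convention behind the reported
#' aberrant-vs-authentic strength comparisons.
#' @param a,b numeric samples.
#' @return list(t, df, p_value).
#' @export
t_unpaired <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need at least two observations per group")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2, p_value = 1))
    stop("zero variance in both samples; t statistic undefined")
  }
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Median with the midpoint convention
#'
#' Mean of the two central order statistics for even n (the default of
#' [stats::median()]); exported so every summary in the package states its
#' convention in one place.
#' @param values numeric vector.
#' @export
median_value <- function(values) {
  if (!length(values)) stop("median of an empty vector")
  stats::median(values)
}

#' Read/write strong-weak pair tables
#'
#' TSV with columns id, site_kind, location, auth_score, cryp_score,
#' model_id, flank_kind, flank_size, residual_intron, delta.
#' @param path TSV path.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("strong_weak_pairs", "data.frame")
  df
}

#' @rdname read_pair_table
#' @param pairs pair table.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
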