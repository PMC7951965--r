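# Seeded generators for every input class the pipeline consumes, each
# emitting its ground truth alongside the data so recovery tests never
# read truth from the generated observables.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

round_half_up <- function(x) floor(x + 0.5)

random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

DONOR_CONSENSUS <- "CAGGTAAGT"     # exon -3..-1 | intron +1..+6

sample_donor_9mer <- function(strength) {
  cons <- strsplit(DONOR_CONSENSUS, "")[[1]]
  out <- vapply(seq_len(9), function(p) {
    if (p %in% 4:5) return(cons[p])        # GT dinucleotide fixed
    if (stats::runif(1) < strength) cons[p]
    else sample(setdiff(DNA_BASES, cons[p]), 1)
  }, character(1))
  paste(out, collapse = "")
}

sample_acceptor_tail <- function(strength, ppt_len = 15) {
  # intron -20..-1: PPT then NAG; exon +1..+3
  py <- vapply(seq_len(20 - 3), function(i)
    if (stats::runif(1) < strength) sample(c("T", "C"), 1, prob = c(0.7, 0.3))
    else sample(c("A", "G"), 1), character(1))
  paste0(paste(py, collapse = ""), sample(c("C", "T"), 1), "AG",
         "G", random_dna(2))
}

#' Specification for a synthetic gene
#'
#' Exon and intron sizes are log-normal; the defaults centre exons on the
#' 139-nt median of human internal exons and keep every intron at or above
#' the ~70 nt minimum of canonical human introns.
#'
#' @param n_exons number of exons (>= 2).
#' @param exon_median,exon_sdlog exon size distribution (nt).
#' @param intron_median,intron_sdlog intron size distribution (nt).
#' @param min_exon,min_intron hard floors (nt).
#' @param donor_strength,acceptor_strength per-position consensus match
#'   probability for splice-site windows, in (0, 1).
#' @param gc background GC content.
#' @return list of class `gene_spec`.
#' @export
gene_spec <- function(n_exons = 5, exon_median = 139, exon_sdlog = 0.45,
                      intron_median = 800, intron_sdlog = 0.6,
                      min_exon = 30, min_intron = 70,
                      donor_strength = 0.85, acceptor_strength = 0.85,
                      gc = 0.45) {
  stopifnot(n_exons >= 2, exon_median >= min_exon, intron_median >= min_intron)
  structure(as.list(environment()), class = "gene_spec")
}

#' Generate a synthetic gene with known structure
#'
#' Builds a gene whose introns all start GT and end AG, whose splice-site
#' windows are sampled from consensus-biased signal distributions, and
#' whose exon/intron sizes follow the spec's log-normal distributions.
#' Deterministic given (spec, seed).
#'
#' @param spec [gene_spec()].
#' @param seed integer seed.
#' @param gene,chrom labels for the emitted [gene_model()].
#' @return list(sequence (character), model ([gene_model()]),
#'   truth = list(exon_sizes, intron_sizes, donor_windows,
#'   acceptor_windows, donor_boundaries, acceptor_boundaries)).
#' @export
gen_gene <- function(spec, seed, gene = "SYNGENE", chrom = "synthetic_contig") {
  with_seed(seed, {
    ne <- spec$n_exons
    exon_sizes <- pmax(spec$min_exon,
                       round(stats::rlnorm(ne, log(spec$exon_median),
                                           spec$exon_sdlog)))
    intron_sizes <- pmax(spec$min_intron,
                         round(stats::rlnorm(ne - 1, log(spec$intron_median),
                                             spec$intron_sdlog)))
    pieces <- character(0)
    starts <- integer(ne); pos <- 0L
    donor_bound <- integer(ne - 1); acc_bound <- integer(ne - 1)
    donor_win <- character(ne - 1); acc_win <- character(ne - 1)
    for (e in seq_len(ne)) {
      starts[e] <- pos
      pieces <- c(pieces, random_dna(exon_sizes[e], spec$gc))
      pos <- pos + exon_sizes[e]
      if (e < ne) {
        donor_bound[e] <- pos
        intr <- random_dna(intron_sizes[e], spec$gc)
        head9 <- sample_donor_9mer(spec$donor_strength)
        tail23 <- sample_acceptor_tail(spec$acceptor_strength)
        # overwrite: last 3 exon nt + first 6 intron nt with the donor 9-mer;
        # last 20 intron nt + first 3 next-exon nt with the acceptor 23-mer
        prev <- pieces[length(pieces)]
        pieces[length(pieces)] <- paste0(substr(prev, 1, nchar(prev) - 3),
                                         substr(head9, 1, 3))
        intr <- paste0(substr(head9, 4, 9),
                       substr(intr, 7, intron_sizes[e] - 20),
                       substr(tail23, 1, 20))
        pieces <- c(pieces, intr)
        pos <- pos + intron_sizes[e]
        acc_bound[e] <- pos
        donor_win[e] <- head9
        acc_win[e] <- tail23
      }
    }
    seqstr <- paste(pieces, collapse = "")
    # stamp the acceptor's 3 exonic nt onto the next exon start
    for (e in seq_len(ne - 1)) {
      substr(seqstr, acc_bound[e] + 1L, acc_bound[e] + 3L) <-
        substr(acc_win[e], 21, 23)
    }
    model <- gene_model(gene, chrom, "+",
                        data.frame(start = starts,
                                   end = starts + exon_sizes))
    list(sequence = seqstr, model = model,
         truth = list(exon_sizes = exon_sizes, intron_sizes = intron_sizes,
                      donor_windows = donor_win, acceptor_windows = acc_win,
                      donor_boundaries = donor_bound,
                      acceptor_boundaries = acc_bound))
  })
}

#' Build a synthetic transposed-element consensus library
#'
#' Random 150-300 nt consensus sequences with distinct family names; no
#' real repeat sequences are bundled.
#' @param n_families number of families.
#' @param seed integer seed.
#' @param len_range consensus length range.
#' @return named character vector.
#' @export
make_te_library <- function(n_families = 4, seed = 1,
                            len_range = c(150, 300)) {
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n_families, replace = TRUE)
    lib <- vapply(lens, random_dna, character(1))
    names(lib) <- sprintf("SYNTE%d", seq_len(n_families))
    lib
  })
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1)
  paste(v, collapse = "")
}

#' Plant nested transposed-element insertions
#'
#' Inserts `n` diverged copies from the consensus library into a host
#' sequence, oldest first; each later copy lands inside a previously
#' inserted one with probability `nest_prob` (splitting the older copy and
#' leaving the split-insertion signature in the emitted hit table), and in
#' un-occupied host sequence otherwise. The hit table mirrors the
#' post-insertion geometry the way a repeat annotator would report it.
#'
#' @param host host DNA (character).
#' @param library consensus library from [make_te_library()].
#' @param n number of insertions.
#' @param nest_prob probability that an insertion nests into an earlier
#'   copy.
#' @param divergence per-base substitution rate applied to each copy.
#' @param seed integer seed.
#' @param chrom contig label for the hit table.
#' @return list(sequence, hits (`repeat_hits`), truth = list(clusters:
#'   data.frame(outer_family, inner_family, host_pos))).
#' @export
gen_nested_te <- function(host, library, n = 2, nest_prob = 1,
                          divergence = 0.1, seed = 1,
                          chrom = "synthetic_contig") {
  stopifnot(n >= 1, length(library) >= 1)
  with_seed(seed, {
    seqstr <- host
    hits <- NULL   # rows: query_start/end 0-based half-open + consensus coords
    truth <- data.frame(outer_family = character(0), inner_family = character(0),
                        host_pos = integer(0), stringsAsFactors = FALSE)
    fams <- sample(names(library), n, replace = n > length(library))
    add_hit <- function(fam, qs, qe, cb, ce, div) {
      data.frame(query_chrom = chrom, query_start = qs, query_end = qe,
                 query_left = 0L, orientation = "+", family = fam,
                 te_class = "SYNTE",
                 cons_begin = cb, cons_end = ce,
                 cons_left = nchar(library[[fam]]) - ce,
                 score = 1000, divergence = 100 * div,
                 stringsAsFactors = FALSE)
    }
    for (t in seq_len(n)) {
      fam <- fams[t]
      copy <- mutate_sequence(library[[fam]], divergence)
      L <- nchar(copy)
      nest_target <- NULL
      if (t > 1 && stats::runif(1) < nest_prob) {
        # nest into a random earlier full-length copy (only rows that are
        # complete, un-split copies qualify)
        cand <- which(hits$cons_begin == 1 &
                        hits$cons_end == nchar(library[hits$family]) &
                        hits$family != fam)
        if (length(cand)) nest_target <- sample(cand, 1)
      }
      if (!is.null(nest_target)) {
        h <- hits[nest_target, ]
        off <- sample(20:(h$query_end - h$query_start - 20), 1)
        at <- h$query_start + off   # insertion point, 0-based
        # split the older hit into two fragments with resuming consensus
        left <- add_hit(h$family, h$query_start, at, h$cons_begin,
                        h$cons_begin + off - 1L, h$divergence / 100)
        right <- add_hit(h$family, at + L, h$query_end + L,
                         h$cons_begin + off, h$cons_end, h$divergence / 100)
        hits <- hits[-nest_target, , drop = FALSE]
        shift <- hits$query_start >= at
        hits$query_start[shift] <- hits$query_start[shift] + L
        hits$query_end[hits$query_end > at] <-
          hits$query_end[hits$query_end > at] + L
        hits <- rbind(hits, left, right,
                      add_hit(fam, at, at + L, 1L, L, divergence))
        truth <- rbind(truth, data.frame(outer_family = h$family,
                                         inner_family = fam, host_pos = at,
                                         stringsAsFactors = FALSE))
      } else {
        # free position outside existing copies
        repeat {
          at <- sample(0:nchar(seqstr), 1)
          if (is.null(hits) ||
              !any(at > hits$query_start & at < hits$query_end)) break
        }
        if (!is.null(hits)) {
          shift <- hits$query_start >= at
          hits$query_start[shift] <- hits$query_start[shift] + L
          hits$query_end[hits$query_end > at] <-
            hits$query_end[hits$query_end > at] + L
        }
        hits <- rbind(hits, add_hit(fam, at, at + L, 1L, L, divergence))
      }
      seqstr <- paste0(substr(seqstr, 1, at), copy,
                       substr(seqstr, at + 1, nchar(seqstr)))
    }
    rownames(hits) <- NULL
    class(hits) <- c("repeat_hits", "data.frame")
    list(sequence = seqstr, hits = hits, truth = list(clusters = truth))
  })
}

#' Internal donor scoring models used by the event generator
#' @keywords internal
generator_donor_models <- function(n_train = 300, strength = 0.85,
                                   seed = 777) {
  with_seed(seed, {
    signal <- vapply(seq_len(n_train), function(i) sample_donor_9mer(strength),
                     character(1))
    decoy <- vapply(seq_len(n_train), function(i) random_dna(9), character(1))
    list(signal = train_markov(signal, pseudocount = 0.5, site_kind = "donor"),
         decoy = train_markov(decoy, pseudocount = 0.5, site_kind = "donor"))
  })
}

#' Generate a mutation event activating an aberrant donor
#'
#' Cryptic events weaken the authentic donor by a substitution inside its
#' -3..+6 footprint while a pre-existing decoy donor sits `offset` nt into
#' the intron; de novo events plant a one-substitution-away donor deep in
#' the intron and the emitted mutation completes its GT. The aberrant
#' 9-mer is chosen (from up to `n_candidates` signal-model draws) so the
#' realized cryptic-minus-authentic score difference is within `max_miss`
#' of `delta`; an error is raised when the context cannot realize it.
#'
#' @param gene output of [gen_gene()].
#' @param kind "cryptic" or "de_novo".
#' @param delta target score difference (aberrant - authentic, bits).
#' @param seed integer seed.
#' @param intron_index which intron hosts the event.
#' @param offset intron offset of the aberrant donor boundary (default 25
#'   for cryptic, 120 for de novo).
#' @param n_candidates,max_miss search budget and tolerance for the
#'   planted score difference.
#' @return list(sequence (mutated), wt_sequence, record
#'   ([splice_records()] row), truth = list(kind, realized_delta,
#'   models)).
#' @export
gen_aberrant_event <- function(gene, kind = c("cryptic", "de_novo"),
                               delta = 1.17, seed = 1, intron_index = 1,
                               offset = NULL, n_candidates = 400,
                               max_miss = 0.3) {
  kind <- match.arg(kind)
  if (is.null(offset)) offset <- if (kind == "cryptic") 25L else 120L
  mods <- generator_donor_models()
  with_seed(seed, {
    seqstr <- gene$sequence
    ab <- gene$truth$donor_boundaries[intron_index]
    intron_len <- gene$truth$intron_sizes[intron_index]
    if (offset + 30 > intron_len)
      stop("intron too short for the requested offset")
    auth_win <- window_from_sequence(seqstr, ab, "donor")
    auth_score <- score_log2odds(mods$signal, mods$decoy, auth_win)$value
    target <- auth_score + delta
    cand <- vapply(seq_len(n_candidates), function(i)
      sample_donor_9mer(0.85), character(1))
    sc <- vapply(cand, function(x)
      score_log2odds(mods$signal, mods$decoy, x)$value, numeric(1))
    best <- which.min(abs(sc - target))
    if (abs(sc[best] - target) > max_miss)
      stop(sprintf("could not realize delta %.2f within %.2f after %d draws",
                   delta, max_miss, n_candidates))
    planted <- cand[best]
    new_boundary <- ab + offset
    if (kind == "cryptic") {
      # decoy donor fully functional before mutation
      substr(seqstr, new_boundary - 3L + 1L, new_boundary + 6L) <- planted
      # weaken the authentic site inside its footprint: +5 G -> C unless
      # that equals the reference, else +6 T -> A
      mp <- ab + 4L   # intron +5 (0-based)
      ref <- substr(seqstr, mp + 1L, mp + 1L)
      alt <- if (ref != "C") "C" else "A"
      wt <- seqstr
      substr(seqstr, mp + 1L, mp + 1L) <- alt
    } else {
      # plant the donor with intron +2 broken (G[A] instead of G[T])
      broken <- planted
      substr(broken, 5, 5) <- "A"
      substr(seqstr, new_boundary - 3L + 1L, new_boundary + 6L) <- broken
      mp <- new_boundary + 1L  # intron +2 of the new site (0-based)
      ref <- "A"; alt <- "T"
      wt <- seqstr
      substr(seqstr, mp + 1L, mp + 1L) <- alt
    }
    rec <- splice_records(id = sprintf("%s_%s_i%d", gene$model$gene, kind,
                                       intron_index),
                          gene = gene$model$gene, site_kind = "donor",
                          authentic_boundary = ab,
                          aberrant_boundary = new_boundary,
                          mut_pos = mp, ref_base = ref, alt_base = alt,
                          location = "intron")
    realized <- score_log2odds(mods$signal, mods$decoy,
                               window_from_sequence(seqstr, new_boundary,
                                                    "donor"))$value -
      auth_score
    list(sequence = seqstr, wt_sequence = wt, record = rec,
         truth = list(kind = kind, realized_delta = realized,
                      planted_window = planted, auth_score = auth_score,
                      models = mods))
  })
}

#' Simulate probing lanes from a known structure
#'
#' Log-normal band intensities whose means depend on the true paired
#' state (`mu_paired` for paired, `mu_unpaired` for unpaired positions).
#' DMS lanes carry signal only at A/C positions; the background
#' (no-reagent) lane contains the same RT-stop floor that contaminates
#' the +reagent lane, so background subtraction recovers the reagent
#' signal exactly in the noiseless limit. The full-length band is
#' attenuated by `fl_decay` relative to an arbitrary gel loading unit.
#'
#' @param structure `secondary_structure` of the probe.
#' @param seq probe sequence.
#' @param reagent "DMS", "NAI" or "RNaseA".
#' @param mu_paired,mu_unpaired mean normalized signal by paired state.
#' @param sigma log-normal noise sd (log scale).
#' @param bg RT-stop background level present in both lanes.
#' @param fl_decay full-length attenuation factor in (0, 1].
#' @param n_reps replicates per condition.
#' @param seed integer seed.
#' @return list(plus = list of `lane_profile`, minus = list of
#'   `lane_profile`, truth = list(paired (logical), responsive (logical:
#'   positions the reagent can report on))).
#' @export
gen_reactivity <- function(structure, seq, reagent = c("DMS", "NAI", "RNaseA"),
                           mu_paired = 0.1, mu_unpaired = 1.0, sigma = 0.25,
                           bg = 0.05, fl_decay = 0.7, n_reps = 3, seed = 1) {
  reagent <- match.arg(reagent)
  with_seed(seed, {
    n <- structure$length
    stopifnot(nchar(seq) == n)
    paired <- logical(n)
    if (nrow(structure$pairs)) paired[c(structure$pairs)] <- TRUE
    b <- strsplit(chartr("tT", "uU", toupper(seq)), "")[[1]]
    responsive <- switch(reagent,
                         DMS = b %in% c("A", "C"),
                         NAI = rep(TRUE, n),
                         RNaseA = b %in% c("C", "U") & !paired)
    mu <- ifelse(paired, mu_paired, mu_unpaired)
    mu[!responsive] <- 0
    FL <- 1000 * fl_decay
    noise <- function(k) if (sigma > 0) stats::rlnorm(k, -sigma^2 / 2, sigma)
    else rep(1, k)
    mk <- function(level, rep_i, reag)
      lane_profile((level + bg) * FL * noise(n), full_length = FL,
                   reagent = reag, probe_id = "synthetic_probe",
                   replicate = rep_i)
    plus <- lapply(seq_len(n_reps), function(r) mk(mu, r, reagent))
    minus <- lapply(seq_len(n_reps), function(r) mk(0, r, "none"))
    list(plus = plus, minus = minus,
         truth = list(paired = paired, responsive = responsive))
  })
}

#' Default quadrant configuration for the synthetic pair table
#'
#' 92 strong-cryptic/weak-authentic pairs split across the four site-kind
#' x location quadrants, with the small-flank counts and flank medians
#' the quadrant analysis reports on real data: 50 intronic 5'ss (17 with
#' upstream exons <= 100 nt, median 125 nt), 11 exonic 5'ss (1 small
#' downstream intron), 20 intronic 3'ss (5 small downstream exons, median
#' 127 nt) and 11 exonic 3'ss (2 small upstream introns).
#' @export
default_pair_quadrants <- function() {
  data.frame(
    site_kind = c("donor", "donor", "acceptor", "acceptor"),
    location = c("intron", "exon", "intron", "exon"),
    N = c(50L, 11L, 20L, 11L),
    frac_small = c(0.34, 0.09, 0.25, 0.18),
    median_flank = c(125, 900, 127, 900),
    stringsAsFactors = FALSE)
}

sorted_flanks <- function(m, n_small, target, thr) {
  # deterministic sorted flank sizes: exactly n_small at or below thr and
  # the sample median pinned to target (midpoint convention)
  stopifnot(n_small < floor(m / 2), target > thr)
  v <- numeric(m)
  if (n_small > 0) v[1:n_small] <- round(seq(thr * 0.6, thr,
                                             length.out = n_small))
  lo_hi <- if (m %% 2 == 0) c(m / 2, m / 2 + 1) else rep((m + 1) / 2, 2)
  v[lo_hi[1]] <- target; v[lo_hi[2]] <- target
  below <- (n_small + 1):(lo_hi[1] - 1)
  if (length(below) && below[1] <= below[length(below)])
    v[below] <- round(seq(thr + 1, target - 1, length.out = length(below)))
  above <- (lo_hi[2] + 1):m
  if (length(above) && above[1] <= m)
    v[above] <- round(seq(target + 1, target + 3 * length(above) + 10,
                          length.out = length(above)))
  v
}

symmetric_around <- function(m, center, step = 0.02) {
  h <- m %/% 2
  offs <- if (m %% 2 == 1) c(-(h:1), 0, 1:h) else c(-(h:1), 1:h)
  center + step * offs
}

#' Generate a deterministic strong-cryptic/weak-authentic pair table
#'
#' Allocates pairs to the four quadrants with exact small-flank counts
#' (round-half-up of `frac_small * N`), pins each quadrant's flank-size
#' median and each site kind's median score excess to the targets, and
#' records all planted values as truth. The construction is deterministic;
#' `seed` only shuffles row order.
#'
#' @param quadrants configuration data.frame, see
#'   [default_pair_quadrants()].
#' @param median_delta named vector: target median score excess per site
#'   kind (bits).
#' @param exon_thr,intron_thr small-flank thresholds (nt).
#' @param seed integer seed (row shuffling only).
#' @return list(pairs (`strong_weak_pairs`), truth).
#' @export
gen_pair_table <- function(quadrants = default_pair_quadrants(),
                           median_delta = c(acceptor = 1.51, donor = 1.17),
                           exon_thr = 100, intron_thr = 200, seed = 1) {
  rows <- list()
  for (q in seq_len(nrow(quadrants))) {
    m <- quadrants$N[q]
    fk <- if (quadrants$location[q] == "intron") "exon" else "intron"
    thr <- if (fk == "exon") exon_thr else intron_thr
    n_small <- round_half_up(quadrants$frac_small[q] * m)
    fl <- sorted_flanks(m, n_small, quadrants$median_flank[q], thr)
    rows[[q]] <- data.frame(
      site_kind = quadrants$site_kind[q], location = quadrants$location[q],
      flank_kind = fk, flank_size = as.integer(fl),
      residual_intron = if (quadrants$location[q] == "intron")
        as.integer(80 + 5 * seq_len(m)) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  for (kind in unique(df$site_kind)) {
    sel <- df$site_kind == kind
    base <- if (kind == "donor") 7.2 else 8.4
    deltas <- symmetric_around(sum(sel), median_delta[[kind]])
    df$auth_score[sel] <- base
    df$cryp_score[sel] <- base + deltas
  }
  df$model_id <- "synthetic_me_v1"
  df$delta <- df$cryp_score - df$auth_score
  df$id <- sprintf("pair%03d", seq_len(nrow(df)))
  df <- df[, c("id", "site_kind", "location", "auth_score", "cryp_score",
               "model_id", "flank_kind", "flank_size", "residual_intron",
               "delta")]
  df <- with_seed(seed, df[sample(nrow(df)), , drop = FALSE])
  rownames(df) <- NULL
  class(df) <- c("strong_weak_pairs", "data.frame")
  small_truth <- vapply(seq_len(nrow(quadrants)), function(q)
    round_half_up(quadrants$frac_small[q] * quadrants$N[q]), numeric(1))
  list(pairs = df,
       truth = list(quadrants = cbind(quadrants, n_small = small_truth),
                    median_delta = median_delta,
                    exon_thr = exon_thr, intron_thr = intron_thr))
}

#' Generate a splice-site strength vs inclusion-level table
#'
#' Emits `n` exon records whose 5'ss scores and inclusion levels have an
#' exact sample Pearson correlation of `r` (deterministic residualization
#' construction; affine maps preserve the correlation).
#'
#' @param n number of exons.
#' @param r target Pearson correlation.
#' @param seed integer seed.
#' @return data.frame: id, me_score (bits), inclusion (percent).
#' @export
gen_inclusion_table <- function(n = 21, r = -0.09, seed = 1) {
  stopifnot(n >= 3, abs(r) < 1)
  with_seed(seed, {
    x <- stats::rnorm(n)
    z <- stats::rnorm(n)
    zr <- stats::residuals(stats::lm(z ~ x))
    xs <- as.numeric(scale(x)); zs <- as.numeric(scale(zr))
    y <- r * xs + sqrt(1 - r^2) * zs
    data.frame(id = sprintf("alu_exon%02d", seq_len(n)),
               me_score = round(5 + 2 * xs, 4),
               inclusion = round(50 + 15 * y, 4))
  })
}

#' Generate a synthetic aberrant-record set with planted summary fractions
#'
#' Builds `n_total` records of one site kind in which exactly
#' `n_multi_records` belong to multi-site mutation events and exactly
#' `round_half_up(frac_stronger * n_total)` have an aberrant score
#' exceeding the authentic score. Used by recovery tests for the
#' database-wide counting operations.
#'
#' @param n_total total records.
#' @param n_multi_records records that share a mutation with another
#'   record (must be even or formable from pairs).
#' @param frac_stronger fraction with aberrant > authentic.
#' @param site_kind "donor" or "acceptor".
#' @param seed integer seed (shuffling only).
#' @return list(records (data.frame with scores), truth).
#' @export
gen_record_set <- function(n_total = 693, n_multi_records = 90,
                           frac_stronger = 0.13, site_kind = "donor",
                           seed = 1) {
  if (n_multi_records %% 2 == 0) {
    n_pairs <- n_multi_records %/% 2
    groups <- rep(sprintf("mut%04d", seq_len(n_pairs)), each = 2)
  } else {
    # an odd total: one mutation activates three sites, the rest pairs
    if (n_multi_records < 3)
      stop("an odd n_multi_records must be at least 3")
    n_pairs <- (n_multi_records - 3L) %/% 2L
    groups <- c(rep(sprintf("mut%04d", seq_len(n_pairs)), each = 2),
                rep("mut_triple", 3))
  }
  n_single <- n_total - length(groups)
  groups <- c(groups, sprintf("solo%04d", seq_len(n_single)))
  n_strong <- round_half_up(frac_stronger * n_total)
  auth <- rep(8, n_total)
  aber <- c(rep(9, n_strong), rep(6, n_total - n_strong))
  df <- data.frame(id = sprintf("rec%04d", seq_len(n_total)),
                   site_kind = site_kind, multiplicity_group = groups,
                   auth_score = auth, cryp_score = aber,
                   model_id = "synthetic_me_v1", stringsAsFactors = FALSE)
  df <- with_seed(seed, df[sample(n_total), , drop = FALSE])
  rownames(df) <- NULL
  list(records = df,
       truth = list(n_multi_records = n_multi_records, n_strong = n_strong,
                    frac_stronger = n_strong / n_total))
}
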