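# RNA secondary structure types, the simplified nearest-neighbour energy
# model, and an exhaustive enumeration engine usable as an independent
# check of the dynamic-programming folding code on short sequences.

RNA_BASES <- c("A", "C", "G", "U")

# pair type indices: 1 AU, 2 UA, 3 GC, 4 CG, 5 GU, 6 UG (A=1 C=2 G=3 U=4)
PAIR_TYPE <- matrix(0L, 4, 4)
PAIR_TYPE[1, 4] <- 1L; PAIR_TYPE[4, 1] <- 2L
PAIR_TYPE[3, 2] <- 3L; PAIR_TYPE[2, 3] <- 4L
PAIR_TYPE[3, 4] <- 5L; PAIR_TYPE[4, 3] <- 6L

#' Simplified nearest-neighbour RNA energy model
#'
#' Stacking energies for canonical pair steps plus length-dependent loop
#' penalties; no dangling ends or coaxial stacking. Stack energies are
#' `-(s_outer + s_inner)/2` kcal/mol with pair strengths GC/CG = 3,
#' AU/UA = 2, GU/UG = 1. Hairpin loops of length L cost
#' `3.0 + 1.75 RT ln(L/3)`, bulge/internal loops of total unpaired size u
#' cost `2.0 + 1.75 RT ln(u)` (capped at `max_interior` unpaired nt),
#' multiloops an affine `a + b * branches + c * unpaired`. Minimum hairpin
#' loop is 3 nt. All parameters are plain list entries and can be replaced.
#'
#' @param temperature Kelvin (default 310.15).
#' @param max_interior largest allowed bulge/internal loop (default 30).
#' @return list of class `energy_model`.
#' @export
energy_model <- function(temperature = 310.15, max_interior = 30) {
  RT <- 0.0019872 * temperature
  s <- c(2, 2, 3, 3, 1, 1)  # AU UA GC CG GU UG
  stack <- -outer(s, s, "+") / 2
  Lh <- 3:400
  hairpin <- c(rep(Inf, 2), 3.0 + 1.75 * RT * log(Lh / 3))  # index = loop length
  u <- 1:max_interior
  interior <- 2.0 + 1.75 * RT * log(u)
  structure(list(version = "simple-nn/1", temperature = temperature, RT = RT,
                 stack = stack, hairpin = hairpin, interior = interior,
                 max_interior = max_interior,
                 ml_a = 3.4, ml_b = 0.4, ml_c = 0.1, min_hairpin = 3L),
            class = "energy_model")
}

rna_to_ints <- function(seq) {
  s <- chartr("tT", "uU", toupper(seq))
  v <- match(strsplit(s, "")[[1]], RNA_BASES)
  if (anyNA(v)) stop("sequence contains non-ACGU(T) characters")
  v
}

hairpin_energy <- function(model, L) {
  if (L < model$min_hairpin) return(Inf)
  if (L <= length(model$hairpin)) model$hairpin[L]
  else 3.0 + 1.75 * model$RT * log(L / 3)
}

interior_energy <- function(model, u) {
  if (u < 1 || u > model$max_interior) return(Inf)
  model$interior[u]
}

#' Construct (and validate) a secondary structure
#'
#' @param pairs two-column integer matrix of base pairs (1-based, i < j),
#'   or an empty matrix/NULL for the open chain.
#' @param length sequence length.
#' @return object of class `secondary_structure` with fields `length`,
#'   `pairs` (sorted by i) and `db` (dot-bracket string).
#' @export
secondary_structure <- function(pairs, length) {
  if (is.null(pairs) || !length(pairs)) pairs <- matrix(integer(0), 0, 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
    if (any(pairs[, 2] - pairs[, 1] <= 3))
      stop("hairpin loops must span at least 3 unpaired nt (j - i > 3)")
    if (any(pairs < 1) || any(pairs > length)) stop("pair index out of range")
    idx <- c(pairs)
    if (anyDuplicated(idx)) stop("a position participates in more than one pair")
    o <- order(pairs[, 1])
    pairs <- pairs[o, , drop = FALSE]
    # nestedness: no i < k < j < l crossings
    if (nrow(pairs) > 1) {
      for (x in seq_len(nrow(pairs) - 1)) {
        i <- pairs[x, 1]; j <- pairs[x, 2]
        k <- pairs[(x + 1):nrow(pairs), 1]; l <- pairs[(x + 1):nrow(pairs), 2]
        if (any(k < j & l > j)) stop("pseudoknotted (crossing) pairs")
      }
    }
  }
  db <- rep(".", length)
  db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")"
  structure(list(length = as.integer(length), pairs = pairs,
                 db = paste(db, collapse = "")),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pair(s)\n%s\n",
              x$length, nrow(x$pairs), x$db))
  invisible(x)
}

#' Parse a dot-bracket string
#' @param db dot-bracket string (characters `.()`).
#' @return `secondary_structure`.
#' @export
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0); pairs <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced bracket at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    } else if (ch[i] != ".") stop("unexpected character '", ch[i], "'")
  }
  if (length(stack)) stop("unbalanced '(' remaining")
  secondary_structure(pairs, length(ch))
}

#' Write a connectivity-table (CT) file
#' @param structure `secondary_structure`.
#' @param seq the sequence.
#' @param path output path.
#' @param energy optional free energy for the header.
#' @export
write_ct <- function(structure, seq, path, energy = NA) {
  n <- structure$length
  partner <- integer(n)
  if (nrow(structure$pairs)) {
    partner[structure$pairs[, 1]] <- structure$pairs[, 2]
    partner[structure$pairs[, 2]] <- structure$pairs[, 1]
  }
  b <- strsplit(chartr("tT", "uU", toupper(seq)), "")[[1]]
  hdr <- if (is.na(energy)) sprintf("%d structure", n)
  else sprintf("%d dG = %.2f", n, energy)
  lines <- c(hdr, sprintf("%d %s %d %d %d %d", 1:n, b, 0:(n - 1),
                          c(2:n, 0), partner, 1:n))
  writeLines(lines, path)
  invisible(path)
}

#' Free energy of a given structure under the model
#'
#' Direct loop decomposition of an explicit pair set: hairpins, stacks,
#' bulge/internal loops and affine multiloops; the exterior loop is free.
#' This is the *definition* of the energy model -- the folding recursions
#' are checked against it.
#'
#' @param structure `secondary_structure` (or a 2-column pair matrix).
#' @param seq sequence.
#' @param model [energy_model()].
#' @return energy in kcal/mol (`Inf` for loops the model disallows).
#' @export
structure_energy <- function(structure, seq, model = energy_model()) {
  pairs <- if (inherits(structure, "secondary_structure")) structure$pairs
  else matrix(as.integer(structure), ncol = 2)
  v <- rna_to_ints(seq)
  np <- nrow(pairs)
  if (!np) return(0)
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  # parent of each pair via a stack sweep
  parent <- integer(np)
  children <- vector("list", np + 1L)  # last slot: exterior
  stack <- integer(0)
  events <- order(c(pairs[, 1], pairs[, 2]))
  pos <- c(pairs[, 1], pairs[, 2])[events]
  which_pair <- c(seq_len(np), seq_len(np))[events]
  is_open <- c(rep(TRUE, np), rep(FALSE, np))[events]
  for (e in seq_along(events)) {
    p <- which_pair[e]
    if (is_open[e]) {
      parent[p] <- if (length(stack)) stack[length(stack)] else 0L
      ci <- parent[p] + 1L
      children[[ci]] <- c(children[[ci]], p)
      stack <- c(stack, p)
    } else stack <- stack[-length(stack)]
  }
  # children were appended parent-index+1; exterior is children[[1]]
  E <- 0
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    pt_out <- PAIR_TYPE[v[i], v[j]]
    if (pt_out == 0L) return(Inf)
    kids <- children[[p + 1L]]
    if (!length(kids)) {
      E <- E + hairpin_energy(model, j - i - 1L)
    } else if (length(kids) == 1L) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      if (k == i + 1L && l == j - 1L) {
        pt_in <- PAIR_TYPE[v[k], v[l]]
        E <- E + model$stack[pt_out, pt_in]
      } else {
        E <- E + interior_energy(model, (k - i - 1L) + (j - l - 1L))
      }
    } else {
      unp <- (j - i - 1L) - sum(pairs[kids, 2] - pairs[kids, 1] + 1L)
      E <- E + model$ml_a + model$ml_b * (length(kids) + 1L) + model$ml_c * unp
    }
    if (!is.finite(E)) return(Inf)
  }
  E
}

#' Exhaustively enumerate nested structures of a short sequence
#'
#' All pseudoknot-free structures over the canonical pairs with minimum
#' hairpin loop 3, optionally excluding pairs touching `forced_unpaired`
#' positions. Exponential: intended for sequences up to ~16 nt as an
#' independent check of the folding recursions.
#'
#' @param seq sequence (<= 20 nt enforced).
#' @param forced_unpaired positions barred from pairing.
#' @return list of 2-column pair matrices (the first entry is the open
#'   chain).
#' @export
enumerate_structures <- function(seq, forced_unpaired = integer(0)) {
  v <- rna_to_ints(seq)
  n <- length(v)
  if (n > 20) stop("enumeration is limited to 20 nt")
  ok <- !(seq_len(n) %in% forced_unpaired)
  rec <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(0), 0, 2)))
    out <- rec(i + 1L, j)                       # i unpaired
    if (ok[i]) {
      for (l in (i + 4L):j) {
        if (!ok[l] || PAIR_TYPE[v[i], v[l]] == 0L) next
        inner <- rec(i + 1L, l - 1L)
        right <- if (l < j) rec(l + 1L, j) else list(matrix(integer(0), 0, 2))
        for (a in inner) for (b in right)
          out[[length(out) + 1L]] <- rbind(c(i, l), a, b)
      }
    }
    out
  }
  rec(1L, n)
}

#' Brute-force folding by enumeration
#'
#' Computes the minimum free energy, the Boltzmann partition function and
#' every pair probability by summing over [enumerate_structures()] output.
#' Serves as the independent oracle for [mfe_fold()] and [partition()].
#'
#' @inheritParams enumerate_structures
#' @param model [energy_model()].
#' @return list(mfe, mfe_pairs, Z, pair_prob (n x n upper-triangular
#'   matrix), n_structures).
#' @export
brute_force_fold <- function(seq, model = energy_model(),
                             forced_unpaired = integer(0)) {
  structs <- enumerate_structures(seq, forced_unpaired)
  n <- nchar(seq)
  Z <- 0; best <- Inf; best_pairs <- matrix(integer(0), 0, 2)
  pp <- matrix(0, n, n)
  kept <- 0L
  for (s in structs) {
    E <- structure_energy(s, seq, model)
    if (!is.finite(E)) next
    kept <- kept + 1L
    w <- exp(-E / model$RT)
    Z <- Z + w
    if (E < best - 1e-12 ||
        (abs(E - best) <= 1e-12 && nrow(s) < nrow(best_pairs))) {
      best <- E; best_pairs <- s
    }
    if (nrow(s)) for (r in seq_len(nrow(s)))
      pp[s[r, 1], s[r, 2]] <- pp[s[r, 1], s[r, 2]] + w
  }
  list(mfe = if (is.finite(best)) best else 0, mfe_pairs = best_pairs,
       Z = Z, pair_prob = pp / Z, n_structures = kept)
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two pair sets; a metric on
#' structures of equal length.
#' @param s1,s2 `secondary_structure`s of the same length.
#' @export
base_pair_distance <- function(s1, s2) {
  if (s1$length != s2$length) stop("structures have different lengths")
  key <- function(s) if (nrow(s$pairs)) paste(s$pairs[, 1], s$pairs[, 2])
  else character(0)
  k1 <- key(s1); k2 <- key(s2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Annotate helices and loops
#'
#' Maximal runs of stacked pairs of length >= `min_stack` are reported as
#' helices; hairpin-closing pairs yield the loop (cap) sequence.
#'
#' @param structure `secondary_structure`.
#' @param seq sequence.
#' @param min_stack minimum contiguous stacked pairs for a helix
#'   (default 3).
#' @return list(helices: data.frame(i_start, j_start, length),
#'   hairpins: data.frame(i, j, loop_seq), n_multiloops).
#' @export
stems_and_loops <- function(structure, seq, min_stack = 3) {
  pairs <- structure$pairs
  sseq <- chartr("tT", "uU", toupper(seq))
  helices <- data.frame(i_start = integer(0), j_start = integer(0),
                        length = integer(0))
  hairpins <- data.frame(i = integer(0), j = integer(0),
                         loop_seq = character(0), stringsAsFactors = FALSE)
  if (!nrow(pairs))
    return(list(helices = helices, hairpins = hairpins, n_multiloops = 0L))
  pset <- paste(pairs[, 1], pairs[, 2])
  has_pair <- function(i, j) paste(i, j) %in% pset
  used <- logical(nrow(pairs))
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    if (used[r]) next
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (has_pair(i - 1L, j + 1L)) next   # not the outermost pair of its run
    len <- 1L
    while (has_pair(i + len, j - len)) len <- len + 1L
    for (d in 0:(len - 1L))
      used[which(pairs[, 1] == i + d & pairs[, 2] == j - d)] <- TRUE
    if (len >= min_stack)
      helices <- rbind(helices, data.frame(i_start = i, j_start = j,
                                           length = len))
  }
  # hairpin loops: pairs with no pair inside
  n_ml <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    inside <- pairs[, 1] > i & pairs[, 2] < j
    if (!any(inside)) {
      hairpins <- rbind(hairpins,
                        data.frame(i = i, j = j,
                                   loop_seq = substr(sseq, i + 1L, j - 1L),
                                   stringsAsFactors = FALSE))
    } else {
      kids <- which(inside)
      # direct children only
      direct <- kids[vapply(kids, function(k) {
        !any(pairs[kids, 1] < pairs[k, 1] & pairs[kids, 2] > pairs[k, 2])
      }, logical(1))]
      if (length(direct) >= 2L) n_ml <- n_ml + 1L
    }
  }
  list(helices = helices, hairpins = hairpins, n_multiloops = n_ml)
}

#' Fraction of a reference stem present in a structure
#' @param reference_pairs 2-column pair matrix of the reference stem.
#' @param structure `secondary_structure`.
#' @return fraction in [0, 1].
#' @export
stem_presence <- function(reference_pairs, structure) {
  reference_pairs <- matrix(as.integer(reference_pairs), ncol = 2)
  if (!nrow(reference_pairs)) stop("empty reference stem")
  have <- paste(structure$pairs[, 1], structure$pairs[, 2])
  mean(paste(reference_pairs[, 1], reference_pairs[, 2]) %in% have)
}
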