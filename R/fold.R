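# Zuker-style minimum-free-energy folding and McCaskill partition-function
# recursions over the simplified nearest-neighbour model in energy_model().
# Decomposition: V (closed by a pair), WM (multiloop segment with >= 1
# branch; each branch costs ml_b, each unpaired nt ml_c), exterior loop
# free. Interior loops are capped at model$max_interior unpaired nt, the
# same cap structure_energy() applies, so the recursions and the explicit
# loop decomposition describe the same ensemble.

fold_prep <- function(seq, model, constraints) {
  v <- rna_to_ints(seq)
  n <- length(v)
  mask <- logical(n)
  if (length(constraints)) {
    constraints <- as.integer(constraints)
    if (any(constraints < 1 | constraints > n))
      stop("constraint position out of range")
    mask[constraints] <- TRUE
  }
  pt <- matrix(0L, n, n)
  for (i in seq_len(max(n - 4L, 0L))) for (j in (i + 4L):n)
    if (!mask[i] && !mask[j]) pt[i, j] <- PAIR_TYPE[v[i], v[j]]
  list(v = v, n = n, mask = mask, pt = pt)
}

#' Minimum free energy fold
#'
#' Nested MFE structure under the simplified nearest-neighbour model,
#' honouring a set of positions forced to stay unpaired (hard
#' constraints). Traceback is deterministic: on energy ties (within 1e-9
#' kcal/mol) the option with fewer pairs is taken first, then options are
#' examined in a fixed enumeration order (hairpin, then interior loops by
#' ascending inner pair, then multiloop splits).
#'
#' @param seq RNA (or DNA; T read as U) sequence.
#' @param model [energy_model()].
#' @param constraints integer positions forced unpaired.
#' @return list(structure = [secondary_structure()], energy).
#' @export
mfe_fold <- function(seq, model = energy_model(), constraints = integer(0)) {
  fp <- fold_prep(seq, model, constraints)
  n <- fp$n; pt <- fp$pt
  tol <- 1e-9
  if (n < 5)
    return(list(structure = secondary_structure(NULL, n), energy = 0))
  V <- matrix(Inf, n, n)
  WM <- matrix(Inf, n, n)
  mi <- model$max_interior
  for (d in 4:(n - 1)) for (i in seq_len(n - d)) {
    j <- i + d
    if (pt[i, j] > 0L) {
      best <- hairpin_energy(model, d - 1L)
      kmax <- min(j - 5L, i + 1L + mi)
      if (kmax >= i + 1L) for (k in (i + 1L):kmax) {
        u1 <- k - i - 1L
        lmin <- max(k + 4L, j - 1L - (mi - u1))
        if (lmin > j - 1L) next
        for (l in lmin:(j - 1L)) {
          if (!is.finite(V[k, l])) next
          e <- if (k == i + 1L && l == j - 1L)
            model$stack[pt[i, j], pt[k, l]]
          else interior_energy(model, u1 + (j - l - 1L))
          cand <- V[k, l] + e
          if (cand < best) best <- cand
        }
      }
      if (d >= 11L) {  # room for two 5-nt branches inside the closing pair
        m2 <- Inf
        for (k in (i + 5L):(j - 6L)) {
          cand <- WM[i + 1L, k] + WM[k + 1L, j - 1L]
          if (cand < m2) m2 <- cand
        }
        cand <- model$ml_a + model$ml_b + m2
        if (cand < best) best <- cand
      }
      V[i, j] <- best
    }
    w <- V[i, j] + model$ml_b
    if (WM[i + 1L, j] + model$ml_c < w) w <- WM[i + 1L, j] + model$ml_c
    if (WM[i, j - 1L] + model$ml_c < w) w <- WM[i, j - 1L] + model$ml_c
    if (d >= 9L) for (k in (i + 4L):(j - 5L)) {
      cand <- WM[i, k] + WM[k + 1L, j]
      if (cand < w) w <- cand
    }
    WM[i, j] <- w
  }
  W <- c(0, numeric(n))  # W[j+1] = best energy of prefix 1..j
  for (j in seq_len(n)) {
    best <- W[j]
    if (j >= 5L) for (i in 1:(j - 4L)) {
      if (!is.finite(V[i, j])) next
      cand <- W[i] + V[i, j]
      if (cand < best) best <- cand
    }
    W[j + 1L] <- best
  }
  # traceback
  pairs <- NULL
  tasks <- list(list(kind = "W", j = n))
  while (length(tasks)) {
    t <- tasks[[length(tasks)]]; tasks[[length(tasks)]] <- NULL
    if (t$kind == "W") {
      j <- t$j
      if (j < 5L) next
      if (W[j + 1L] >= W[j] - tol) { tasks <- c(tasks, list(list(kind = "W", j = j - 1L))); next }
      done <- FALSE
      for (i in 1:(j - 4L)) {
        if (is.finite(V[i, j]) && abs(W[i] + V[i, j] - W[j + 1L]) <= tol) {
          tasks <- c(tasks, list(list(kind = "W", j = i - 1L),
                                 list(kind = "V", i = i, j = j)))
          done <- TRUE; break
        }
      }
      if (!done) stop("traceback failure in exterior loop")
    } else if (t$kind == "V") {
      i <- t$i; j <- t$j
      pairs <- rbind(pairs, c(i, j))
      e <- V[i, j]
      if (abs(hairpin_energy(model, j - i - 1L) - e) <= tol) next
      found <- FALSE
      kmax <- min(j - 5L, i + 1L + mi)
      if (kmax >= i + 1L) for (k in (i + 1L):kmax) {
        u1 <- k - i - 1L
        lmin <- max(k + 4L, j - 1L - (mi - u1))
        if (lmin > j - 1L) next
        for (l in lmin:(j - 1L)) {
          if (!is.finite(V[k, l])) next
          el <- if (k == i + 1L && l == j - 1L)
            model$stack[pt[i, j], pt[k, l]]
          else interior_energy(model, u1 + (j - l - 1L))
          if (abs(V[k, l] + el - e) <= tol) {
            tasks <- c(tasks, list(list(kind = "V", i = k, j = l)))
            found <- TRUE; break
          }
        }
        if (found) break
      }
      if (found) next
      if (j - i >= 11L) for (k in (i + 5L):(j - 6L)) {
        if (abs(model$ml_a + model$ml_b + WM[i + 1L, k] + WM[k + 1L, j - 1L] - e) <= tol) {
          tasks <- c(tasks, list(list(kind = "WM", i = i + 1L, j = k),
                                 list(kind = "WM", i = k + 1L, j = j - 1L)))
          found <- TRUE; break
        }
      }
      if (!found) stop("traceback failure in V")
    } else {  # WM
      i <- t$i; j <- t$j
      e <- WM[i, j]
      if (!is.finite(e)) stop("traceback entered an infeasible WM cell")
      if (j - i >= 4L && abs(WM[i + 1L, j] + model$ml_c - e) <= tol) {
        tasks <- c(tasks, list(list(kind = "WM", i = i + 1L, j = j))); next
      }
      if (j - i >= 4L && abs(WM[i, j - 1L] + model$ml_c - e) <= tol) {
        tasks <- c(tasks, list(list(kind = "WM", i = i, j = j - 1L))); next
      }
      if (is.finite(V[i, j]) && abs(V[i, j] + model$ml_b - e) <= tol) {
        tasks <- c(tasks, list(list(kind = "V", i = i, j = j))); next
      }
      found <- FALSE
      if (j - i >= 9L) for (k in (i + 4L):(j - 5L)) {
        if (abs(WM[i, k] + WM[k + 1L, j] - e) <= tol) {
          tasks <- c(tasks, list(list(kind = "WM", i = i, j = k),
                                 list(kind = "WM", i = k + 1L, j = j)))
          found <- TRUE; break
        }
      }
      if (!found) stop("traceback failure in WM")
    }
  }
  list(structure = secondary_structure(pairs, n), energy = W[n + 1L])
}

partition_inside <- function(seq, model, constraints) {
  fp <- fold_prep(seq, model, constraints)
  n <- fp$n; pt <- fp$pt
  RT <- model$RT
  wb <- exp(-model$ml_b / RT); wc <- exp(-model$ml_c / RT)
  wa <- exp(-model$ml_a / RT)
  Qb <- matrix(0, n, n); QM <- matrix(0, n, n); QM1 <- matrix(0, n, n)
  mi <- model$max_interior
  if (n >= 5) for (d in 4:(n - 1)) for (i in seq_len(n - d)) {
    j <- i + d
    if (pt[i, j] > 0L) {
      q <- exp(-hairpin_energy(model, d - 1L) / RT)
      kmax <- min(j - 5L, i + 1L + mi)
      if (kmax >= i + 1L) for (k in (i + 1L):kmax) {
        u1 <- k - i - 1L
        lmin <- max(k + 4L, j - 1L - (mi - u1))
        if (lmin > j - 1L) next
        for (l in lmin:(j - 1L)) {
          if (Qb[k, l] == 0) next
          e <- if (k == i + 1L && l == j - 1L)
            model$stack[pt[i, j], pt[k, l]]
          else interior_energy(model, u1 + (j - l - 1L))
          q <- q + Qb[k, l] * exp(-e / RT)
        }
      }
      if (d >= 11L) {
        qm2 <- 0
        for (k in (i + 6L):(j - 5L))  # split: QM over [i+1,k-1], QM1 over [k,j-1]
          qm2 <- qm2 + QM[i + 1L, k - 1L] * QM1[k, j - 1L]
        q <- q + wa * wb * qm2
      }
      Qb[i, j] <- q
    }
    # QM1[i, j]: exactly one branch starting at i, trailing unpaired to j
    QM1[i, j] <- (if (d > 4L) QM1[i, j - 1L] * wc else 0) + Qb[i, j] * wb
    # QM[i, j]: >= 1 branch; last branch starts at k
    s <- (if (d > 4L) QM[i, j - 1L] * wc else 0)
    for (k in i:(j - 4L)) {
      if (Qb[k, j] == 0) next
      lead <- if (k >= i + 5L) QM[i, k - 1L] else 0
      s <- s + (wc^(k - i) + lead) * Qb[k, j] * wb
    }
    QM[i, j] <- s
  }
  # exterior prefix / suffix partition functions
  Q1 <- c(1, numeric(n))   # Q1[j+1] = Z of prefix 1..j
  for (j in seq_len(n)) {
    s <- Q1[j]
    if (j >= 5L) for (k in 1:(j - 4L)) if (Qb[k, j] > 0) s <- s + Q1[k] * Qb[k, j]
    Q1[j + 1L] <- s
  }
  Qr <- c(numeric(n), 1, 1)  # Qr[i] = Z of suffix i..n; Qr[n+1] = 1
  for (i in n:1) {
    s <- Qr[i + 1L]
    if (i <= n - 4L) for (l in (i + 4L):n) if (Qb[i, l] > 0) s <- s + Qb[i, l] * Qr[l + 1L]
    Qr[i] <- s
  }
  if (!is.finite(Q1[n + 1L]))
    warning("partition function overflow; sequence too long/stable for ",
            "double precision at this temperature")
  list(n = n, pt = pt, Qb = Qb, QM = QM, QM1 = QM1, Q1 = Q1, Qr = Qr,
       Z = Q1[n + 1L], wb = wb, wc = wc, wa = wa)
}

#' Partition function and base-pair probabilities
#'
#' McCaskill-style inside/outside recursions over the same decomposition
#' as [mfe_fold()]. Returns the full pair-probability matrix, the
#' partition function Z and the ensemble free energy.
#'
#' @inheritParams mfe_fold
#' @param max_length guard against accidental huge inputs (default 500;
#'   the O(n^4) outside pass is intended for sequences up to a few hundred
#'   nt).
#' @return list of class `pair_prob`: p (n x n, upper triangle), Z,
#'   ensemble_energy.
#' @export
partition <- function(seq, model = energy_model(), constraints = integer(0),
                      max_length = 500) {
  if (nchar(seq) > max_length)
    stop("sequence longer than max_length = ", max_length)
  ins <- partition_inside(seq, model, constraints)
  n <- ins$n
  P <- matrix(0, n, n)        # pair probabilities
  Pt <- matrix(0, n, n)       # p / Qb
  if (n >= 5) {
    RT <- model$RT; mi <- model$max_interior
    idx <- which(ins$Qb > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(-(idx[, 2] - idx[, 1])), , drop = FALSE]
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        acc <- ins$Q1[i] * ins$Qr[j + 1L] / ins$Z      # exterior
        # enclosed via stack/bulge/interior loop
        hmin <- max(1L, i - 1L - mi)
        if (i > 1L && j < n) for (h in hmin:(i - 1L)) {
          u1 <- i - h - 1L
          lmax <- min(n, j + 1L + (mi - u1))
          for (l in (j + 1L):lmax) {
            if (Pt[h, l] == 0) next
            e <- if (h == i - 1L && l == j + 1L)
              model$stack[ins$pt[h, l], ins$pt[i, j]]
            else interior_energy(model, u1 + (l - j - 1L))
            acc <- acc + Pt[h, l] * exp(-e / RT)
          }
        }
        # enclosed in a multiloop closed by (h, l)
        if (i > 1L && j < n) {
          hh <- 1:(i - 1L); ll <- (j + 1L):n
          QMl <- vapply(hh, function(h)
            if (i - 1L - h >= 5L) ins$QM[h + 1L, i - 1L] else 0, numeric(1))
          cL <- ins$wc^(i - 1L - hh)
          QMr <- vapply(ll, function(l)
            if (l - 1L - j >= 5L) ins$QM[j + 1L, l - 1L] else 0, numeric(1))
          cR <- ins$wc^(ll - 1L - j)
          Pm <- Pt[hh, ll, drop = FALSE]
          full <- as.numeric(t(QMl + cL) %*% Pm %*% (QMr + cR))
          noBranch <- as.numeric(t(cL) %*% Pm %*% cR)
          acc <- acc + ins$wa * ins$wb * ins$wb * (full - noBranch)
        }
        Pt[i, j] <- acc
        P[i, j] <- acc * ins$Qb[i, j]
      }
    }
  }
  structure(list(p = P, Z = ins$Z,
                 ensemble_energy = -model$RT * log(ins$Z), length = n),
            class = "pair_prob")
}

#' Partition function only (no pair probabilities)
#' @inheritParams mfe_fold
#' @return scalar Z.
#' @export
partition_Z <- function(seq, model = energy_model(),
                        constraints = integer(0)) {
  partition_inside(seq, model, constraints)$Z
}

#' Probability of an unpaired window (PU value)
#'
#' Equilibrium probability that every position of the window is unpaired:
#' the ratio of the partition function with the window forced unpaired to
#' the unconstrained partition function. PU values quantify the
#' single-strandedness of splicing-regulatory motifs.
#'
#' @param seq sequence.
#' @param window integer length-2 `(start, end)`, 1-based inclusive.
#' @param model [energy_model()].
#' @param constraints additional forced-unpaired positions applied to both
#'   numerator and denominator.
#' @return list of class `pu_result`: window, PU.
#' @export
pu_value <- function(seq, window, model = energy_model(),
                     constraints = integer(0)) {
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be (start, end) with start <= end")
  n <- nchar(seq)
  if (window[1] < 1 || window[2] > n) stop("window outside sequence")
  Z <- partition_Z(seq, model, constraints)
  Zc <- partition_Z(seq, model, union(constraints, window[1]:window[2]))
  structure(list(window = as.integer(window), PU = Zc / Z),
            class = "pu_result")
}

#' Per-window PU profile
#'
#' PU values for a sliding window along the sequence (width-1 windows give
#' a per-nucleotide unpaired probability).
#' @param seq sequence.
#' @param width window width.
#' @param model [energy_model()].
#' @return data.frame: start, end, PU.
#' @export
pu_profile <- function(seq, width = 1L, model = energy_model()) {
  n <- nchar(seq)
  Z <- partition_Z(seq, model)
  starts <- seq_len(n - width + 1L)
  pu <- vapply(starts, function(s)
    partition_Z(seq, model, s:(s + width - 1L)) / Z, numeric(1))
  data.frame(start = starts, end = starts + width - 1L, PU = pu)
}

#' Reactivity-constrained MFE fold
#'
#' Positions with reactivity above `threshold` (on the 2/8-normalized
#' scale) are forced unpaired as hard constraints, then the MFE structure
#' is computed. Positions with `NA` reactivity carry no constraint.
#'
#' @param seq sequence.
#' @param reactivity numeric vector aligned to `seq` (NA = no data).
#' @param threshold force-unpaired cutoff (default 0.7).
#' @param model [energy_model()].
#' @return list(structure, energy, constrained_positions).
#' @export
reactivity_constrained_fold <- function(seq, reactivity, threshold = 0.7,
                                        model = energy_model()) {
  if (length(reactivity) != nchar(seq))
    stop("reactivity profile not aligned to sequence")
  forced <- which(!is.na(reactivity) & reactivity > threshold)
  res <- mfe_fold(seq, model, constraints = forced)
  res$constrained_positions <- forced
  res
}
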