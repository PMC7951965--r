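DNA_BASES <- c("A", "C", "G", "T")

#' Encode a DNA/RNA string as base indices
#'
#' A=1, C=2, G=3, T=4; U is mapped to T (all internal handling is in the
#' DNA alphabet).
#' @param seq character string.
#' @return integer vector.
#' @keywords internal
seq_to_ints <- function(seq) {
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  v <- match(strsplit(s, "")[[1]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains non-ACGT(U) characters: ", seq)
  v
}

#' Train a first-order Markov model of a splice-site window
#'
#' Positional inhomogeneous chain: a base distribution at position 1 and a
#' 4x4 conditional table P(x_i | x_{i-1}) at every later position, each
#' smoothed with `pseudocount` added to every cell before normalization.
#'
#' @param seqs character vector of equal-length training windows (signal or
#'   decoy sites).
#' @param pseudocount per-cell smoothing count (default 0.5).
#' @param site_kind optional label ("donor"/"acceptor") carried in the model.
#' @return object of class `markov_model`.
#' @export
train_markov <- function(seqs, pseudocount = 0.5, site_kind = NA_character_) {
  if (!length(seqs)) stop("need at least one training sequence")
  k <- nchar(seqs[1])
  bad <- which(nchar(seqs) != k)
  if (length(bad))
    stop(sprintf("sequence %d ('%s') has length %d, expected %d",
                 bad[1], seqs[bad[1]], nchar(seqs[bad[1]]), k))
  raw <- vapply(seqs, seq_to_ints, integer(k))
  mat <- if (k == 1L) matrix(raw, ncol = 1L) else t(raw)
  p0 <- tabulate(mat[, 1], 4) + pseudocount
  if (sum(p0) <= 0) stop("position-1 counts are all zero with pseudocount 0")
  p0 <- p0 / sum(p0)
  cond <- vector("list", max(k - 1L, 0L))
  for (p in seq_len(k - 1L)) {
    tab <- matrix(pseudocount, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (i in seq_len(nrow(mat)))
      tab[mat[i, p], mat[i, p + 1L]] <- tab[mat[i, p], mat[i, p + 1L]] + 1
    rs <- rowSums(tab)
    tab <- tab / ifelse(rs > 0, rs, 1)  # unobserved contexts stay all-zero rows
    cond[[p]] <- tab
  }
  structure(list(site_kind = site_kind, k = k, p0 = p0, cond = cond,
                 pseudocount = pseudocount),
            class = "markov_model")
}

#' Sequence probability under a splice-site model
#'
#' @param model a `markov_model` or `maxent_model`.
#' @param seq k-mer to evaluate.
#' @return probability (may be 0 for unsmoothed models).
#' @export
seq_prob <- function(model, seq) UseMethod("seq_prob")

#' @export
seq_prob.markov_model <- function(model, seq) {
  v <- seq_to_ints(seq)
  if (length(v) != model$k)
    stop(sprintf("sequence length %d, model expects %d", length(v), model$k))
  p <- model$p0[v[1]]
  for (i in seq_len(model$k - 1L))
    p <- p * model$cond[[i]][v[i], v[i + 1L]]
  unname(p)
}

#' @export
seq_prob.maxent_model <- function(model, seq) {
  v <- seq_to_ints(seq)
  if (length(v) != model$k)
    stop(sprintf("sequence length %d, model expects %d", length(v), model$k))
  idx <- sum((v - 1L) * 4L^((model$k - 1L):0L)) + 1L
  unname(model$prob[idx])
}

#' Marginal probability of a window prefix
#'
#' Probability that the first `m` positions of the model's window equal the
#' given prefix, marginalizing over the remaining positions. Used to divide
#' out fragment overlaps in decomposed acceptor scoring.
#' @param model `markov_model` or `maxent_model`.
#' @param prefix character prefix (length <= model k).
#' @return probability.
#' @export
prefix_prob <- function(model, prefix) UseMethod("prefix_prob")

#' @export
prefix_prob.markov_model <- function(model, prefix) {
  v <- seq_to_ints(prefix)
  m <- length(v)
  if (m > model$k) stop("prefix longer than model window")
  p <- model$p0[v[1]]
  if (m > 1) for (i in seq_len(m - 1L))
    p <- p * model$cond[[i]][v[i], v[i + 1L]]
  unname(p)
}

#' @export
prefix_prob.maxent_model <- function(model, prefix) {
  v <- seq_to_ints(prefix)
  m <- length(v)
  if (m > model$k) stop("prefix longer than model window")
  # position 1 is the most significant digit, so a prefix is a contiguous
  # block of the enumerated k-mer domain
  i0 <- sum((v - 1L) * 4L^((m - 1L):0L))
  block <- 4L^(model$k - m)
  sum(model$prob[(i0 * block + 1L):((i0 + 1L) * block)])
}

#' Log2-odds intrinsic splice-site strength ("ME score" when the models are
#' maximum-entropy models)
#'
#' `value = log2(P_signal(seq) / P_decoy(seq))`, in bits. Works with any mix
#' of model classes sharing the window length.
#'
#' @param signal_model,decoy_model trained models of the same k.
#' @param seq k-mer to score.
#' @return object of class `site_score`: list(value, model_id).
#' @export
score_log2odds <- function(signal_model, decoy_model, seq) {
  if (signal_model$k != decoy_model$k)
    stop("signal and decoy models have different window lengths")
  ps <- seq_prob(signal_model, seq)
  pd <- seq_prob(decoy_model, seq)
  if (pd == 0)
    stop("decoy probability is zero for '", seq,
         "'; retrain the decoy model with a positive pseudocount")
  structure(list(value = log2(ps / pd),
                 model_id = paste(class(signal_model)[1], signal_model$k,
                                  sep = "_")),
            class = "site_score")
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("<site_score> %.4f bits (%s)\n", x$value, x$model_id))
  invisible(x)
}

#' Train a maximum-entropy splice-site model
#'
#' Fits the maximum-entropy distribution over the 4^k window domain subject
#' to marginal constraints (single positions and position pairs) matching
#' the training set, by generalized iterative scaling. Each constraint
#' group contributes exactly one active feature per sequence, so the GIS
#' feature total is constant and the update is
#' `w <- w * (empirical/model)^(1/C)` with `C` the number of groups.
#'
#' @param seqs equal-length training windows (length <= 9 so the domain is
#'   enumerable).
#' @param constraint_set list of integer vectors, each of length 1 (a
#'   positional marginal) or 2 (a position-pair marginal).
#' @param tol convergence tolerance on the max marginal deviation
#'   (default 1e-4).
#' @param max_iter iteration cap (default 5000); non-convergence sets
#'   `converged = FALSE` with a warning rather than failing.
#' @param site_kind optional label.
#' @return object of class `maxent_model` with the induced probability
#'   vector over the enumerated domain.
#' @export
train_maxent <- function(seqs, constraint_set, tol = 1e-4, max_iter = 5000,
                         site_kind = NA_character_) {
  if (!length(seqs)) stop("need at least one training sequence")
  k <- nchar(seqs[1])
  if (k > 9) stop("window length ", k, " exceeds the enumerable limit of 9")
  if (any(nchar(seqs) != k)) stop("training sequences have unequal lengths")
  groups <- lapply(constraint_set, as.integer)
  for (g in groups)
    if (!length(g) %in% 1:2 || any(g < 1 | g > k))
      stop("constraints must be single positions or position pairs within 1..k")
  N <- 4L^k
  base_at <- lapply(seq_len(k), function(p)
    ((seq_len(N) - 1L) %/% 4L^(k - p)) %% 4L + 1L)
  gval <- lapply(groups, function(g) {
    if (length(g) == 1L) base_at[[g]] else
      4L * (base_at[[g[1]]] - 1L) + base_at[[g[2]]]
  })
  raw <- vapply(seqs, seq_to_ints, integer(k))
  mat <- if (k == 1L) matrix(raw, ncol = 1L) else t(raw)
  nseq <- nrow(mat)
  emp <- lapply(groups, function(g) {
    v <- if (length(g) == 1L) mat[, g] else 4L * (mat[, g[1]] - 1L) + mat[, g[2]]
    tabulate(v, if (length(g) == 1L) 4L else 16L) / nseq
  })
  C <- length(groups)
  logw <- lapply(groups, function(g) numeric(if (length(g) == 1L) 4L else 16L))
  converged <- FALSE
  iter <- 0L
  if (C == 0L) {
    prob <- rep(1 / N, N)
    converged <- TRUE
  } else {
    repeat {
      iter <- iter + 1L
      lp <- numeric(N)
      for (j in seq_len(C)) lp <- lp + logw[[j]][gval[[j]]]
      lp <- lp - max(lp[is.finite(lp)])
      prob <- exp(lp)
      prob <- prob / sum(prob)
      dev <- 0
      modm <- vector("list", C)
      for (j in seq_len(C)) {
        m <- as.vector(rowsum(prob, gval[[j]],
                              reorder = TRUE))
        # rowsum drops absent levels; rebuild full-length marginal
        full <- numeric(length(emp[[j]]))
        full[sort(unique(gval[[j]]))] <- m
        modm[[j]] <- full
        dev <- max(dev, max(abs(full - emp[[j]])))
      }
      if (dev <= tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
      for (j in seq_len(C)) {
        upd <- (log(emp[[j]]) - log(modm[[j]])) / C
        upd[emp[[j]] == 0] <- -Inf
        upd[emp[[j]] > 0 & modm[[j]] == 0] <- 0   # unreachable under -Inf weights
        logw[[j]] <- logw[[j]] + upd
      }
    }
  }
  if (!converged)
    warning(sprintf("maxent training stopped at max_iter=%d (max deviation > %g)",
                    max_iter, tol))
  structure(list(site_kind = site_kind, k = k, constraint_set = groups,
                 log_weights = logw, prob = prob, tol = tol,
                 iterations = iter, converged = converged),
            class = "maxent_model")
}

#' Score a 23-mer acceptor by overlapping-fragment decomposition
#'
#' The full acceptor window is too large for an enumerable maximum-entropy
#' domain, so it is scored as a product of fragment probabilities divided
#' by the marginal probabilities of the declared overlaps (the chain-rule
#' correction), separately for signal and decoy, then log2-ratioed.
#' Overlap marginals are taken as prefix marginals under the *downstream*
#' fragment's model.
#'
#' @param fragments list of fragment specs: each
#'   `list(start =, end =, signal =, decoy =)` with 1-based inclusive
#'   coordinates inside the window; fragments sorted by start must tile the
#'   window with overlaps >= 0 and each span at most 9 nt.
#' @param seq the full window (e.g. a 23-mer acceptor).
#' @return `site_score`.
#' @export
score_acceptor_decomposed <- function(fragments, seq) {
  L <- nchar(seq)
  fr <- fragments[order(vapply(fragments, function(f) f$start, numeric(1)))]
  starts <- vapply(fr, function(f) as.integer(f$start), integer(1))
  ends <- vapply(fr, function(f) as.integer(f$end), integer(1))
  if (any(ends - starts + 1L > 9L))
    stop("fragment spans more than 9 positions; domain too large")
  if (starts[1] != 1L || ends[length(fr)] != L)
    stop("fragments must tile positions 1..", L)
  for (i in seq_along(fr)) {
    f <- fr[[i]]
    if (f$signal$k != ends[i] - starts[i] + 1L ||
        f$decoy$k != ends[i] - starts[i] + 1L)
      stop("fragment ", i, " model window length does not match its span")
  }
  if (length(fr) > 1L) {
    gaps <- starts[-1L] - ends[-length(fr)] - 1L
    if (any(gaps > 0L)) stop("tiling gap between fragments")
  }
  log2sig <- 0; log2dec <- 0
  for (i in seq_along(fr)) {
    sub <- substr(seq, starts[i], ends[i])
    log2sig <- log2sig + log2(seq_prob(fr[[i]]$signal, sub))
    log2dec <- log2dec + log2(seq_prob(fr[[i]]$decoy, sub))
    if (i > 1L) {
      ov <- ends[i - 1L] - starts[i] + 1L
      if (ov > 0L) {
        ovseq <- substr(seq, starts[i], ends[i - 1L])
        log2sig <- log2sig - log2(prefix_prob(fr[[i]]$signal, ovseq))
        log2dec <- log2dec - log2(prefix_prob(fr[[i]]$decoy, ovseq))
      }
    }
  }
  structure(list(value = log2sig - log2dec,
                 model_id = sprintf("decomposed_%d", L)),
            class = "site_score")
}

#' Serialize a splice-site model to versioned JSON
#' @param model `markov_model` or `maxent_model`.
#' @param path output path.
#' @export
write_splice_model <- function(model, path) {
  obj <- list(schema = "crypticsplice_model/1", type = class(model)[1])
  if (inherits(model, "markov_model")) {
    obj$payload <- list(site_kind = model$site_kind, k = model$k,
                        p0 = model$p0, cond = lapply(model$cond, as.vector),
                        pseudocount = model$pseudocount)
  } else if (inherits(model, "maxent_model")) {
    obj$payload <- list(site_kind = model$site_kind, k = model$k,
                        constraint_set = lapply(model$constraint_set, I),
                        log_weights = model$log_weights, tol = model$tol,
                        iterations = model$iterations,
                        converged = model$converged)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized splice-site model
#' @param path JSON file written by [write_splice_model()].
#' @export
read_splice_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "crypticsplice_model/1"))
    stop("unrecognized model schema: ", obj$schema)
  p <- obj$payload
  as_row_list <- function(x) {
    # jsonlite simplifies equal-length vector lists to a matrix
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
    else if (is.list(x)) x
    else list(x)
  }
  if (obj$type == "markov_model") {
    cond <- lapply(as_row_list(p$cond), function(v)
      matrix(v, 4, 4, dimnames = list(DNA_BASES, DNA_BASES)))
    structure(list(site_kind = p$site_kind, k = p$k, p0 = p$p0, cond = cond,
                   pseudocount = p$pseudocount), class = "markov_model")
  } else if (obj$type == "maxent_model") {
    groups <- lapply(as_row_list(p$constraint_set), as.integer)
    lw <- as_row_list(p$log_weights)
    k <- p$k; N <- 4L^k
    base_at <- lapply(seq_len(k), function(q)
      ((seq_len(N) - 1L) %/% 4L^(k - q)) %% 4L + 1L)
    lp <- numeric(N)
    for (j in seq_along(groups)) {
      g <- groups[[j]]
      val <- if (length(g) == 1L) base_at[[g]] else
        4L * (base_at[[g[1]]] - 1L) + base_at[[g[2]]]
      lp <- lp + lw[[j]][val]
    }
    lp <- lp - max(lp[is.finite(lp)])
    prob <- exp(lp); prob <- prob / sum(prob)
    structure(list(site_kind = p$site_kind, k = k, constraint_set = groups,
                   log_weights = lw, prob = prob, tol = p$tol,
                   iterations = p$iterations, converged = p$converged),
              class = "maxent_model")
  } else stop("unsupported model type: ", obj$type)
}

#' Import an externally published k-mer score table
#'
#' Accepts a two-column TSV (kmer, score in bits) so canonical published
#' splice-site parameterizations can be dropped in without retraining.
#' @param path TSV path.
#' @return named numeric vector of class `score_table`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("score table needs (kmer, score) columns")
  v <- as.numeric(df[[2]])
  names(v) <- toupper(df[[1]])
  class(v) <- "score_table"
  v
}

#' Look up a k-mer in an imported score table
#' @param table `score_table`.
#' @param seq k-mer.
#' @return `site_score`.
#' @export
score_table_lookup <- function(table, seq) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  if (!seq %in% names(table)) stop("k-mer not present in score table: ", seq)
  structure(list(value = unname(table[[seq]]), model_id = "imported_table"),
            class = "site_score")
}
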