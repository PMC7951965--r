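#' Construct a probing lane profile
#'
#' One gel lane: per-position reverse-transcription stop intensities plus
#' the full-length (read-through) band, for one reagent and replicate.
#'
#' @param intensities non-negative numeric vector (5'->3' positions of the
#'   probed region).
#' @param full_length intensity of the fully extended product (> 0).
#' @param reagent one of "DMS", "NAI", "RNaseA", "none".
#' @param probe_id,replicate labels.
#' @return object of class `lane_profile`.
#' @export
lane_profile <- function(intensities, full_length,
                         reagent = c("DMS", "NAI", "RNaseA", "none"),
                         probe_id = "probe", replicate = 1L) {
  reagent <- match.arg(reagent)
  if (any(intensities < 0)) stop("band intensities must be >= 0")
  if (!is.finite(full_length) || full_length <= 0)
    stop("full-length intensity must be > 0")
  structure(list(probe_id = probe_id, reagent = reagent,
                 intensities = as.numeric(intensities),
                 full_length = as.numeric(full_length),
                 replicate = as.integer(replicate)),
            class = "lane_profile")
}

#' Normalize a lane to its full-length product
#' @param lane `lane_profile`.
#' @return numeric vector `intensities / full_length`.
#' @export
normalize_to_full_length <- function(lane) {
  if (lane$full_length <= 0) stop("full-length intensity must be > 0")
  lane$intensities / lane$full_length
}

#' Subtract the no-reagent background
#' @param plus_norm,minus_norm equal-length normalized vectors (+reagent
#'   and control lanes).
#' @return raw reactivity (may be negative before clipping).
#' @export
subtract_background <- function(plus_norm, minus_norm) {
  if (length(plus_norm) != length(minus_norm))
    stop("plus and minus lanes have different lengths")
  plus_norm - minus_norm
}

#' 2/8 reactivity normalization
#'
#' Excludes the top ceil(2% n) values as outliers and divides the profile
#' by the mean of the next ceil(8% n) values.
#' @param values numeric vector, length >= 10.
#' @return rescaled values.
#' @export
normalize_2_8 <- function(values) {
  n <- length(values)
  if (n < 10) stop("2/8 normalization needs at least 10 values")
  s <- sort(values, decreasing = TRUE)
  n_out <- ceiling(0.02 * n)
  n_top <- ceiling(0.08 * n)
  divisor <- mean(s[(n_out + 1):(n_out + n_top)])
  if (!is.finite(divisor) || divisor <= 0)
    stop("degenerate profile: 2/8 divisor is not positive")
  values / divisor
}

#' Clip negative reactivities at a floor
#' @param values numeric vector.
#' @param floor clip floor (default -2, the plotting convention for
#'   background-subtracted profiles).
#' @export
clip_floor <- function(values, floor = -2) pmax(values, floor)

#' Full reactivity pipeline for one probe
#'
#' normalize-to-full-length per lane, subtract the control, optionally
#' rescale by the 2/8 rule, clip at the floor. The chain is invariant to
#' rescaling both lanes' raw intensities and full-length bands by any
#' common positive factor.
#'
#' @param plus_lane,minus_lane `lane_profile`s (+reagent / control).
#' @param rule "2_8" or "fl" (full-length only).
#' @param floor clip floor.
#' @return list of class `reactivity_profile`: probe_id, reagent,
#'   reactivity, scheme.
#' @export
reactivity_pipeline <- function(plus_lane, minus_lane, rule = c("2_8", "fl"),
                                floor = -2) {
  rule <- match.arg(rule)
  raw <- subtract_background(normalize_to_full_length(plus_lane),
                             normalize_to_full_length(minus_lane))
  if (rule == "2_8") raw <- normalize_2_8(raw)
  structure(list(probe_id = plus_lane$probe_id, reagent = plus_lane$reagent,
                 reactivity = clip_floor(raw, floor), scheme = rule),
            class = "reactivity_profile")
}

#' RNase cleavage profile
#'
#' Full-length-normalized, control-subtracted cleavage intensities for an
#' enzymatic digestion lane.
#' @param digest_lane,control_lane `lane_profile`s.
#' @return numeric cleavage vector.
#' @export
rnase_profile <- function(digest_lane, control_lane) {
  subtract_background(normalize_to_full_length(digest_lane),
                      normalize_to_full_length(control_lane))
}

#' Flag large cleavage fold changes between mutant and WT
#'
#' Positions where `mut/wt > threshold` or `< 1/threshold`; a pseudo-floor
#' `eps` is added to both terms so zero-signal positions behave sanely.
#' @param mut_profile,wt_profile cleavage vectors.
#' @param threshold fold-change cutoff (default 3).
#' @param eps denominator pseudo-floor (default 1e-6).
#' @return data.frame: position, wt, mut, fold, flagged, direction.
#' @export
fold_change <- function(mut_profile, wt_profile, threshold = 3, eps = 1e-6) {
  if (length(mut_profile) != length(wt_profile))
    stop("profiles have different lengths")
  m <- pmax(mut_profile, 0) + eps
  w <- pmax(wt_profile, 0) + eps
  fold <- m / w
  data.frame(position = seq_along(fold), wt = wt_profile, mut = mut_profile,
             fold = fold,
             flagged = fold > threshold | fold < 1 / threshold,
             direction = ifelse(fold >= 1, "up", "down"))
}

#' Per-position differential reactivity test
#'
#' One-way ANOVA across groups at every position, followed by Tukey's HSD
#' for the mutant-vs-WT contrast when more than two groups are supplied.
#' With exactly two groups Tukey's adjustment is the identity and the
#' ANOVA F-test p value is reported directly (equivalent to the
#' equal-variance t test). Positions with zero within-group variance are
#' reported with p = 0 and a `degenerate` flag when the group means
#' differ (and p = 1 when they do not).
#'
#' @param wt_profiles,mut_profiles matrices, one row per replicate, one
#'   column per position (>= 2 replicates each).
#' @param alpha significance level (default 0.05).
#' @param extra_groups optional named list of further replicate matrices
#'   (e.g. a second probing condition); triggers the Tukey post-hoc path.
#' @return data.frame of class `diff_sites`: position, mean_wt, mean_mut,
#'   f_statistic, p_value, direction ("up"/"down" = mutant vs WT),
#'   significant, degenerate.
#' @export
differential_test <- function(wt_profiles, mut_profiles, alpha = 0.05,
                              extra_groups = list()) {
  wt_profiles <- as.matrix(wt_profiles)
  mut_profiles <- as.matrix(mut_profiles)
  if (ncol(wt_profiles) != ncol(mut_profiles))
    stop("profiles have different lengths")
  if (nrow(wt_profiles) < 2 || nrow(mut_profiles) < 2)
    stop("need >= 2 replicates per group")
  mats <- c(list(wt = wt_profiles, mut = mut_profiles),
            lapply(extra_groups, as.matrix))
  npos <- ncol(wt_profiles)
  out <- data.frame(position = seq_len(npos), mean_wt = NA_real_,
                    mean_mut = NA_real_, f_statistic = NA_real_,
                    p_value = NA_real_, direction = NA_character_,
                    significant = FALSE, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  grp <- factor(rep(names(mats), vapply(mats, nrow, integer(1))),
                levels = names(mats))
  two_groups <- length(mats) == 2L
  for (j in seq_len(npos)) {
    y <- unlist(lapply(mats, function(m) m[, j]), use.names = FALSE)
    mw <- mean(wt_profiles[, j]); mm <- mean(mut_profiles[, j])
    out$mean_wt[j] <- mw; out$mean_mut[j] <- mm
    out$direction[j] <- if (mm >= mw) "up" else "down"
    within_var <- sum(vapply(mats, function(m) stats::var(m[, j]), numeric(1)))
    if (within_var == 0) {
      out$degenerate[j] <- TRUE
      out$p_value[j] <- if (mw == mm) 1 else 0
    } else {
      fit <- stats::aov(y ~ grp)
      tab <- summary(fit)[[1]]
      out$f_statistic[j] <- tab[1, "F value"]
      out$p_value[j] <- if (two_groups) tab[1, "Pr(>F)"]
      else stats::TukeyHSD(fit)$grp["mut-wt", "p adj"]
    }
    out$significant[j] <- out$p_value[j] <= alpha
  }
  class(out) <- c("diff_sites", "data.frame")
  out
}

#' Read/write lane profiles as TSV
#'
#' Two-column TSV (position, intensity) preceded by `# key value` metadata
#' lines for probe_id, reagent, replicate and full_length.
#' @param path file path.
#' @export
read_lane_profile <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "\\s+")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]))
  lane_profile(df$intensity[order(df$position)],
               full_length = as.numeric(meta$full_length),
               reagent = meta$reagent, probe_id = meta$probe_id,
               replicate = as.integer(meta$replicate))
}

#' @rdname read_lane_profile
#' @param lane `lane_profile`.
#' @export
write_lane_profile <- function(lane, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# probe_id %s", lane$probe_id),
               sprintf("# reagent %s", lane$reagent),
               sprintf("# replicate %d", lane$replicate),
               sprintf("# full_length %.10g", lane$full_length),
               "position\tintensity"), con)
  utils::write.table(data.frame(position = seq_along(lane$intensities),
                                intensity = lane$intensities),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
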