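#' Run configuration
#'
#' Thresholds and seeds for the staged analyses; round-trips through YAML.
#'
#' @param exon_thr,intron_thr small exon/intron thresholds (nt).
#' @param min_intron minimum spliceable intron (nt).
#' @param reactivity_threshold force-unpaired cutoff for constrained
#'   folding.
#' @param alpha significance level for differential reactivity.
#' @param gap_tol consensus resumption tolerance for cluster detection.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(exon_thr = 100, intron_thr = 200, min_intron = 70,
                       reactivity_threshold = 0.7, alpha = 0.05,
                       gap_tol = 30, seed = 1, out_dir = ".") {
  cfg <- list(exon_thr = exon_thr, intron_thr = intron_thr,
              min_intron = min_intron,
              reactivity_threshold = reactivity_threshold, alpha = alpha,
              gap_tol = gap_tol, seed = seed, out_dir = out_dir)
  for (nm in c("exon_thr", "intron_thr", "min_intron",
               "reactivity_threshold", "alpha", "gap_tol"))
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_provenance <- function(config, path) {
  yaml::write_yaml(list(
    package = "crypticsplice",
    version = as.character(utils::packageVersion("crypticsplice")),
    seed = config$seed,
    config_digest = paste(names(unclass(config)),
                          vapply(unclass(config), function(x)
                            paste(format(x), collapse = ","), character(1)),
                          sep = "=", collapse = ";"),
    config = unclass(config)), path)
  invisible(path)
}

#' Database-level summary of aberrant splice-site records
#'
#' Counts cryptic vs de novo sites per site kind, exon/intron location,
#' multiplicity fractions and aberrant-vs-authentic strength comparisons
#' (pooled-variance t test per site kind), failing fast if any record
#' still carries an unset class.
#'
#' @param records data.frame with at least `site_kind`,
#'   `aberrant_class`, `location`, `multiplicity_group` and (optionally)
#'   `auth_score`/`cryp_score` columns.
#' @return list of class `aberrant_summary`.
#' @export
summarize_aberrant_records <- function(records) {
  if (!nrow(records))
    return(structure(list(n = 0L, by_kind = NULL, multiplicity = NULL,
                          strength = NULL), class = "aberrant_summary"))
  if ("aberrant_class" %in% names(records) &&
      any(records$aberrant_class == "unset"))
    stop("records carry unset aberrant_class; classify before summarizing")
  by_kind <- as.data.frame(table(site_kind = records$site_kind,
                                 class = records$aberrant_class))
  by_loc <- if ("location" %in% names(records))
    as.data.frame(table(site_kind = records$site_kind,
                        location = records$location)) else NULL
  mult <- lapply(split(records, records$site_kind), fraction_multiple)
  strength <- NULL
  if (all(c("auth_score", "cryp_score") %in% names(records))) {
    strength <- lapply(split(records, records$site_kind), function(d) {
      res <- t_unpaired(d$cryp_score, d$auth_score)
      c(n = nrow(d), mean_aberrant = mean(d$cryp_score),
        mean_authentic = mean(d$auth_score), t = res$t, p = res$p_value,
        frac_stronger = mean(d$cryp_score > d$auth_score))
    })
  }
  structure(list(n = nrow(records), by_kind = by_kind, by_location = by_loc,
                 multiplicity = mult, strength = strength),
            class = "aberrant_summary")
}

#' Exon/intron size-constraint analysis of a pair table
#'
#' Quadrant summary at the configured thresholds plus medians of the score
#' excess per site kind and of adjacent exon sizes for intron-located
#' sites. Output row order is fixed (acceptor/donor x intron/exon).
#'
#' @param pairs `strong_weak_pairs` table.
#' @param config `run_config`.
#' @return list of class `size_constraints`: quadrants, median_delta (per
#'   site kind), median_adjacent_exon (per site kind, intron-located
#'   pairs), n_pairs, short_residuals (rows with residual intron below
#'   `min_intron`).
#' @export
analyze_size_constraints <- function(pairs, config = run_config()) {
  quads <- quadrant_summary(pairs, config$exon_thr, config$intron_thr)
  med_delta <- vapply(split(pairs, pairs$site_kind),
                      function(d) median_value(d$delta), numeric(1))
  intronic <- pairs[pairs$location == "intron", , drop = FALSE]
  med_exon <- vapply(split(intronic, intronic$site_kind),
                     function(d) median_value(d$flank_size), numeric(1))
  short_res <- pairs[!is.na(pairs$residual_intron) &
                       pairs$residual_intron < config$min_intron, ,
                     drop = FALSE]
  structure(list(quadrants = quads, median_delta = med_delta,
                 median_adjacent_exon = med_exon, n_pairs = nrow(pairs),
                 short_residuals = short_res),
            class = "size_constraints")
}

#' End-to-end synthetic probing workflow
#'
#' Simulates WT and mutant probes whose structures differ at planted
#' positions, runs the lane-normalization pipeline, the differential
#' reactivity test, reactivity-constrained folding, PU values for a window
#' of interest, and a stem-presence report of the WT reference stem in
#' each structure. Writes TSV outputs plus a provenance block when
#' `config$out_dir` exists.
#'
#' @param wt_seq,mut_seq probe sequences (same length).
#' @param window window of interest for PU values, 1-based inclusive
#'   `(start, end)` (e.g. the decoy 5'ss footprint).
#' @param config `run_config`.
#' @param write_outputs write TSVs + provenance under `config$out_dir`.
#' @return list of class `probing_run`.
#' @export
run_probing_workflow <- function(wt_seq, mut_seq, window,
                                 config = run_config(),
                                 write_outputs = FALSE) {
  if (nchar(wt_seq) != nchar(mut_seq))
    stop("WT and mutant probes must have equal length")
  model <- energy_model()
  wt_mfe <- mfe_fold(wt_seq, model)
  mut_mfe <- mfe_fold(mut_seq, model)
  sim_wt <- gen_reactivity(wt_mfe$structure, wt_seq, reagent = "NAI",
                           seed = config$seed)
  sim_mut <- gen_reactivity(mut_mfe$structure, mut_seq, reagent = "NAI",
                            seed = config$seed + 1L)
  react <- function(sim) {
    profs <- lapply(seq_along(sim$plus), function(r)
      reactivity_pipeline(sim$plus[[r]], sim$minus[[r]], rule = "2_8"))
    do.call(rbind, lapply(profs, function(p) p$reactivity))
  }
  wt_mat <- react(sim_wt); mut_mat <- react(sim_mut)
  diff <- differential_test(wt_mat, mut_mat, alpha = config$alpha)
  wt_fold <- reactivity_constrained_fold(wt_seq, colMeans(wt_mat),
                                         config$reactivity_threshold, model)
  mut_fold <- reactivity_constrained_fold(mut_seq, colMeans(mut_mat),
                                          config$reactivity_threshold, model)
  pu <- list(wt = pu_value(wt_seq, window, model),
             mut = pu_value(mut_seq, window, model))
  ref_stem <- wt_mfe$structure$pairs
  stems <- list(
    wt = if (nrow(ref_stem)) stem_presence(ref_stem, wt_fold$structure) else NA,
    mut = if (nrow(ref_stem)) stem_presence(ref_stem, mut_fold$structure) else NA)
  res <- structure(list(wt_reactivity = wt_mat, mut_reactivity = mut_mat,
                        diff = diff, wt_structure = wt_fold$structure,
                        mut_structure = mut_fold$structure, pu = pu,
                        stem_presence = stems,
                        distance = base_pair_distance(wt_fold$structure,
                                                      mut_fold$structure)),
                   class = "probing_run")
  if (write_outputs) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(position = seq_len(ncol(wt_mat)),
                                  wt = colMeans(wt_mat),
                                  mut = colMeans(mut_mat)),
                       file.path(config$out_dir, "reactivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff, file.path(config$out_dir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(wt_fold$structure$db, mut_fold$structure$db),
               file.path(config$out_dir, "structures.db"))
    write_provenance(config, file.path(config$out_dir, "provenance.yaml"))
  }
  res
}
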