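#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString
#'   reverseComplement
#' @importFrom utils read.delim write.table
NULL

RECORD_COLUMNS <- c("id", "gene", "site_kind", "authentic_boundary",
                    "aberrant_boundary", "mut_pos", "ref_base", "alt_base",
                    "hgvs", "aberrant_class", "location", "phenotype",
                    "multiplicity_group")

#' Construct a gene model
#'
#' A gene model ties a gene symbol to a contig, a strand and an ordered set
#' of exons. Exon coordinates are 0-based half-open *on the gene's sense
#' strand*: position 0 is the first base of the gene sequence as read 5'->3'
#' on the coding strand. For minus-strand genes the gene sequence is the
#' reverse complement of the contig, so exon coordinates still increase
#' 5'->3' along the mRNA.
#'
#' @param gene gene symbol.
#' @param chrom contig name (must match a FASTA record name).
#' @param strand "+" or "-" (orientation of the gene on the contig).
#' @param exons data.frame with integer columns `start`, `end`
#'   (0-based half-open, sense-strand coordinates), sorted, non-overlapping.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, exons) {
  stopifnot(is.character(gene), length(gene) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons)))
    stop("exons needs 'start' and 'end' columns")
  if (nrow(exons) < 1L) stop("gene model needs at least one exon")
  if (any(exons$start >= exons$end) || any(exons$start < 0))
    stop("exon intervals must satisfy 0 <= start < end")
  o <- order(exons$start)
  exons <- exons[o, c("start", "end"), drop = FALSE]
  if (nrow(exons) > 1L) {
    intron_len <- exons$start[-1L] - exons$end[-nrow(exons)]
    if (any(intron_len < 1L))
      stop("exons overlap or abut; every implied intron must be >= 1 nt")
  }
  rownames(exons) <- NULL
  structure(list(gene = gene, chrom = chrom, strand = strand, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s), %d exon(s), span %d-%d\n",
              x$gene, x$chrom, x$strand, nrow(x$exons),
              min(x$exons$start), max(x$exons$end)))
  invisible(x)
}

#' Intron intervals implied by a gene model
#'
#' @param model a [gene_model()].
#' @return data.frame with 0-based half-open `start`, `end` columns
#'   (sense-strand coordinates); zero rows for single-exon genes.
#' @export
gene_introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
}

#' Sense-strand sequence of a gene
#'
#' Returns the gene's sequence read 5'->3' on its coding strand: the contig
#' sequence for plus-strand genes, its reverse complement for minus-strand
#' genes. All record coordinates in this package live on this sequence.
#'
#' @param genome named `DNAStringSet` (or named character vector).
#' @param model a [gene_model()].
#' @return character string, uppercase DNA.
#' @export
gene_sense_sequence <- function(genome, model) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!model$chrom %in% names(genome))
    stop(sprintf("contig '%s' not found in genome", model$chrom))
  s <- genome[[model$chrom]]
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

new_splice_records <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("splice_records", "data.frame")
  df
}

#' Build a table of aberrant splice-site records
#'
#' One row per aberrant-site event: the underlying mutation, the authentic
#' splice-site boundary it perturbs, and the aberrant boundary it activates.
#' Boundaries are 0-based sense-strand positions of the first *intronic*
#' base for donors and the first *exonic* base for acceptors. `mut_pos` is
#' the 0-based position of the substituted base. On disk (TSV/JSON) all
#' positions are 1-based inclusive, the convention of HGVS-style reports.
#'
#' @param id,gene,site_kind,authentic_boundary,aberrant_boundary vectors.
#' @param mut_pos,ref_base,alt_base mutation triple.
#' @param hgvs,phenotype free-text labels (optional).
#' @param aberrant_class "cryptic", "de_novo" or "unset".
#' @param location "exon", "intron" or "unset".
#' @param multiplicity_group identifier shared by records arising from one
#'   mutation; defaults to gene + mutation.
#' @return data.frame of class `splice_records`.
#' @export
splice_records <- function(id, gene, site_kind, authentic_boundary,
                           aberrant_boundary, mut_pos, ref_base, alt_base,
                           hgvs = NA_character_,
                           aberrant_class = "unset", location = "unset",
                           phenotype = NA_character_,
                           multiplicity_group = NULL) {
  n <- length(id)
  if (is.null(multiplicity_group))
    multiplicity_group <- paste(gene, mut_pos, ref_base, alt_base, sep = ":")
  df <- data.frame(id = as.character(id), gene = as.character(gene),
                   site_kind = as.character(site_kind),
                   authentic_boundary = as.integer(authentic_boundary),
                   aberrant_boundary = as.integer(aberrant_boundary),
                   mut_pos = as.integer(mut_pos),
                   ref_base = toupper(as.character(ref_base)),
                   alt_base = toupper(as.character(alt_base)),
                   hgvs = rep_len(as.character(hgvs), n),
                   aberrant_class = rep_len(as.character(aberrant_class), n),
                   location = rep_len(as.character(location), n),
                   phenotype = rep_len(as.character(phenotype), n),
                   multiplicity_group = rep_len(as.character(multiplicity_group), n),
                   stringsAsFactors = FALSE)
  problems <- validate_record_fields(df)
  if (length(problems))
    stop("invalid splice-site record(s):\n  ", paste(problems, collapse = "\n  "))
  new_splice_records(df)
}

validate_record_fields <- function(df) {
  problems <- character(0)
  bad <- function(i, msg) sprintf("row %d (%s): %s", i, df$id[i], msg)
  for (i in seq_len(nrow(df))) {
    if (!df$site_kind[i] %in% c("donor", "acceptor"))
      problems <- c(problems, bad(i, "site_kind must be donor/acceptor"))
    if (!df$aberrant_class[i] %in% c("cryptic", "de_novo", "unset"))
      problems <- c(problems, bad(i, "bad aberrant_class"))
    if (!df$location[i] %in% c("exon", "intron", "unset"))
      problems <- c(problems, bad(i, "bad location"))
    if (is.na(df$ref_base[i]) || is.na(df$alt_base[i]) ||
        identical(df$ref_base[i], df$alt_base[i]))
      problems <- c(problems, bad(i, "ref_base must differ from alt_base"))
    if (!is.na(df$authentic_boundary[i]) && !is.na(df$aberrant_boundary[i]) &&
        df$authentic_boundary[i] == df$aberrant_boundary[i])
      problems <- c(problems, bad(i, "aberrant boundary equals authentic boundary"))
  }
  problems
}

#' Read aberrant splice-site records
#'
#' Reads a TSV (header = documented column schema) or JSON-lines stream of
#' records. File positions are 1-based inclusive and are converted to the
#' package's internal 0-based convention. Malformed rows raise an error
#' naming the offending line; they are never silently dropped.
#'
#' @param path file path.
#' @param dialect "tsv" or "json".
#' @return `splice_records` data.frame.
#' @export
read_splice_records <- function(path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character")
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(RECORD_COLUMNS)),
                                   RECORD_COLUMNS))
    } else {
      rows <- lapply(lines, function(l) {
        x <- jsonlite::fromJSON(l)
        x[vapply(x, is.null, logical(1))] <- NA
        as.data.frame(x, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
    }
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing_cols))
    stop("record table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, RECORD_COLUMNS]
  for (col in c("authentic_boundary", "aberrant_boundary", "mut_pos")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop(sprintf("unparseable coordinate in column '%s', data line(s) %s",
                   col, paste(bad, collapse = ", ")))
    # file positions are 1-based inclusive
    df[[col]] <- as.integer(v) - 1L
  }
  df$aberrant_class[is.na(df$aberrant_class) | df$aberrant_class == ""] <- "unset"
  df$location[is.na(df$location) | df$location == ""] <- "unset"
  for (col in c("hgvs", "phenotype"))
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  problems <- validate_record_fields(df)
  if (length(problems))
    stop("invalid record row(s):\n  ", paste(problems, collapse = "\n  "))
  new_splice_records(df)
}

#' Write aberrant splice-site records
#'
#' Inverse of [read_splice_records()]; positions are written 1-based
#' inclusive. `read_splice_records(write_splice_records(x))` is the
#' identity on valid records.
#'
#' @param records `splice_records`.
#' @param path output file.
#' @param dialect "tsv" or "json" (JSON lines).
#' @export
write_splice_records <- function(records, path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(records)
  for (col in c("authentic_boundary", "aberrant_boundary", "mut_pos"))
    df[[col]] <- df[[col]] + 1L
  if (dialect == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
  }
  invisible(path)
}

#' Validate records against a reference genome
#'
#' For each record checks (a) that the gene's sense-strand base at the
#' mutation position equals `ref_base` and (b) that the aberrant boundary
#' carries a legal splice-site dinucleotide -- GT or GC immediately after an
#' aberrant donor boundary, AG immediately before an aberrant acceptor
#' boundary -- evaluated on the *post-mutation* sequence, since the mutation
#' may be what creates the dinucleotide. GC donors pass (GC 5'ss are rare
#' but legitimate); any other donor dinucleotide fails.
#'
#' @param records `splice_records`.
#' @param genome named `DNAStringSet` or character vector of contigs.
#' @param models named list of [gene_model()]s keyed by gene symbol.
#' @return data.frame: id, ref_ok, dinucleotide, dinuc_ok, pass, reason.
#' @export
validate_against_reference <- function(records, genome, models) {
  out <- data.frame(id = records$id, ref_ok = NA, dinucleotide = NA_character_,
                    dinuc_ok = NA, pass = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    gm <- models[[r$gene]]
    if (is.null(gm)) { out$reason[i] <- "no gene model"; next }
    seq <- gene_sense_sequence(genome, gm)
    n <- nchar(seq)
    if (r$mut_pos < 0 || r$mut_pos >= n) { out$reason[i] <- "out of range"; next }
    ref_at <- substr(seq, r$mut_pos + 1L, r$mut_pos + 1L)
    out$ref_ok[i] <- identical(ref_at, r$ref_base)
    mutated <- seq
    substr(mutated, r$mut_pos + 1L, r$mut_pos + 1L) <- r$alt_base
    b <- r$aberrant_boundary
    if (r$site_kind == "donor") {
      if (b < 0 || b + 1L >= n) { out$reason[i] <- "out of range"; next }
      dinuc <- substr(mutated, b + 1L, b + 2L)
      ok <- dinuc %in% c("GT", "GC")
    } else {
      if (b - 2L < 0 || b > n) { out$reason[i] <- "out of range"; next }
      dinuc <- substr(mutated, b - 1L, b)
      ok <- dinuc == "AG"
    }
    out$dinucleotide[i] <- dinuc
    out$dinuc_ok[i] <- ok
    out$pass[i] <- isTRUE(out$ref_ok[i]) && ok
    out$reason[i] <- if (out$pass[i]) "ok" else if (!isTRUE(out$ref_ok[i]))
      "reference mismatch" else sprintf("illegal dinucleotide %s", dinuc)
  }
  out
}

#' Extract the scoring window around a splice-site boundary
#'
#' Donors use the 9-nt footprint spanning exon positions -3..-1 and intron
#' +1..+6; acceptors the 23-nt footprint spanning intron -20..-1 and exon
#' +1..+3. `boundary` is the 0-based sense-strand position of the first
#' intronic base (donor) or the first exonic base (acceptor). Minus-strand
#' genes are handled upstream: all coordinates already live on the sense
#' sequence, so the same arithmetic applies.
#'
#' @param genome named `DNAStringSet`/character contigs.
#' @param model [gene_model()].
#' @param boundary 0-based sense-strand junction position.
#' @param site_kind "donor" or "acceptor".
#' @return uppercase DNA string (9-mer or 23-mer).
#' @export
extract_site_window <- function(genome, model, boundary,
                                site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  seq <- gene_sense_sequence(genome, model)
  window_from_sequence(seq, boundary, site_kind)
}

#' @rdname extract_site_window
#' @param seq sense-strand gene sequence (character).
#' @export
window_from_sequence <- function(seq, boundary,
                                 site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  n <- nchar(seq)
  if (site_kind == "donor") { from <- boundary - 3L; to <- boundary + 6L }
  else { from <- boundary - 20L; to <- boundary + 3L }
  if (from < 0 || to > n)
    stop(sprintf("%s window [%d,%d) overruns the sequence (length %d)",
                 site_kind, from, to, n))
  toupper(substr(seq, from + 1L, to))
}
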