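#' Pipeline configuration
#'
#' Collects every tunable threshold of the annotation-confidence workflow in
#' one validated object. Defaults follow standard practice for contig-level
#' viral metagenome annotation: BLAST hits are kept at e-value <= 1e-5 and at
#' most 25 hits per query, contigs shorter than 500 nt are discarded, and the
#' goodness-of-assignment boundary separating high-confidence from novel
#' assignments sits at 60% query coverage (strict: a taxon is high-confidence
#' only when its mean query coverage exceeds the boundary). The circovirus
#' species-demarcation threshold is 75% genome-wide nucleotide identity.
#'
#' @param evalue_max maximum e-value for a hit to be retained (> 0).
#' @param top_hits number of hits kept per query, ranked by bitscore (>= 1).
#' @param min_contig_len minimum query (contig) length in nucleotides.
#' @param coverage_boundary percent query coverage above which a taxon
#'   cluster is called high-confidence (strict ">").
#' @param demarcation_identity percent genome-wide identity below which two
#'   genomes are distinct species (strict "<").
#' @param min_terminal_repeat minimum exact terminal direct repeat length, in
#'   nucleotides, accepted as evidence of a circular genome.
#' @param lca_score_window fraction of the top bitscore: hits scoring at
#'   least (1 - window) * top bitscore enter the lowest-common-ancestor set.
#' @param related_rank taxonomic rank at or below which a best hit counts as
#'   "related" to the truth in the calibration experiment.
#' @param match,mismatch nucleotide match reward and mismatch penalty.
#' @param gap_open,gap_extend affine gap costs (positive numbers; a gap of
#'   length L costs gap_open + L * gap_extend).
#' @param rng_seed integer seed recorded in run manifests; NULL leaves the
#'   RNG untouched.
#' @return an object of class \code{pipeline_config} (a validated list).
#' @export
pipeline_config <- function(evalue_max = 1e-5,
                            top_hits = 25L,
                            min_contig_len = 500L,
                            coverage_boundary = 60,
                            demarcation_identity = 75,
                            min_terminal_repeat = 20L,
                            lca_score_window = 0.10,
                            related_rank = "family",
                            match = 2,
                            mismatch = -3,
                            gap_open = 5,
                            gap_extend = 2,
                            rng_seed = NULL) {
  cfg <- list(
    evalue_max = as.numeric(evalue_max),
    top_hits = as.integer(top_hits),
    min_contig_len = as.integer(min_contig_len),
    coverage_boundary = as.numeric(coverage_boundary),
    demarcation_identity = as.numeric(demarcation_identity),
    min_terminal_repeat = as.integer(min_terminal_repeat),
    lca_score_window = as.numeric(lca_score_window),
    related_rank = as.character(related_rank),
    match = as.numeric(match),
    mismatch = as.numeric(mismatch),
    gap_open = as.numeric(gap_open),
    gap_extend = as.numeric(gap_extend),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  stopifnot(
    cfg$evalue_max > 0,
    cfg$top_hits >= 1L,
    cfg$min_contig_len >= 0L,
    cfg$coverage_boundary >= 0, cfg$coverage_boundary <= 100,
    cfg$demarcation_identity >= 0, cfg$demarcation_identity <= 100,
    cfg$min_terminal_repeat >= 1L,
    cfg$lca_score_window >= 0, cfg$lca_score_window <= 1,
    cfg$match > 0, cfg$mismatch < 0, cfg$gap_open >= 0, cfg$gap_extend > 0
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Plain-text \code{key = value} format, one key per line; \code{#} starts a
#' comment. Every key must be a \code{\link{pipeline_config}} argument; keys
#' not present keep their defaults.
#'
#' @param path path to the configuration file.
#' @return a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(pipeline_config())
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(\\S+)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  for (k in keys) {
    if (k != "related_rank") args[[k]] <- as.numeric(args[[k]])
  }
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (k in names(x)) {
    cat(sprintf("  %-21s %s\n", k, if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}
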