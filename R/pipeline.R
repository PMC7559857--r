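#' @title Workflow orchestration: annotate, compare, report
#' @description Thin composition of the stage functions: read -> filter ->
#'   assign -> cluster -> abundance -> classify, plus cross-pool comparison
#'   and report assembly. Every run records a manifest (config snapshot,
#'   input checksums, per-stage row counts, seed) so re-runs on the same
#'   inputs are byte-identical and auditable.
#' @name pipeline
NULL

manifest_checksum <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    # in-memory input: hash its serialization (version-pinned for stability)
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2L)
    unname(tools::md5sum(f))
  }
}

#' Annotate one pool: filter, assign, cluster, quantify, classify
#'
#' Inputs may be file paths (read with the package readers) or the
#' corresponding in-memory objects.
#'
#' @param hits hit table or path (\code{\link{read_hit_table}} dialect;
#'   paths must carry the qlen/staxid extension columns).
#' @param counts counts table or path (\code{\link{read_counts}} dialect).
#' @param tree \code{taxonomy} or path.
#' @param host_map \code{host_map} or path (optional).
#' @param exclusions an \code{\link{exclusion_set}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param mode taxon-assignment strategy (\code{"best_hit"} or \code{"lca"}).
#' @param sample_id pool label recorded in outputs.
#' @param out_dir optional directory; when given, stage TSVs and
#'   \code{manifest.json} are written there.
#' @return list of class \code{annotate_run}: filtered, assigned, clusters,
#'   abundance, calls, manifest.
#' @export
run_annotate <- function(hits, counts, tree, host_map = NULL,
                         exclusions = exclusion_set(),
                         config = pipeline_config(),
                         mode = c("best_hit", "lca"),
                         sample_id = "sample", out_dir = NULL) {
  mode <- match.arg(mode)
  checksums <- list(hits = manifest_checksum(hits),
                    counts = manifest_checksum(counts))
  if (is.character(hits)) {
    if (!file.exists(hits)) stop("run_annotate: missing input file ", hits)
    hits <- read_hit_table(hits)
  }
  if (is.character(counts)) {
    if (!file.exists(counts)) stop("run_annotate: missing input file ", counts)
    counts <- read_counts(counts)
  }
  if (is.character(tree)) tree <- read_taxonomy(tree)
  if (is.character(host_map) && !inherits(host_map, "host_map")) {
    host_map <- read_host_map(host_map)
  }

  filtered <- filter_hits(hits, exclusions, config)
  assigned <- assign_taxa(filtered, tree, mode, config)
  clusters <- cluster_by_taxon(assigned)
  # carry the broad flag onto clusters for downstream consumers
  broad_by_query <- tapply(filtered$broad_flag, filtered$query_id, any)
  clusters$broad_flag <- vapply(clusters$member_queries, function(m)
    any(broad_by_query[m], na.rm = TRUE), NA)

  ab <- rpkm_table(counts[counts$sample_id == sample_id |
                            length(unique(counts$sample_id)) == 1L, ,
                          drop = FALSE])
  contig_rpkm <- stats::setNames(ab$rpkm, ab$contig_id)
  taxon_rpkm <- stats::setNames(rpkm_taxon(clusters, contig_rpkm),
                                clusters$tax_id)
  calls <- classify(clusters, config, host_map, taxon_rpkm, tree)

  manifest <- list(
    sample_id = sample_id, mode = mode,
    config = unclass(config), input_checksums = checksums,
    rows = list(read = nrow(hits), filtered = nrow(filtered),
                assigned = nrow(assigned), clustered = nrow(clusters),
                classified = nrow(calls)),
    version = as.character(utils::packageVersion("viromecore")),
    rng_seed = config$rng_seed)

  out <- structure(list(filtered = filtered, assigned = assigned,
                        clusters = clusters, abundance = ab, calls = calls,
                        manifest = manifest),
                   class = "annotate_run")
  if (!is.null(out_dir)) write_annotate_run(out, out_dir, tree)
  out
}

write_annotate_run <- function(run, out_dir, tree = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_hit_table(run$filtered, file.path(out_dir, "filtered_hits.tsv"))
  utils::write.table(run$assigned, file.path(out_dir, "assigned.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_clusters(run$clusters, file.path(out_dir, "clusters.tsv"), tree)
  write_abundance(run$abundance, file.path(out_dir, "abundance.tsv"))
  utils::write.table(run$calls, file.path(out_dir, "confidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Compare annotated pools: richness, signatures, host groups
#'
#' @param pools list of \code{pool_virome} (at least two).
#' @param tree a \code{taxonomy}.
#' @param host_map a \code{host_map}.
#' @param level rank for richness (default species).
#' @param include_broad include broad-category taxa.
#' @param out_dir optional output directory for the comparative TSVs.
#' @return list: richness, signatures (data.frame over all pool pairs),
#'   host_groups, presence (pools x taxa matrix).
#' @export
run_compare <- function(pools, tree, host_map = NULL, level = "species",
                        include_broad = FALSE, out_dir = NULL) {
  if (length(pools) < 2L) stop("run_compare: need at least two pools")
  rich <- richness(pools, tree, level, include_broad)
  prs <- utils::combn(length(pools), 2L)
  signatures <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    sr <- signature_taxa(pools[[prs[1, i]]], pools[[prs[2, i]]], include_broad)
    data.frame(pool_a = sr$pool_pair[1], pool_b = sr$pool_pair[2],
               n_shared = sr$n_shared,
               shared_taxa = paste(sr$shared_taxa, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  hg <- if (is.null(host_map)) NULL else host_group_summary(pools, host_map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(signatures, file.path(out_dir, "signatures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(hg)) {
      utils::write.table(hg, file.path(out_dir, "host_groups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
      data.frame(metric = c("total", "singletons"),
                 value = c(rich$total, rich$singletons)),
      file.path(out_dir, "richness.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rich$presence * 1L,
                       file.path(out_dir, "presence_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  list(richness = rich, signatures = signatures, host_groups = hg,
       presence = rich$presence)
}

#' Assemble the goodness-of-assignment report for one pool
#'
#' @param calls a \code{confidence_calls} data.frame.
#' @param config a \code{pipeline_config}.
#' @param out_dir optional directory: writes \code{scatter.tsv},
#'   \code{scatter.png} and \code{summary.json}.
#' @return list: scatter (data.frame), plot (ggplot), summary (list).
#' @export
run_report <- function(calls, config = pipeline_config(), out_dir = NULL) {
  sc <- scatter_table(calls)
  plt <- plot_confidence(calls, config)
  summary <- list(
    n_taxa = nrow(calls),
    n_high_confidence = sum(calls$class == "high_confidence"),
    n_novel = sum(calls$class == "novel"),
    total_rpkm = sum(calls$rpkm),
    host_groups = as.list(table(calls$host_group)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sc, file.path(out_dir, "scatter.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ggplot2::ggsave(file.path(out_dir, "scatter.png"), plt,
                    width = 7, height = 5, dpi = 150)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scatter = sc, plot = plt, summary = summary)
}

#' Annotate every pool of a simulation and return pool viromes
#'
#' Convenience wrapper running \code{\link{run_annotate}} on each pool of
#' a \code{virome_simulation} with its own taxonomy, host map and
#' control-derived exclusions.
#'
#' @param sim a \code{virome_simulation}.
#' @param config a \code{pipeline_config}.
#' @param mode assignment strategy.
#' @return named list of \code{pool_virome}; the underlying
#'   \code{annotate_run}s are in attribute \code{"runs"}.
#' @export
annotate_simulation <- function(sim, config = pipeline_config(),
                                mode = "best_hit") {
  runs <- lapply(sim$pool_names, function(pool) {
    run_annotate(sim$hits[[pool]],
                 sim$counts[sim$counts$sample_id == pool, , drop = FALSE],
                 sim$tree, sim$host_map, sim$exclusions, config, mode,
                 sample_id = pool)
  })
  names(runs) <- sim$pool_names
  pools <- lapply(sim$pool_names, function(pool)
    pool_virome(pool, runs[[pool]]$calls,
                site_label = sub("_.*$", "", pool)))
  names(pools) <- sim$pool_names
  attr(pools, "runs") <- runs
  pools
}
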