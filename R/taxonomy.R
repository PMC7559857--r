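#' @title Taxonomy trees, host-group maps and taxon assignment
#' @description Backing structures for lowest-common-ancestor (LCA)
#'   classification. A taxonomy is a rooted tree of nodes (tax_id,
#'   parent_id, rank, name) following the NCBI dump convention that the
#'   root is its own parent.
#' @name taxonomy
NULL

#' Controlled vocabulary of taxonomic ranks, root-most first.
#' @export
TAX_RANKS <- c("root", "superkingdom", "kingdom", "phylum", "class",
               "order", "family", "genus", "species", "no_rank")

#' Controlled vocabulary of virus host groups.
#' @export
HOST_GROUPS <- c("mosquito", "bat", "other_mammal", "human", "plant",
                 "environmental", "bacteriophage", "other_vertebrate",
                 "other_invertebrate", "unassigned")

#' Sentinel tax_id for queries with no surviving hits.
#' @export
UNASSIGNED_TAXON <- NA_integer_

#' Build a taxonomy tree from a node table
#'
#' @param nodes data.frame with columns tax_id, parent_id, rank, name.
#'   Exactly one node must be its own parent (the root); every parent_id
#'   must resolve and no cycles are permitted.
#' @return an object of class \code{taxonomy}: the node table plus indexed
#'   parent/rank/name lookups and per-node depth (root depth 0).
#' @export
taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("tax_id", "parent_id", "rank", "name") %in% names(nodes)))
  nodes$tax_id <- as.integer(nodes$tax_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$rank <- as.character(nodes$rank)
  nodes$name <- as.character(nodes$name)
  if (anyNA(nodes$tax_id) || any(nodes$tax_id <= 0L)) {
    stop("taxonomy format error: tax_id must be a positive integer")
  }
  if (anyDuplicated(nodes$tax_id)) {
    stop("taxonomy format error: duplicate tax_id ",
         paste(unique(nodes$tax_id[duplicated(nodes$tax_id)]), collapse = ", "))
  }
  bad_rank <- setdiff(unique(nodes$rank), TAX_RANKS)
  if (length(bad_rank)) {
    stop("taxonomy format error: unknown rank(s) ", paste(bad_rank, collapse = ", "))
  }
  id <- as.character(nodes$tax_id)
  parent <- stats::setNames(nodes$parent_id, id)
  missing_parent <- setdiff(nodes$parent_id, nodes$tax_id)
  if (length(missing_parent)) {
    stop("taxonomy structure error: unresolved parent_id ",
         paste(missing_parent, collapse = ", "))
  }
  roots <- nodes$tax_id[nodes$tax_id == nodes$parent_id]
  if (length(roots) != 1L) {
    stop("taxonomy structure error: expected exactly one self-parent root, found ",
         length(roots))
  }
  # depth by iterative parent-walk; a walk longer than the node count is a cycle
  n <- nrow(nodes)
  depth <- stats::setNames(rep(NA_integer_, n), id)
  for (i in seq_len(n)) {
    cur <- nodes$tax_id[i]
    steps <- 0L
    chain <- integer(0)
    while (is.na(depth[as.character(cur)]) && cur != roots) {
      chain <- c(chain, cur)
      cur <- parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) stop("taxonomy structure error: cycle involving tax_id ", nodes$tax_id[i])
    }
    base <- if (cur == roots) 0L else depth[[as.character(cur)]]
    if (length(chain)) depth[as.character(rev(chain))] <- base + seq_along(chain)
    if (cur == roots) depth[as.character(roots)] <- 0L
  }
  structure(list(
    nodes = nodes,
    root = roots,
    parent = parent,
    rank = stats::setNames(nodes$rank, id),
    name = stats::setNames(nodes$name, id),
    depth = depth
  ), class = "taxonomy")
}

#' Read a taxonomy TSV (tax_id, parent_id, rank, name; header required)
#' @param path path to the tab-separated node table.
#' @return a \code{taxonomy}.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "character", "character"),
                          quote = "", comment.char = "")
  need <- c("tax_id", "parent_id", "rank", "name")
  if (!all(need %in% names(df))) {
    stop("taxonomy format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  taxonomy(df[need])
}

#' Write a taxonomy to TSV
#' @param tree a \code{taxonomy}.
#' @param path output path.
#' @export
write_taxonomy <- function(tree, path) {
  utils::write.table(tree$nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy:", nrow(x$nodes), "nodes, root tax_id", x$root,
      "max depth", max(x$depth), "\n")
  invisible(x)
}

has_taxon <- function(tree, taxa) as.character(taxa) %in% names(tree$parent)

#' Root-to-node path of tax_ids (root first, node last)
#' @param tree a \code{taxonomy}.
#' @param tax_id a single tax_id present in the tree.
#' @return integer vector of tax_ids.
#' @export
tax_path <- function(tree, tax_id) {
  if (!has_taxon(tree, tax_id)) stop("unknown tax_id: ", tax_id)
  cur <- as.integer(tax_id)
  path <- integer(tree$depth[[as.character(cur)]] + 1L)
  for (i in rev(seq_along(path))) {
    path[i] <- cur
    cur <- tree$parent[[as.character(cur)]]
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon,
#' computed by equalizing depths and walking parents in lockstep.
#'
#' @param tree a \code{taxonomy}.
#' @param taxa non-empty vector of tax_ids, all present in the tree.
#' @return a single tax_id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0L) stop("lca: empty taxon set")
  unknown <- taxa[!has_taxon(tree, taxa)]
  if (length(unknown)) stop("lca: unknown tax_id ", paste(unknown, collapse = ", "))
  cur <- taxa[1]
  for (other in taxa[-1]) {
    a <- cur; b <- other
    da <- tree$depth[[as.character(a)]]; db <- tree$depth[[as.character(b)]]
    while (da > db) { a <- tree$parent[[as.character(a)]]; da <- da - 1L }
    while (db > da) { b <- tree$parent[[as.character(b)]]; db <- db - 1L }
    while (a != b) {
      a <- tree$parent[[as.character(a)]]
      b <- tree$parent[[as.character(b)]]
    }
    cur <- a
  }
  cur
}

#' Ancestor of a taxon at a given rank
#'
#' Walks the parent chain and returns the first node whose rank equals
#' \code{rank}; NA when no ancestor carries that rank (for instance a taxon
#' attached above family level when family is requested).
#'
#' @param tree a \code{taxonomy}.
#' @param tax_id tax_id present in the tree (vectorized).
#' @param rank one of \code{TAX_RANKS}.
#' @return integer vector of tax_ids (NA where unresolvable).
#' @export
ancestor_at_rank <- function(tree, tax_id, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  vapply(as.integer(tax_id), function(tid) {
    if (is.na(tid) || !has_taxon(tree, tid)) return(NA_integer_)
    cur <- tid
    repeat {
      if (tree$rank[[as.character(cur)]] == rank) return(cur)
      nxt <- tree$parent[[as.character(cur)]]
      if (nxt == cur) return(NA_integer_)
      cur <- nxt
    }
  }, integer(1))
}

#' Read a host-group map TSV (tax_id, host_group; header required)
#'
#' @param path path to the tab-separated table.
#' @return named integer-keyed vector of class \code{host_map}; labels are
#'   validated against \code{HOST_GROUPS}.
#' @export
read_host_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  if (!all(c("tax_id", "host_group") %in% names(df))) {
    stop("host map format error: need columns tax_id, host_group")
  }
  host_map(stats::setNames(as.character(df$host_group), as.integer(df$tax_id)))
}

#' Construct a host-group map from a named vector (names = tax_ids)
#' @param x named character vector, values in \code{HOST_GROUPS}.
#' @export
host_map <- function(x = character()) {
  bad <- setdiff(unique(unname(x)), HOST_GROUPS)
  if (length(bad)) stop("unknown host group(s): ", paste(bad, collapse = ", "))
  structure(x, class = "host_map")
}

#' Resolve tax_ids to host-group labels ("unassigned" when unmapped)
#' @param map a \code{host_map}.
#' @param taxa vector of tax_ids.
#' @return character vector of labels.
#' @export
host_group <- function(map, taxa) {
  out <- unname(unclass(map)[as.character(taxa)])
  out[is.na(out)] <- "unassigned"
  out
}

#' Write a host-group map to TSV
#' @param map a \code{host_map}.
#' @param path output path.
#' @export
write_host_map <- function(map, path) {
  utils::write.table(
    data.frame(tax_id = as.integer(names(map)), host_group = unname(unclass(map))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign a taxon to one query from its (pre-filtered) hits
#'
#' Two strategies mirroring common practice: \code{best_hit} takes the taxon
#' of the maximal-bitscore hit (ties broken by lowest e-value, then lowest
#' tax_id); \code{lca} takes the lowest common ancestor of all hits whose
#' bitscore is at least (1 - lca_score_window) times the top bitscore, the
#' MEGAN-style "top percent" idea reduced to a single tunable.
#'
#' @param hits data.frame of hit records for ONE query (may be empty).
#' @param tree a \code{taxonomy}.
#' @param mode \code{"best_hit"} or \code{"lca"}.
#' @param config a \code{pipeline_config}.
#' @return a tax_id, or \code{UNASSIGNED_TAXON} for an empty hit list.
#' @export
assign_taxon <- function(hits, tree, mode = c("best_hit", "lca"),
                         config = pipeline_config()) {
  mode <- match.arg(mode)
  if (is.null(hits) || nrow(hits) == 0L) return(UNASSIGNED_TAXON)
  if (mode == "best_hit") {
    ord <- order(-hits$bitscore, hits$evalue, hits$subject_taxid)
    return(as.integer(hits$subject_taxid[ord[1]]))
  }
  top <- max(hits$bitscore)
  keep <- hits$bitscore >= (1 - config$lca_score_window) * top
  lca(tree, hits$subject_taxid[keep])
}

#' Assign taxa to every query in a hit table
#'
#' Applies \code{\link{assign_taxon}} per query and returns one row per
#' query carrying the assigned tax_id together with the best hit's identity,
#' query coverage and subject, which downstream clustering summarizes.
#'
#' @param hits filtered hit table (see \code{\link{filter_hits}}).
#' @param tree a \code{taxonomy}.
#' @param mode assignment strategy, as \code{\link{assign_taxon}}.
#' @param config a \code{pipeline_config}.
#' @return data.frame: query_id, tax_id, subject_id, pident, query_coverage,
#'   bitscore, evalue, query_length.
#' @export
assign_taxa <- function(hits, tree, mode = c("best_hit", "lca"),
                        config = pipeline_config()) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), tax_id = integer(),
                      subject_id = character(), pident = numeric(),
                      query_coverage = numeric(), bitscore = numeric(),
                      evalue = numeric(), query_length = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(hits, hits$query_id), function(h) {
    tid <- assign_taxon(h, tree, mode, config)
    ord <- order(-h$bitscore, h$evalue, h$subject_taxid)
    best <- h[ord[1], ]
    data.frame(query_id = best$query_id, tax_id = tid,
               subject_id = best$subject_id, pident = best$pident,
               query_coverage = query_coverage(best),
               bitscore = best$bitscore, evalue = best$evalue,
               query_length = best$query_length, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
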