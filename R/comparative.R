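#' @title Cross-pool virome comparison: richness, ecosystem signatures,
#'   host groups
#' @name comparative
NULL

#' A single pool's virome
#'
#' @param sample_id pool identifier.
#' @param calls a \code{confidence_calls} data.frame (or any data.frame
#'   with tax_id and rpkm columns; class/host_group optional).
#' @param site_label optional geographic/site label.
#' @return list of class \code{pool_virome}.
#' @export
pool_virome <- function(sample_id, calls, site_label = NA_character_) {
  stopifnot(all(c("tax_id", "rpkm") %in% names(calls)))
  if (anyDuplicated(calls$tax_id)) stop("pool_virome: duplicate tax_id in ", sample_id)
  if (any(calls$rpkm < 0)) stop("pool_virome: negative rpkm in ", sample_id)
  structure(list(sample_id = as.character(sample_id),
                 site_label = site_label, calls = calls),
            class = "pool_virome")
}

pool_taxa <- function(pool, include_broad = TRUE) {
  calls <- pool$calls
  if (!include_broad && "broad_flag" %in% names(calls)) {
    calls <- calls[!calls$broad_flag, , drop = FALSE]
  }
  calls$tax_id
}

#' Virome richness across pools
#'
#' Distinct taxa across all pools at a requested rank, per-pool counts,
#' and the number of singletons (taxa detected in exactly one pool). Taxa
#' that do not resolve to the requested rank are counted at their own
#' level (with a message). Broad-category taxa are excluded by default.
#'
#' @param pools list of \code{pool_virome}.
#' @param tree a \code{taxonomy} used to resolve ranks.
#' @param level rank at which to count (default "species").
#' @param include_broad include broad-category (uncultured/unclassified)
#'   taxa flagged upstream.
#' @return list: total, singletons, per_pool (named counts), taxa
#'   (presence matrix pools x taxa).
#' @export
richness <- function(pools, tree, level = "species", include_broad = FALSE) {
  resolved <- lapply(pools, function(p) {
    taxa <- pool_taxa(p, include_broad)
    at <- ancestor_at_rank(tree, taxa, level)
    n_un <- sum(is.na(at))
    if (n_un > 0L) {
      message("richness: ", n_un, " taxa in ", p$sample_id,
              " not resolvable to ", level, "; counted at their own level")
    }
    unique(ifelse(is.na(at), taxa, at))
  })
  names(resolved) <- vapply(pools, function(p) p$sample_id, "")
  all_taxa <- sort(unique(unlist(resolved)))
  pres <- vapply(resolved, function(tx) all_taxa %in% tx,
                 logical(length(all_taxa)))
  pres <- matrix(pres, nrow = length(all_taxa),
                 dimnames = list(all_taxa, names(resolved)))
  occ <- rowSums(pres)
  list(total = length(all_taxa),
       singletons = sum(occ == 1L),
       per_pool = vapply(resolved, length, 0L),
       presence = t(pres))
}

#' Ecosystem signature taxa shared between two pools
#'
#' @param a,b \code{pool_virome} objects.
#' @param include_broad include broad-category taxa.
#' @return list of class \code{signature_report}: pool_pair, shared_taxa,
#'   n_shared, exclusive counts per pool.
#' @export
signature_taxa <- function(a, b, include_broad = FALSE) {
  ta <- pool_taxa(a, include_broad); tb <- pool_taxa(b, include_broad)
  shared <- sort(intersect(ta, tb))
  structure(list(pool_pair = c(a$sample_id, b$sample_id),
                 shared_taxa = shared, n_shared = length(shared),
                 exclusive = stats::setNames(c(length(setdiff(ta, tb)),
                                               length(setdiff(tb, ta))),
                                             c(a$sample_id, b$sample_id))),
            class = "signature_report")
}

#' Host-group richness and cumulative abundance per pool
#'
#' For each pool and host group: the number of taxa and the summed RPKM.
#' Taxa absent from the map fall under "unassigned". The per-pool RPKM
#' total is conserved across groups.
#'
#' @param pools list of \code{pool_virome}.
#' @param host_map a \code{host_map}.
#' @return data.frame: sample_id, host_group, n_taxa, rpkm.
#' @export
host_group_summary <- function(pools, host_map) {
  out <- do.call(rbind, lapply(pools, function(p) {
    if (nrow(p$calls) == 0L) return(NULL)
    grp <- host_group(host_map, p$calls$tax_id)
    agg <- do.call(rbind, lapply(split(seq_len(nrow(p$calls)), grp), function(idx) {
      data.frame(host_group = grp[idx[1]], n_taxa = length(idx),
                 rpkm = sum(p$calls$rpkm[idx]), stringsAsFactors = FALSE)
    }))
    cbind(sample_id = p$sample_id, agg)
  }))
  rownames(out) <- NULL
  out
}
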