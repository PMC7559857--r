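#' @title BLAST-style tabular hit ingestion, filtering and taxon clustering
#' @name hits
NULL

OUTFMT6_COLS <- c("query_id", "subject_id", "pident", "align_length",
                  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a BLAST outfmt-6-like tabular hit file
#'
#' Accepts the 12 standard tab-separated columns (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) with no
#' header, optionally extended by columns 13 (qlen) and 14 (staxid). When
#' the extension columns are absent, query lengths and subject taxa must be
#' supplied as sidecar tables. Rows violating the record invariants
#' (coordinates outside the query, identity outside [0,100], negative
#' e-value, non-numeric fields) are rejected, not fatal: they are reported
#' via \code{message()} and attached as the \code{"rejected"} attribute
#' (data.frame of line numbers and reasons).
#'
#' @param path hit table path.
#' @param query_lengths optional data.frame (query_id, length) or named
#'   vector; required when the table lacks a qlen column.
#' @param subject_taxa optional data.frame (subject_id, tax_id) or named
#'   vector; required when the table lacks a staxid column.
#' @return data.frame of hit records with canonical columns
#'   (OUTFMT6 columns plus query_length and subject_taxid).
#' @export
read_hit_table <- function(path, query_lengths = NULL, subject_taxa = NULL) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 12L) {
    stop("hit table format error: expected >= 12 tab-separated columns, got ", ncol(raw))
  }
  has_qlen <- ncol(raw) >= 13L
  has_taxid <- ncol(raw) >= 14L
  names(raw)[1:12] <- OUTFMT6_COLS
  if (has_qlen) names(raw)[13] <- "query_length"
  if (has_taxid) names(raw)[14] <- "subject_taxid"

  num_cols <- c("pident", "align_length", "mismatch", "gapopen", "qstart",
                "qend", "sstart", "send", "evalue", "bitscore",
                if (has_qlen) "query_length", if (has_taxid) "subject_taxid")
  df <- raw
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))

  if (!has_qlen) {
    ql <- sidecar_vector(query_lengths, c("query_id", "length"),
                         "query_lengths sidecar required (table has no qlen column)")
    df$query_length <- unname(ql[df$query_id])
  }
  if (!has_taxid) {
    st <- sidecar_vector(subject_taxa, c("subject_id", "tax_id"),
                         "subject_taxa sidecar required (table has no staxid column)")
    df$subject_taxid <- unname(st[df$subject_id])
  }

  reason <- rep(NA_character_, nrow(df))
  bad_num <- rowSums(is.na(df[num_cols])) > 0 |
    is.na(df$query_length) | is.na(df$subject_taxid)
  reason[bad_num] <- "non-numeric or unresolvable field"
  ok <- !bad_num
  viol <- ok & !(df$qstart >= 1 & df$qstart <= df$qend &
                   df$qend <= df$query_length &
                   df$pident >= 0 & df$pident <= 100 & df$evalue >= 0)
  reason[viol] <- "invariant violation (coords/identity/evalue)"
  keep <- is.na(reason)

  rejected <- data.frame(line = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L) {
    message("read_hit_table: rejected ", nrow(rejected), " of ", nrow(df),
            " rows (", path, ")")
  }
  out <- df[keep, c(OUTFMT6_COLS, "query_length", "subject_taxid")]
  out$query_length <- as.integer(out$query_length)
  out$subject_taxid <- as.integer(out$subject_taxid)
  for (cc in c("align_length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send")) out[[cc]] <- as.integer(out[[cc]])
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

sidecar_vector <- function(x, cols, msg) {
  if (is.null(x)) stop("hit table format error: ", msg)
  if (is.data.frame(x)) {
    stopifnot(all(cols %in% names(x)))
    stats::setNames(x[[cols[2]]], as.character(x[[cols[1]]]))
  } else {
    x
  }
}

#' Write hit records back to the 14-column tabular dialect
#' @param hits hit table as returned by \code{\link{read_hit_table}}.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[, c(OUTFMT6_COLS, "query_length", "subject_taxid")]
  # e-values and bitscores kept at full precision so read->write->read is exact
  out$pident <- formatC(out$pident, format = "fg", digits = 15)
  out$evalue <- formatC(out$evalue, format = "g", digits = 17)
  out$bitscore <- formatC(out$bitscore, format = "g", digits = 17)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Percent of the query spanned by a hit
#'
#' Single-HSP span: 100 * (qend - qstart + 1) / query_length. Vectorized
#' over the rows of a hit table.
#'
#' @param hits hit table (rows are individual HSPs).
#' @return numeric vector of percentages in (0, 100].
#' @export
query_coverage <- function(hits) {
  100 * (hits$qend - hits$qstart + 1) / hits$query_length
}

#' Exclusion lists for contaminant and uninformative hits
#'
#' Subjects seen in the no-template control, known vector sequences and
#' plasmids are excluded outright; "broad category" taxa (uncultured /
#' unclassified bins) are only flagged here, because they are excluded from
#' richness summaries but retained in the goodness-of-assignment analysis.
#'
#' @param control_subjects,vector_subjects,plasmid_subjects character
#'   vectors of subject_ids (exact match).
#' @param broad_taxa integer vector of tax_ids to flag as broad categories.
#' @export
exclusion_set <- function(control_subjects = character(),
                          vector_subjects = character(),
                          plasmid_subjects = character(),
                          broad_taxa = integer()) {
  structure(list(control_subjects = as.character(control_subjects),
                 vector_subjects = as.character(vector_subjects),
                 plasmid_subjects = as.character(plasmid_subjects),
                 broad_taxa = as.integer(broad_taxa)),
            class = "exclusion_set")
}

#' Build an exclusion set from a no-template-control hit table
#'
#' A subject counts as "detected in the control" when a control hit to it
#' passes the e-value threshold; weaker control alignments are noise and do
#' not blacklist a subject.
#'
#' @param control_hits hit table from the no-template control.
#' @param config a \code{\link{pipeline_config}} (e-value threshold).
#' @param vector_subjects,plasmid_subjects,broad_taxa passed through to
#'   \code{\link{exclusion_set}}.
#' @return an \code{exclusion_set}.
#' @export
control_exclusions <- function(control_hits, config = pipeline_config(),
                               vector_subjects = character(),
                               plasmid_subjects = character(),
                               broad_taxa = integer()) {
  detected <- unique(control_hits$subject_id[control_hits$evalue <= config$evalue_max])
  exclusion_set(control_subjects = detected,
                vector_subjects = vector_subjects,
                plasmid_subjects = plasmid_subjects,
                broad_taxa = broad_taxa)
}

#' Filter a hit table
#'
#' Applies, in order: the e-value ceiling; the per-query cap of
#' \code{top_hits} hits ranked by bitscore (ties by subject_id); removal of
#' hits to excluded subjects (control, vector, plasmid); removal of all hits
#' for queries shorter than \code{min_contig_len}. Broad-category taxa are
#' flagged in a \code{broad_flag} column, not removed. The whole operation
#' is idempotent. Per-category removal counts are reported via
#' \code{message()} and attached as the \code{"removed"} attribute.
#'
#' @param hits hit table.
#' @param exclusions an \code{\link{exclusion_set}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return the surviving hit table with a logical \code{broad_flag} column.
#' @export
filter_hits <- function(hits, exclusions = exclusion_set(),
                        config = pipeline_config()) {
  n0 <- nrow(hits)
  h <- hits[hits$evalue <= config$evalue_max, , drop = FALSE]
  n_eval <- n0 - nrow(h)

  if (nrow(h) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(h)), h$query_id), function(idx) {
      ord <- order(-h$bitscore[idx], h$subject_id[idx])
      idx[ord[seq_len(min(config$top_hits, length(idx)))]]
    }), use.names = FALSE)
    keep <- sort(keep)
    n_top <- nrow(h) - length(keep)
    h <- h[keep, , drop = FALSE]
  } else n_top <- 0L

  excl_subj <- unique(c(exclusions$control_subjects, exclusions$vector_subjects,
                        exclusions$plasmid_subjects))
  drop_excl <- h$subject_id %in% excl_subj
  n_excl <- sum(drop_excl)
  h <- h[!drop_excl, , drop = FALSE]

  drop_len <- h$query_length < config$min_contig_len
  n_len <- sum(drop_len)
  h <- h[!drop_len, , drop = FALSE]

  h$broad_flag <- h$subject_taxid %in% exclusions$broad_taxa
  rownames(h) <- NULL
  removed <- c(evalue = n_eval, top_hits = n_top, excluded_subject = n_excl,
               short_query = n_len)
  if (sum(removed) > 0L) {
    message("filter_hits: removed ", sum(removed), "/", n0, " hits (",
            paste(names(removed), removed, sep = "=", collapse = ", "), ")")
  }
  attr(h, "removed") <- removed
  h
}

#' Cluster assigned queries by taxon
#'
#' One cluster per distinct assigned tax_id, carrying the unweighted
#' arithmetic mean of member identities and query coverages, the member
#' queries, and a per-subject breakdown (mean identity / mean coverage per
#' subject_id) for taxa hit through several database sequences.
#'
#' @param assigned data.frame from \code{\link{assign_taxa}} (one row per
#'   query: query_id, tax_id, subject_id, pident, query_coverage).
#' @return data.frame of class \code{taxon_clusters}: tax_id, n_contigs,
#'   mean_identity, mean_query_coverage, plus list-columns member_queries
#'   and per_subject.
#' @export
cluster_by_taxon <- function(assigned) {
  assigned <- assigned[!is.na(assigned$tax_id), , drop = FALSE]
  if (nrow(assigned) == 0L) {
    out <- data.frame(tax_id = integer(), n_contigs = integer(),
                      mean_identity = numeric(), mean_query_coverage = numeric())
    out$member_queries <- list()
    out$per_subject <- list()
    class(out) <- c("taxon_clusters", class(out))
    return(out)
  }
  if (anyDuplicated(assigned$query_id)) {
    stop("cluster_by_taxon: multiple assignments for query ",
         assigned$query_id[duplicated(assigned$query_id)][1])
  }
  grp <- split(assigned, assigned$tax_id)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(tax_id = g$tax_id[1], n_contigs = nrow(g),
               mean_identity = mean(g$pident),
               mean_query_coverage = mean(g$query_coverage))
  }))
  out$member_queries <- lapply(grp, function(g) g$query_id)
  out$per_subject <- lapply(grp, function(g) {
    sb <- split(g, g$subject_id)
    do.call(rbind, lapply(sb, function(s) {
      data.frame(subject_id = s$subject_id[1], n = nrow(s),
                 mean_identity = mean(s$pident),
                 mean_query_coverage = mean(s$query_coverage),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  class(out) <- c("taxon_clusters", class(out))
  out
}

#' Write taxon clusters to TSV (list-columns serialized compactly)
#' @param clusters a \code{taxon_clusters} data.frame.
#' @param path output path.
#' @param tree optional \code{taxonomy} used to add a name column.
#' @export
write_clusters <- function(clusters, path, tree = NULL) {
  flat <- data.frame(
    tax_id = clusters$tax_id,
    name = if (is.null(tree)) NA_character_ else
      unname(tree$name[as.character(clusters$tax_id)]),
    n_contigs = clusters$n_contigs,
    mean_identity = clusters$mean_identity,
    mean_query_coverage = clusters$mean_query_coverage,
    member_queries = vapply(clusters$member_queries, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
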