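#' @title RPKM abundance per contig and per taxon
#' @description Reads per kilobase of contig per million mapped reads,
#'   normalizing by contig length and per-sample sequencing depth. The
#'   depth denominator is the per-sample total of reads mapped to any
#'   contig (not raw read count).
#' @name abundance
NULL

#' Read a per-contig mapping count table
#'
#' TSV with header: sample_id, contig_id, length, mapped_reads.
#'
#' @param path counts table path.
#' @return validated data.frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  need <- c("sample_id", "contig_id", "length", "mapped_reads")
  if (!all(need %in% names(df))) {
    stop("counts format error: need columns ", paste(need, collapse = ", "))
  }
  df$length <- as.integer(df$length)
  df$mapped_reads <- as.integer(df$mapped_reads)
  if (any(df$length <= 0L)) stop("counts format error: non-positive contig length")
  if (any(df$mapped_reads < 0L)) stop("counts format error: negative mapped_reads")
  df[need]
}

#' RPKM of a contig
#'
#' \code{mapped_reads / ((length/1000) * (total_mapped/1e6))}. Vectorized
#' over contigs; \code{total_mapped} is the sample's mapped-read total.
#'
#' @param mapped_reads reads mapped to the contig (>= 0).
#' @param length contig length in nucleotides (> 0).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return nonnegative numeric RPKM values.
#' @export
rpkm_contig <- function(mapped_reads, length, total_mapped) {
  if (any(total_mapped <= 0)) stop("rpkm_contig: undefined depth (total_mapped must be > 0)")
  stopifnot(all(length > 0), all(mapped_reads >= 0))
  mapped_reads / ((length / 1000) * (total_mapped / 1e6))
}

#' Per-sample contig RPKM table
#'
#' @param counts data.frame as from \code{\link{read_counts}}.
#' @return data.frame: sample_id, contig_id, length, mapped_reads, rpkm.
#' @export
rpkm_table <- function(counts) {
  totals <- tapply(counts$mapped_reads, counts$sample_id, sum)
  counts$rpkm <- rpkm_contig(counts$mapped_reads, counts$length,
                             unname(totals[as.character(counts$sample_id)]))
  counts
}

#' RPKM of a taxon cluster
#'
#' Unweighted arithmetic mean of the member contigs' RPKM values, applied
#' to every cluster in the table.
#'
#' @param clusters a \code{taxon_clusters} data.frame.
#' @param contig_rpkm named numeric vector, contig_id -> rpkm.
#' @return numeric vector of per-cluster RPKM, aligned with
#'   \code{clusters$tax_id}.
#' @export
rpkm_taxon <- function(clusters, contig_rpkm) {
  vapply(clusters$member_queries, function(members) {
    miss <- setdiff(members, names(contig_rpkm))
    if (length(miss)) {
      stop("rpkm_taxon: no RPKM entry for contig ", paste(miss, collapse = ", "))
    }
    mean(contig_rpkm[members])
  }, numeric(1))
}

#' Write an abundance table (long format)
#' @param df rows of (sample_id, level, id, rpkm).
#' @param path output path.
#' @export
write_abundance <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
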