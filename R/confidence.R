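#' @title Goodness-of-assignment classification and CRESS enrichment
#' @description The two-dimensional confidence analytic: taxon clusters are
#'   plotted by mean percent query coverage (x) against mean percent
#'   pairwise identity (y); clusters whose coverage exceeds the boundary
#'   (default 60%) form the high-confidence "core virome", the rest are
#'   treated as largely novel sequences whose hits match the database only
#'   over short stretches. Enrichment of CRESS-DNA taxa among the novel
#'   class is tested with a 2x2 Pearson chi-square.
#' @name confidence
NULL

#' Classify taxon clusters by the query-coverage boundary
#'
#' The boundary is strict: \code{class = "high_confidence"} iff
#' \code{mean_query_coverage > coverage_boundary}, so the ">60%" and
#' "0-60%" groups partition exactly. Output is sorted by descending RPKM.
#'
#' @param clusters a \code{taxon_clusters} data.frame.
#' @param config a \code{\link{pipeline_config}}.
#' @param host_map optional \code{host_map}; absent taxa become "unassigned".
#' @param taxon_rpkm optional named vector tax_id -> RPKM (defaults to 0).
#' @param tree optional \code{taxonomy} to attach display names.
#' @return data.frame of class \code{confidence_calls}: tax_id, name,
#'   mean_identity, mean_query_coverage, class, host_group, rpkm.
#' @export
classify <- function(clusters, config = pipeline_config(), host_map = NULL,
                     taxon_rpkm = NULL, tree = NULL) {
  n <- nrow(clusters)
  rpkm <- if (is.null(taxon_rpkm)) rep(0, n) else {
    v <- unname(taxon_rpkm[as.character(clusters$tax_id)])
    v[is.na(v)] <- 0
    v
  }
  calls <- data.frame(
    tax_id = clusters$tax_id,
    name = if (is.null(tree)) NA_character_ else
      unname(tree$name[as.character(clusters$tax_id)]),
    mean_identity = clusters$mean_identity,
    mean_query_coverage = clusters$mean_query_coverage,
    class = ifelse(clusters$mean_query_coverage > config$coverage_boundary,
                   "high_confidence", "novel"),
    host_group = if (is.null(host_map)) rep("unassigned", n) else
      host_group(host_map, clusters$tax_id),
    rpkm = rpkm,
    stringsAsFactors = FALSE)
  if ("broad_flag" %in% names(clusters)) calls$broad_flag <- clusters$broad_flag
  calls <- calls[order(-calls$rpkm, calls$tax_id), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("confidence_calls", class(calls))
  calls
}

#' Scatter table behind the goodness-of-assignment plot
#'
#' One row per taxon: x = mean query coverage, y = mean identity,
#' size = RPKM, color key = host group. Zero-RPKM taxa are retained with
#' size 0.
#'
#' @param calls a \code{confidence_calls} data.frame.
#' @return plain data.frame (tax_id, name, x, y, size, host_group, class).
#' @export
scatter_table <- function(calls) {
  if (nrow(calls) == 0L) stop("scatter_table: no calls")
  data.frame(tax_id = calls$tax_id, name = calls$name,
             x = calls$mean_query_coverage, y = calls$mean_identity,
             size = calls$rpkm, host_group = calls$host_group,
             class = calls$class, stringsAsFactors = FALSE)
}

#' Bubble plot of goodness-of-assignment fit
#'
#' @param calls a \code{confidence_calls} data.frame.
#' @param config a \code{pipeline_config} (drawn boundary line).
#' @return a ggplot object.
#' @export
plot_confidence <- function(calls, config = pipeline_config()) {
  df <- scatter_table(calls)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   size = size, color = host_group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = config$coverage_boundary, linetype = 2) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(x = "% coverage of query sequence",
                  y = "% pairwise sequence identity",
                  size = "RPKM", color = "host group") +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::theme_bw()
}

#' Pearson chi-square test on a 2x2 table
#'
#' Statistic \eqn{\sum (O - E)^2 / E} with expectations from the margins;
#' p-value from the chi-square survival function at 1 degree of freedom.
#' No continuity correction by default; \code{correct = TRUE} applies the
#' Yates correction.
#'
#' @param table 2x2 matrix of nonnegative counts; both margins must be > 0.
#' @param correct apply the Yates continuity correction.
#' @return list of class \code{enrichment_result}: table, statistic, df,
#'   p_value.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chi_square_2x2: degenerate table (zero margin)")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  structure(list(table = tab, statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("2x2 chi-square: statistic =", format(x$statistic, digits = 4),
      ", df = 1, p =", format(x$p_value, digits = 4), "\n")
  print(x$table)
  invisible(x)
}

#' CRESS-DNA enrichment among novel (low-coverage) hits
#'
#' Builds the 2x2 table class (novel / high_confidence) x category
#' (CRESS / non-CRESS) over the supplied calls and applies
#' \code{\link{chi_square_2x2}}.
#'
#' @param calls a \code{confidence_calls} data.frame.
#' @param cress_taxa tax_ids counted as CRESS-DNA viruses (typically every
#'   species under the CRESS families).
#' @param correct Yates correction flag, passed through.
#' @return an \code{enrichment_result}; the table has rows novel /
#'   high_confidence and columns cress / non_cress.
#' @export
cress_enrichment <- function(calls, cress_taxa, correct = FALSE) {
  is_cress <- calls$tax_id %in% cress_taxa
  is_novel <- calls$class == "novel"
  tab <- matrix(c(sum(is_novel & is_cress), sum(is_novel & !is_cress),
                  sum(!is_novel & is_cress), sum(!is_novel & !is_cress)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("novel", "high_confidence"),
                                c("cress", "non_cress")))
  chi_square_2x2(tab, correct = correct)
}

#' CRESS fraction summaries (by taxon count and by abundance)
#'
#' The fraction of CRESS taxa among novel hits, among high-confidence hits
#' and overall, computed both over taxa and weighted by RPKM, since either
#' summary is a defensible reading of "fraction of CRESS-DNA viruses".
#'
#' @param calls a \code{confidence_calls} data.frame.
#' @param cress_taxa tax_ids counted as CRESS.
#' @return data.frame: group, frac_taxa, frac_rpkm.
#' @export
cress_fractions <- function(calls, cress_taxa) {
  is_cress <- calls$tax_id %in% cress_taxa
  grp <- list(novel = calls$class == "novel",
              high_confidence = calls$class == "high_confidence",
              overall = rep(TRUE, nrow(calls)))
  do.call(rbind, lapply(names(grp), function(g) {
    sel <- grp[[g]]
    data.frame(group = g,
               n_taxa = sum(sel),
               frac_taxa = if (any(sel)) mean(is_cress[sel]) else NA_real_,
               frac_rpkm = if (any(sel) && sum(calls$rpkm[sel]) > 0)
                 sum(calls$rpkm[sel & is_cress]) / sum(calls$rpkm[sel])
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
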