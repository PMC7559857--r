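#' @title Circular genome analyses: terminal repeats, species demarcation,
#'   in-silico PCR
#' @description CRESS-DNA-style genome procedures. An assembled contig of a
#'   circular genome typically carries a terminal direct repeat: its start
#'   is re-assembled at its end, so an exact prefix equal to a suffix of
#'   the contig is evidence of circularity, and trimming the repeated
#'   suffix recovers the circular genome. Species demarcation for
#'   circoviruses places two genomes in different species when their
#'   genome-wide nucleotide identity is below 75%.
#' @name genome_analysis
NULL

#' Detect circularity via an exact terminal direct repeat
#'
#' Finds the longest exact, non-self-overlapping prefix of the contig that
#' equals its suffix (overlap at most half the contig length). When the
#' overlap reaches \code{min_overlap}, the contig is called circular and
#' the repeated suffix trimmed; otherwise it is linear.
#'
#' @param contig a \code{labeled_seq} or character string; must be longer
#'   than \code{2 * min_overlap}.
#' @param min_overlap minimum repeat length in nucleotides (default 20).
#' @return list of class \code{circularity_call}: contig_id, is_circular,
#'   overlap_length, trimmed_length, trimmed_sequence.
#' @export
detect_circularity <- function(contig, min_overlap = 20L) {
  s <- as_sequence(contig)
  n <- nchar(s)
  if (n <= 2L * min_overlap) {
    stop("detect_circularity: contig length ", n,
         " not greater than 2 * min_overlap (", 2L * min_overlap, ")")
  }
  id <- if (inherits(contig, "labeled_seq")) contig$seq_id else NA_character_
  best <- 0L
  for (k in seq.int(n %/% 2L, min_overlap)) {
    if (substr(s, 1L, k) == substr(s, n - k + 1L, n)) { best <- k; break }
  }
  if (best >= min_overlap) {
    structure(list(contig_id = id, is_circular = TRUE, overlap_length = best,
                   trimmed_length = n - best,
                   trimmed_sequence = substr(s, 1L, n - best)),
              class = "circularity_call")
  } else {
    structure(list(contig_id = id, is_circular = FALSE, overlap_length = 0L,
                   trimmed_length = n, trimmed_sequence = s),
              class = "circularity_call")
  }
}

#' @export
print.circularity_call <- function(x, ...) {
  cat("circularity_call", x$contig_id, ":",
      if (x$is_circular) paste0("circular (", x$overlap_length,
                                " nt terminal repeat), trimmed to ",
                                x$trimmed_length, " nt")
      else "linear", "\n")
  invisible(x)
}

rotate_sequence <- function(s, offset) {
  n <- nchar(s)
  offset <- ((offset - 1L) %% n) + 1L
  if (offset == 1L) s else paste0(substr(s, offset, n), substr(s, 1L, offset - 1L))
}

#' Genome-wide pairwise nucleotide identity
#'
#' Global alignment identity (matches over alignment columns). For
#' circular genomes the rotation of \code{a} is anchored before the global
#' alignment: the best local alignment between the two sequences picks the
#' rotation that brings the anchored region into register
#' (\code{exhaustive = TRUE} instead scans every rotation, quadratic but
#' exact).
#'
#' @param a,b \code{labeled_seq} or character strings.
#' @param circular treat both sequences as circular genomes.
#' @param scoring an \code{\link{align_scoring}}.
#' @param exhaustive with \code{circular}, try all rotations of \code{a}.
#' @return percent identity in [0, 100].
#' @export
genome_identity <- function(a, b, circular = FALSE, scoring = align_scoring(),
                            exhaustive = FALSE) {
  sa <- as_sequence(a); sb <- as_sequence(b)
  if (!circular) return(global_align(sa, sb, scoring)$identity)
  if (exhaustive) {
    return(max(vapply(seq_len(nchar(sa)), function(off) {
      global_align(rotate_sequence(sa, off), sb, scoring)$identity
    }, numeric(1))))
  }
  anchor <- local_align(sa, sb, scoring)
  if (anchor$score <= 0) return(global_align(sa, sb, scoring)$identity)
  # rotate a so that the anchored region starts in register with b
  off <- ((anchor$q_start - anchor$s_start) %% nchar(sa)) + 1L
  global_align(rotate_sequence(sa, off), sb, scoring)$identity
}

#' Species-demarcation verdict from genome-wide identity
#'
#' Strict "<": identity below \code{demarcation_identity} (default 75%)
#' means a distinct (novel) species; at or above it, a variant of the
#' matched species.
#'
#' @param identity percent identity in [0, 100].
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{"novel_species"} or \code{"variant"}.
#' @export
demarcate <- function(identity, config = pipeline_config()) {
  stopifnot(identity >= 0, identity <= 100)
  ifelse(identity < config$demarcation_identity, "novel_species", "variant")
}

#' A PCR primer pair
#' @param name assay name.
#' @param forward,reverse primer sequences, 5'->3', A/C/G/T only.
#' @param max_amplicon maximum product length in nucleotides.
#' @export
primer_pair <- function(name, forward, reverse, max_amplicon = 200L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(nchar(forward) > 0, nchar(reverse) > 0)
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse)) {
    stop("primer_pair: primers must be over A/C/G/T")
  }
  structure(list(name = as.character(name), forward = forward,
                 reverse = reverse, max_amplicon = as.integer(max_amplicon)),
            class = "primer_pair")
}

#' Read a primers TSV (name, forward, reverse, max_amplicon; header required)
#' @param path path to the table.
#' @return list of \code{primer_pair}.
#' @export
read_primers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  need <- c("name", "forward", "reverse", "max_amplicon")
  if (!all(need %in% names(df))) {
    stop("primers format error: need columns ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    primer_pair(df$name[i], df$forward[i], df$reverse[i], df$max_amplicon[i])
  })
}

find_exact <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' In-silico PCR with exact primer matching
#'
#' Forward primer matched exactly on the plus strand; the reverse
#' complement of the reverse primer matched downstream within
#' \code{max_amplicon}. Amplicon length is measured from the forward
#' primer's 5' base to the reverse primer's 5' base inclusive (the
#' rightmost base of the reverse-complement match). Circular templates
#' wrap across the origin; products are reported once, by their start
#' position on the original coordinates.
#'
#' @param template a \code{labeled_seq} or character string.
#' @param primers a \code{\link{primer_pair}}.
#' @param circular template is a circular genome.
#' @return data.frame: start (forward 5' position), length. Zero rows when
#'   there is no product.
#' @export
insilico_pcr <- function(template, primers, circular = FALSE) {
  s <- as_sequence(template)
  n <- nchar(s)
  rv_rc <- revcomp(primers$reverse)
  search_s <- if (circular) paste0(s, substr(s, 1L, min(primers$max_amplicon, n))) else s
  fw_pos <- find_exact(primers$forward, search_s)
  fw_pos <- fw_pos[fw_pos <= n]                      # one start per origin position
  rv_pos <- find_exact(rv_rc, search_s)
  products <- data.frame(start = integer(), length = integer())
  for (f in fw_pos) {
    ends <- rv_pos + nchar(rv_rc) - 1L               # reverse primer 5' base
    len <- ends - f + 1L
    ok <- len >= nchar(primers$forward) + nchar(primers$reverse) &
      len <= primers$max_amplicon
    for (L in sort(len[ok])) {
      products <- rbind(products, data.frame(start = f, length = L))
    }
  }
  products <- unique(products)
  products <- products[order(products$start, products$length), , drop = FALSE]
  rownames(products) <- NULL
  products
}
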