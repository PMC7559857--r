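#' @title Pairwise nucleotide alignment (BLAST stand-in)
#' @description Local (Smith-Waterman semantics) and global
#'   (Needleman-Wunsch) alignment used as the search engine on synthetic
#'   databases, computed with Biostrings. Affine gaps: a gap of length L
#'   costs gap_open + L * gap_extend.
#' @name align
NULL

#' Alignment scoring parameters
#'
#' Defaults (match 2, mismatch -3, gap open 5, gap extend 2) are
#' megablast-like; gap costs are positive penalties.
#'
#' @param match positive match reward.
#' @param mismatch negative mismatch score.
#' @param gap_open,gap_extend positive affine gap costs.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

scoring_from_config <- function(config) {
  align_scoring(config$match, config$mismatch, config$gap_open, config$gap_extend)
}

subst_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

as_sequence <- function(x) {
  if (inherits(x, "labeled_seq")) x$sequence else as.character(x)
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman semantics: the empty alignment scores 0, so a pair with
#' no positive-scoring path returns score 0 with empty spans. Identity is
#' matches over aligned columns (gaps included); query coverage is the
#' aligned query span over the query length.
#'
#' @param query,subject character strings or \code{labeled_seq} objects.
#' @param scoring an \code{\link{align_scoring}}.
#' @return one-row data.frame: score, identity, query_coverage, q_start,
#'   q_end, s_start, s_end, align_length.
#' @export
local_align <- function(query, subject, scoring = align_scoring()) {
  q <- as_sequence(query); s <- as_sequence(subject)
  if (nchar(q) == 0L || nchar(s) == 0L) stop("local_align: empty sequence")
  aln <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                       substitutionMatrix = subst_matrix(scoring),
                                       gapOpening = scoring$gap_open,
                                       gapExtension = scoring$gap_extend)
  sc <- Biostrings::score(aln)
  cols <- Biostrings::nchar(aln)  # alignment columns, gaps included
  if (sc <= 0 || cols == 0L) {
    return(data.frame(score = 0, identity = 0, query_coverage = 0,
                      q_start = NA_integer_, q_end = NA_integer_,
                      s_start = NA_integer_, s_end = NA_integer_,
                      align_length = 0L))
  }
  qs <- Biostrings::start(Biostrings::pattern(aln))
  qe <- Biostrings::end(Biostrings::pattern(aln))
  data.frame(score = sc,
             identity = 100 * Biostrings::nmatch(aln) / cols,
             query_coverage = 100 * (qe - qs + 1) / nchar(q),
             q_start = qs, q_end = qe,
             s_start = Biostrings::start(Biostrings::subject(aln)),
             s_end = Biostrings::end(Biostrings::subject(aln)),
             align_length = cols)
}

# Vectorized local alignment of one query against many subjects (one C
# call); returns one row per subject. Rows with no positive-scoring path
# have score 0 and NA spans.
local_align_many <- function(query, subjects, scoring = align_scoring()) {
  q <- as_sequence(query)
  stopifnot(nchar(q) > 0L, length(subjects) > 0L)
  if (!inherits(subjects, "DNAStringSet")) {
    subjects <- Biostrings::DNAStringSet(subjects)
  }
  aln <- Biostrings::pairwiseAlignment(
    subjects, q, type = "local",
    substitutionMatrix = subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  sc <- Biostrings::score(aln)
  cols <- Biostrings::nchar(aln)  # alignment columns, gaps included
  qs <- Biostrings::start(Biostrings::subject(aln))
  qe <- Biostrings::end(Biostrings::subject(aln))
  out <- data.frame(
    score = ifelse(sc > 0, sc, 0),
    identity = ifelse(sc > 0 & cols > 0, 100 * Biostrings::nmatch(aln) / cols, 0),
    query_coverage = ifelse(sc > 0, 100 * (qe - qs + 1) / nchar(q), 0),
    q_start = ifelse(sc > 0, qs, NA_integer_),
    q_end = ifelse(sc > 0, qe, NA_integer_),
    s_start = ifelse(sc > 0, Biostrings::start(Biostrings::pattern(aln)), NA_integer_),
    s_end = ifelse(sc > 0, Biostrings::end(Biostrings::pattern(aln)), NA_integer_),
    align_length = ifelse(sc > 0, cols, 0L))
  out
}

#' Global alignment identity of two sequences
#'
#' Needleman-Wunsch with end gaps penalized; identity is matches over
#' alignment columns (gaps included) times 100.
#'
#' @param a,b character strings or \code{labeled_seq} objects.
#' @param scoring an \code{\link{align_scoring}}.
#' @return list(score, identity).
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  sa <- as_sequence(a); sb <- as_sequence(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("global_align: empty sequence")
  aln <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                       substitutionMatrix = subst_matrix(scoring),
                                       gapOpening = scoring$gap_open,
                                       gapExtension = scoring$gap_extend)
  cols <- Biostrings::nchar(aln)  # alignment columns, gaps included
  list(score = Biostrings::score(aln),
       identity = 100 * Biostrings::nmatch(aln) / cols)
}
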