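#' @title Mutation-simulation calibration of annotation drift
#' @description Emulates the model-sequence experiment: a short query drawn
#'   from a known genome is mutated at controlled rates, searched against a
#'   labeled database with the built-in local aligner, and the drift of the
#'   best hit away from the true taxon is quantified per rate. Misassigned
#'   hits are expected to show the diagnostic geometry of novel sequences:
#'   high pairwise identity over only a minor fraction of the query.
#' @name calibration
NULL

sequence_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  unique(substring(s, starts, starts + k - 1L))
}

#' Exact k-mer index over a sequence database
#'
#' Maps every k-mer occurring in the database to the indices of the
#' subjects containing it; used as a BLAST-like seeding prefilter by
#' \code{\link{search_database}} on desk-scale synthetic databases.
#'
#' @param db list of \code{labeled_seq}.
#' @param k word size (default 14).
#' @return an object of class \code{kmer_index}.
#' @export
kmer_index <- function(db, k = 14L) {
  env <- new.env(hash = TRUE, size = 2L * sum(vapply(db, function(s)
    nchar(s$sequence), 0L)))
  for (i in seq_along(db)) {
    for (kmer in sequence_kmers(db[[i]]$sequence, k)) {
      env[[kmer]] <- c(env[[kmer]], i)
    }
  }
  structure(list(env = env, k = as.integer(k), n_subjects = length(db)),
            class = "kmer_index")
}

index_candidates <- function(index, q) {
  qk <- sequence_kmers(q, index$k)
  hits <- unlist(mget(qk, envir = index$env, ifnotfound = list(NULL)),
                 use.names = FALSE)
  sort(unique(hits))
}

#' Rank database sequences against a query by local alignment
#'
#' Exhaustive by default (every subject is aligned); with a
#' \code{\link{kmer_index}} supplied, subjects sharing no exact k-mer with
#' the query are skipped.
#'
#' @param query a \code{labeled_seq} or character string.
#' @param db non-empty list of \code{labeled_seq}.
#' @param scoring an \code{\link{align_scoring}}.
#' @param top_n maximum number of results.
#' @param index optional \code{kmer_index} built over \code{db}.
#' @param .stringset optional prebuilt \code{DNAStringSet} of the database
#'   sequences (avoids re-conversion in tight replicate loops).
#' @return data.frame sorted by score descending (ties by subject_id):
#'   subject_id, subject_taxid, score, identity, query_coverage, q_start,
#'   q_end, s_start, s_end, align_length.
#' @export
search_database <- function(query, db, scoring = align_scoring(),
                            top_n = 25L, index = NULL, .stringset = NULL) {
  if (length(db) == 0L) stop("search_database: empty database")
  q <- as_sequence(query)
  idx <- seq_along(db)
  if (!is.null(index)) {
    stopifnot(inherits(index, "kmer_index"), index$n_subjects == length(db))
    idx <- index_candidates(index, q)
    if (length(idx) == 0L) return(empty_search_result())
  }
  ss <- if (is.null(.stringset)) {
    Biostrings::DNAStringSet(vapply(db, function(s) s$sequence, ""))
  } else .stringset
  res <- local_align_many(q, ss[idx], scoring)
  out <- cbind(data.frame(
    subject_id = vapply(db[idx], function(s) s$seq_id, ""),
    subject_taxid = vapply(db[idx], function(s) s$tax_id, 0L),
    stringsAsFactors = FALSE), res)
  out <- out[out$score > 0, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_search_result())
  out <- out[order(-out$score, out$subject_id), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

empty_search_result <- function() {
  data.frame(subject_id = character(), subject_taxid = integer(),
             score = numeric(), identity = numeric(),
             query_coverage = numeric(), q_start = integer(),
             q_end = integer(), s_start = integer(), s_end = integer(),
             align_length = integer(), stringsAsFactors = FALSE)
}

#' Are two taxa related at or below a rank?
#'
#' Related means both resolve to the same ancestor at \code{rank} (default
#' family). Either taxon failing to resolve at that rank counts as
#' unrelated, the conservative reading of cross-kingdom misassignment.
#' @param tree a \code{taxonomy}.
#' @param a,b tax_ids.
#' @param rank rank defining relatedness.
#' @return logical.
#' @export
taxa_related <- function(tree, a, b, rank = "family") {
  aa <- ancestor_at_rank(tree, a, rank)
  bb <- ancestor_at_rank(tree, b, rank)
  !is.na(aa) && !is.na(bb) && aa == bb
}

#' Calibration curve: annotation drift under controlled mutation
#'
#' For each mutation rate and replicate the source query is mutated
#' (\code{\link{mutate_sequence}}), searched against the database, and the
#' best hit recorded. A replicate is misassigned when the best-hit taxon
#' shares no ancestor with the true taxon at or below \code{related_rank}
#' (or when no hit is found at all). Per rate the curve reports the mean
#' best-hit identity and coverage (local alignment), the mean ungapped
#' identity of the mutated query against its source (forced to
#' 100*(1-rate) by the mutation operator and recomputed here as a check),
#' and the misassignment fraction; \code{borderline_flag} marks rates where
#' replicates split between correct and misassigned calls.
#'
#' @param seq source \code{labeled_seq}; its tax_id must be in \code{tree}.
#' @param db list of \code{labeled_seq} with taxa in \code{tree}.
#' @param tree a \code{taxonomy}.
#' @param rates numeric vector of mutation rates in [0, 1].
#' @param reps replicates per rate (>= 1).
#' @param rng_seed integer seed driving the whole experiment.
#' @param scoring an \code{\link{align_scoring}}.
#' @param related_rank rank defining a "related" (correct) assignment.
#' @return data.frame of class \code{calibration_curve}: rate, reps,
#'   mean_best_identity, mean_best_coverage, mean_source_identity,
#'   misassignment_fraction, borderline_flag; per-replicate detail in the
#'   \code{"replicates"} attribute.
#' @export
calibration_curve <- function(seq, db, tree, rates = c(0.1, 0.2, 0.25, 0.3, 0.4, 0.5),
                              reps = 30L, rng_seed = 1L,
                              scoring = align_scoring(),
                              related_rank = "family") {
  if (reps < 1L) stop("calibration_curve: reps must be >= 1")
  stopifnot(all(rates >= 0 & rates <= 1))
  if (!has_taxon(tree, seq$tax_id)) stop("calibration_curve: source taxon not in tree")
  db_ss <- Biostrings::DNAStringSet(vapply(db, function(s) s$sequence, ""))
  detail <- with_seed(rng_seed, {
    do.call(rbind, lapply(rates, function(rate) {
      do.call(rbind, lapply(seq_len(reps), function(rep) {
        mut <- mutate_sequence(seq, rate)
        res <- search_database(mut, db, scoring, top_n = 1L, .stringset = db_ss)
        if (nrow(res) == 0L) {
          data.frame(rate = rate, rep = rep, best_taxid = NA_integer_,
                     best_identity = NA_real_, best_coverage = NA_real_,
                     source_identity = hamming_identity(mut, seq),
                     misassigned = TRUE)
        } else {
          data.frame(rate = rate, rep = rep, best_taxid = res$subject_taxid[1],
                     best_identity = res$identity[1],
                     best_coverage = res$query_coverage[1],
                     source_identity = hamming_identity(mut, seq),
                     misassigned = !taxa_related(tree, seq$tax_id,
                                                 res$subject_taxid[1], related_rank))
        }
      }))
    }))
  })
  curve <- do.call(rbind, lapply(split(detail, detail$rate), function(d) {
    mf <- mean(d$misassigned)
    data.frame(rate = d$rate[1], reps = nrow(d),
               mean_best_identity = mean(d$best_identity, na.rm = TRUE),
               mean_best_coverage = mean(d$best_coverage, na.rm = TRUE),
               mean_source_identity = mean(d$source_identity),
               misassignment_fraction = mf,
               borderline_flag = mf > 0 && mf < 1)
  }))
  rownames(curve) <- NULL
  attr(curve, "replicates") <- detail
  class(curve) <- c("calibration_curve", class(curve))
  curve
}

#' Write a calibration curve to TSV
#' @param curve a \code{calibration_curve}.
#' @param path output path.
#' @export
write_calibration <- function(curve, path) {
  utils::write.table(as.data.frame(unclass(curve)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
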