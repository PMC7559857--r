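#' @title Taxon-labeled nucleotide sequences and FASTA I/O
#' @name sequences
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' A taxon-labeled nucleotide sequence
#'
#' @param seq_id sequence identifier.
#' @param tax_id taxon identifier (NA allowed for unlabeled contigs).
#' @param sequence nucleotide string over A/C/G/T (case-insensitive;
#'   ambiguity codes are rejected).
#' @export
labeled_sequence <- function(seq_id, tax_id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("labeled_sequence: empty sequence for ", seq_id)
  if (grepl("[^ACGT]", sequence)) {
    stop("labeled_sequence: non-ACGT character in ", seq_id,
         " (ambiguity codes are not accepted)")
  }
  structure(list(seq_id = as.character(seq_id),
                 tax_id = if (is.na(tax_id)) NA_integer_ else as.integer(tax_id),
                 sequence = sequence),
            class = "labeled_seq")
}

#' @export
print.labeled_seq <- function(x, ...) {
  cat("labeled_seq", x$seq_id, "tax", x$tax_id, "len", nchar(x$sequence), "\n")
  invisible(x)
}

#' Read a labeled FASTA database
#'
#' Header convention \code{>seq_id|tax_id}; a header without \code{|} gives
#' an NA taxon (plain contig FASTA).
#'
#' @param path FASTA path.
#' @return list of \code{labeled_seq}.
#' @export
read_seq_db <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    hdr <- strsplit(names(ss)[i], "\\s+")[[1]][1]
    parts <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    labeled_sequence(parts[1],
                     if (length(parts) >= 2L) as.integer(parts[2]) else NA_integer_,
                     as.character(ss[[i]]))
  })
}

#' Write labeled sequences as FASTA (\code{>seq_id|tax_id} headers)
#' @param db list of \code{labeled_seq}.
#' @param path output path.
#' @param extra optional character vector appended to each header
#'   (e.g. \code{"circular=true"}).
#' @export
write_seq_db <- function(db, path, extra = NULL) {
  ss <- Biostrings::DNAStringSet(vapply(db, function(s) s$sequence, ""))
  hdr <- vapply(db, function(s) {
    if (is.na(s$tax_id)) s$seq_id else paste0(s$seq_id, "|", s$tax_id)
  }, "")
  if (!is.null(extra)) hdr <- paste(hdr, extra)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param x character string over A/C/G/T.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random nucleotide sequence (uniform base model)
#' @param n length in nucleotides.
#' @return character string.
#' @export
random_sequence <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

#' Introduce an exact number of random point mutations
#'
#' Substitutes exactly \code{round(rate * length)} distinct positions,
#' chosen uniformly without replacement, each with a uniformly chosen
#' different base, so the Hamming distance to the input is forced to that
#' count and pairwise identity to the source is exactly
#' \code{100 * (1 - round(rate*L)/L)}. Deterministic given \code{rng_seed};
#' the caller's RNG state is preserved.
#'
#' @param seq a \code{labeled_seq} or character string.
#' @param rate mutation rate in [0, 1] (fraction of total length).
#' @param rng_seed optional integer seed; NULL draws from the current RNG.
#' @return same type as the input, mutated.
#' @export
mutate_sequence <- function(seq, rate, rng_seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop("mutate_sequence: rate must be a single number in [0, 1]")
  }
  s <- as_sequence(seq)
  n <- nchar(s)
  k <- round(rate * n)
  mut <- function() {
    if (k == 0L) return(s)
    bases <- strsplit(s, "")[[1]]
    pos <- sample.int(n, k)
    for (p in pos) {
      bases[p] <- sample(setdiff(DNA_BASES4, bases[p]), 1L)
    }
    paste(bases, collapse = "")
  }
  out <- if (is.null(rng_seed)) mut() else with_seed(rng_seed, mut())
  if (inherits(seq, "labeled_seq")) {
    labeled_sequence(seq$seq_id, seq$tax_id, out)
  } else out
}

#' Ungapped (position-wise) percent identity of equal-length strings
#' @param a,b character strings of equal length.
#' @export
hamming_identity <- function(a, b) {
  a <- as_sequence(a); b <- as_sequence(b)
  stopifnot(nchar(a) == nchar(b), nchar(a) > 0)
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  100 * sum(va == vb) / length(va)
}

# Run code under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
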