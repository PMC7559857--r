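# Independent oracles: hand-written dynamic programming, brute-force tree
# walks and quadrature, kept deliberately separate from the package's
# implementation paths.

# Affine-gap Smith-Waterman score by full DP (Gotoh); a gap of length L
# costs go + L * ge, matching the package's convention.
sw_score_oracle <- function(a, b, match = 2, mismatch = -3, go = 5, ge = 2) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (go + ge), E[i + 1, j] - ge)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (go + ge), F[i, j + 1] - ge)
      s <- if (va[i] == vb[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# Affine-gap Needleman-Wunsch score (end gaps penalized) by full DP.
nw_score_oracle <- function(a, b, match = 2, mismatch = -3, go = 5, ge = 2) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  H <- matrix(-Inf, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in seq_len(m)) { E[1, j + 1] <- -(go + j * ge); H[1, j + 1] <- E[1, j + 1] }
  for (i in seq_len(n)) { F[i + 1, 1] <- -(go + i * ge); H[i + 1, 1] <- F[i + 1, 1] }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (go + ge), E[i + 1, j] - ge)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (go + ge), F[i, j + 1] - ge)
      s <- if (va[i] == vb[j]) match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  H[n + 1, m + 1]
}

# LCA by brute force: intersect full root paths, take the deepest element.
lca_oracle <- function(tree, taxa) {
  paths <- lapply(unique(as.integer(taxa)), function(t) tax_path(tree, t))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# Random rooted taxonomy of n nodes (node i's parent drawn among 1..i-1).
random_taxonomy <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
    taxonomy(data.frame(tax_id = seq_len(n), parent_id = parent,
                        rank = c("root", rep("no_rank", n - 1L)),
                        name = paste0("node", seq_len(n))))
  })
}

# A pair of sequences for alignment oracle checks: sometimes related
# (mutated copy or shared fragment), sometimes independent.
random_seq_pair <- function(max_len = 80) {
  n <- sample(10:max_len, 1)
  a <- random_sequence(n)
  kind <- sample(3, 1)
  b <- switch(kind,
              random_sequence(sample(10:max_len, 1)),
              mutate_sequence(a, runif(1, 0.05, 0.4)),
              paste0(random_sequence(sample(0:10, 1)),
                     substr(a, 1, sample(5:n, 1)),
                     random_sequence(sample(0:10, 1))))
  list(a = a, b = b)
}

# Small fixed 7-node, 3-level taxonomy used across tests:
# root(1) -> family 2 -> genus 3,4 -> species 5,6 (under 3) and 7 (under 4)
fixture_tree <- function() {
  taxonomy(data.frame(
    tax_id = 1:7,
    parent_id = c(1L, 1L, 2L, 2L, 3L, 3L, 4L),
    rank = c("root", "family", "genus", "genus", "species", "species", "species"),
    name = c("root", "famA", "genA", "genB", "spA1", "spA2", "spB1")))
}

# Minimal valid hit-record rows for filter/cluster tests.
make_hits <- function(query_id, subject_id, pident = 95, qstart = 1,
                      qend = 100, query_length = 1000, evalue = 1e-20,
                      bitscore = 100, subject_taxid = 5L) {
  data.frame(query_id = query_id, subject_id = subject_id, pident = pident,
             align_length = qend - qstart + 1L, mismatch = 0L, gapopen = 0L,
             qstart = qstart, qend = qend, sstart = 1L,
             send = qend - qstart + 1L, evalue = evalue, bitscore = bitscore,
             query_length = query_length, subject_taxid = subject_taxid,
             stringsAsFactors = FALSE)
}
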