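test_that("circularity detection recovers constructed terminal repeats exactly", {
  withr::with_seed(91, {
    for (k in c(25L, 141L, 300L)) {
      G <- random_sequence(1500)
      contig <- paste0(G, substr(G, 1, k))
      cc <- detect_circularity(contig, min_overlap = 20)
      expect_true(cc$is_circular)
      expect_equal(cc$overlap_length, k)
      expect_equal(cc$trimmed_sequence, G)
      # round-trip: re-appending the overlap reproduces the input
      expect_equal(paste0(cc$trimmed_sequence,
                          substr(cc$trimmed_sequence, 1, cc$overlap_length)),
                   contig)
    }
  })
})

test_that("random sequences are called linear and short contigs rejected", {
  withr::with_seed(92, {
    calls <- replicate(25, detect_circularity(random_sequence(1000), 20)$is_circular)
    expect_true(mean(calls) <= 0.04)
  })
  expect_error(detect_circularity(random_sequence(40), 20), "not greater than")
})

test_that("genome identity: identical, reverse-complement, and DP oracle", {
  s <- random_sequence(200)
  expect_equal(genome_identity(s, s), 100)
  withr::with_seed(93, {
    # reverse complement of a random sequence is far from identical
    ids <- replicate(5, {
      g <- random_sequence(1000)
      genome_identity(g, revcomp(g))
    })
    expect_true(all(ids < 70))
    # symmetry
    for (i in 1:5) {
      p <- random_seq_pair(80)
      expect_equal(genome_identity(p$a, p$b), genome_identity(p$b, p$a),
                   tolerance = 1e-9)
    }
    # global scores against the independent DP oracle
    for (i in 1:25) {
      p <- random_seq_pair(80)
      expect_equal(global_align(p$a, p$b)$score, nw_score_oracle(p$a, p$b))
    }
  })
})

test_that("circular identity is rotation-invariant via the anchor seed", {
  withr::with_seed(94, {
    G <- random_sequence(600)
    Gm <- mutate_sequence(G, 0.1)
    for (off in c(1, 150, 400)) {
      rot <- paste0(substr(Gm, off, 600), substr(Gm, 1, off - 1))
      id <- genome_identity(rot, G, circular = TRUE)
      expect_gt(id, 85)
    }
    # linear comparison of a rotated genome is much worse
    rot <- paste0(substr(Gm, 300, 600), substr(Gm, 1, 299))
    expect_lt(genome_identity(rot, G, circular = FALSE),
              genome_identity(rot, G, circular = TRUE))
  })
})

test_that("demarcation verdicts follow the strict 75% rule", {
  cfg <- pipeline_config()
  expect_equal(demarcate(78, cfg), "variant")
  expect_equal(demarcate(74.9, cfg), "novel_species")
  expect_equal(demarcate(75.0, cfg), "variant")
})

test_that("in-silico PCR finds constructed products and obeys orientation", {
  pp <- primer_pair("test", "ATCCAGCCGTAGAAGTCGTC", "CGGAAAATCAAAGCGTGCAC",
                    max_amplicon = 200)
  withr::with_seed(95, {
    insert <- random_sequence(20)
    template <- paste0(random_sequence(100), pp$forward, insert,
                       revcomp(pp$reverse), random_sequence(100))
    prod <- insilico_pcr(template, pp)
    expect_equal(nrow(prod), 1L)
    expect_equal(prod$length, nchar(pp$forward) + 20L + nchar(pp$reverse))
    # no product on a template lacking the primers
    expect_equal(nrow(insilico_pcr(random_sequence(500), pp)), 0L)
    # reverse primer in the wrong orientation yields nothing
    bad <- paste0(random_sequence(50), pp$forward, insert, pp$reverse,
                  random_sequence(50))
    expect_equal(nrow(insilico_pcr(bad, pp)), 0L)
  })
})

test_that("in-silico PCR on circular templates is rotation-invariant and wraps", {
  pp <- primer_pair("t", "ACGTACGTACGTACGTACGT", "TTTTCCCCGGGGAAAATTTT",
                    max_amplicon = 250)
  withr::with_seed(96, {
    circle <- paste0(pp$forward, random_sequence(60), revcomp(pp$reverse),
                     random_sequence(400))
    base_len <- sort(insilico_pcr(circle, pp, circular = TRUE)$length)
    for (off in c(30, 250, 470)) {
      rot <- paste0(substr(circle, off, nchar(circle)), substr(circle, 1, off - 1))
      expect_equal(sort(insilico_pcr(rot, pp, circular = TRUE)$length), base_len)
    }
    # linear search misses the wrapped product for a rotation splitting the site
    rot <- paste0(substr(circle, 30, nchar(circle)), substr(circle, 1, 29))
    expect_equal(nrow(insilico_pcr(rot, pp, circular = FALSE)), 0L)
  })
})

test_that("planted multi-site templates match a brute-force scan oracle", {
  pp <- primer_pair("t", "GATTACAGATTACAGATTAC", "CTGAGTCCTGAGTCCTGAGT",
                    max_amplicon = 300)
  brute <- function(template) {
    n <- nchar(template)
    fw <- pp$forward; rv <- revcomp(pp$reverse)
    out <- integer(0)
    for (i in seq_len(n - nchar(fw) + 1)) {
      if (substr(template, i, i + nchar(fw) - 1) != fw) next
      for (j in seq_len(n - nchar(rv) + 1)) {
        e <- j + nchar(rv) - 1
        L <- e - i + 1
        if (L >= nchar(fw) + nchar(rv) && L <= pp$max_amplicon &&
            substr(template, j, e) == rv) out <- c(out, L)
      }
    }
    sort(out)
  }
  withr::with_seed(97, {
    for (i in 1:20) {
      k <- sample(0:3, 1)
      parts <- c()
      for (site in seq_len(k)) {
        parts <- c(parts, pp$forward, random_sequence(sample(5:200, 1)),
                   revcomp(pp$reverse), random_sequence(sample(20:120, 1)))
      }
      template <- paste0(random_sequence(80), paste(parts, collapse = ""),
                         random_sequence(80))
      expect_equal(sort(insilico_pcr(template, pp)$length), brute(template))
    }
  })
})
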