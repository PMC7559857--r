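write_hit_lines <- function(df, path) {
  write_hit_table(df, path)
}

test_that("hit tables round-trip through the 14-column dialect", {
  withr::with_seed(5, {
    n <- 100
    qlen <- sample(600:3000, n, replace = TRUE)
    qe <- pmin(qlen, sample(100:2000, n, replace = TRUE))
    qs <- pmax(1L, qe - sample(50:500, n, replace = TRUE))
    h <- data.frame(
      query_id = paste0("q", sample(20, n, TRUE)),
      subject_id = paste0("s", sample(30, n, TRUE)),
      pident = round(runif(n, 60, 100), 3),
      align_length = qe - qs + 1L, mismatch = sample(0:20, n, TRUE),
      gapopen = sample(0:3, n, TRUE), qstart = qs, qend = qe,
      sstart = sample(1000, n, TRUE), send = sample(1000, n, TRUE),
      evalue = 10^-runif(n, 3, 50), bitscore = round(runif(n, 40, 900), 2),
      query_length = qlen, subject_taxid = sample(1000:1100, n, TRUE),
      stringsAsFactors = FALSE)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_hit_table(h, f)
    h2 <- read_hit_table(f)
    attr(h2, "rejected") <- NULL
    expect_equal(h2, h, tolerance = 1e-12)
  })
})

test_that("invalid rows are rejected with line numbers, not fatal", {
  f <- withr::local_tempfile(fileext = ".tsv")
  good <- "q1\ts1\t95.5\t100\t2\t0\t1\t100\t1\t100\t1e-30\t180\t1000\t1001"
  bad_coord <- "q2\ts1\t95.5\t100\t2\t0\t50\t1200\t1\t100\t1e-30\t180\t1000\t1001"
  bad_num <- "q3\ts1\tniner\t100\t2\t0\t1\t100\t1\t100\t1e-30\t180\t1000\t1001"
  writeLines(c(good, bad_coord, bad_num), f)
  expect_message(h <- read_hit_table(f), "rejected 2 of 3")
  expect_equal(nrow(h), 1L)
  rej <- attr(h, "rejected")
  expect_equal(rej$line, c(2L, 3L))
  expect_match(rej$reason[1], "invariant")
  expect_match(rej$reason[2], "non-numeric")
})

test_that("12-column tables require sidecars for lengths and taxa", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t95.5\t100\t2\t0\t1\t100\t1\t100\t1e-30\t180", f)
  expect_error(read_hit_table(f), "sidecar")
  h <- read_hit_table(f,
                      query_lengths = data.frame(query_id = "q1", length = 1000L),
                      subject_taxa = data.frame(subject_id = "s1", tax_id = 1001L))
  expect_equal(h$query_length, 1000L)
  expect_equal(h$subject_taxid, 1001L)
})

test_that("query_coverage matches the span formula on random valid coordinates", {
  expect_equal(query_coverage(make_hits("q", "s", qstart = 1, qend = 100,
                                        query_length = 100)), 100)
  expect_equal(query_coverage(make_hits("q", "s", qstart = 21, qend = 80,
                                        query_length = 100)), 60)
  withr::with_seed(9, {
    for (i in 1:50) {
      L <- sample(100:5000, 1)
      qe <- sample(seq_len(L), 1); qs <- sample(seq_len(qe), 1)
      h <- make_hits("q", "s", qstart = qs, qend = qe, query_length = L)
      expect_equal(query_coverage(h), 100 * (qe - qs + 1) / L)
      expect_gt(query_coverage(h), 0)
      expect_lte(query_coverage(h), 100)
    }
  })
})

test_that("filter_hits applies e-value, top-N, exclusions and length rules", {
  cfg <- pipeline_config()
  # 30 passing hits for one query -> 25 survive
  h30 <- do.call(rbind, lapply(1:30, function(i)
    make_hits("q1", paste0("s", sprintf("%02d", i)), bitscore = 200 - i)))
  out <- filter_hits(h30, config = cfg)
  expect_equal(nrow(out), 25L)
  expect_equal(sort(out$bitscore, decreasing = TRUE)[1], 199)
  expect_equal(min(out$bitscore), 175)

  # e-value threshold is strict
  he <- rbind(make_hits("q1", "s1", evalue = 1e-4),
              make_hits("q1", "s2", evalue = 1e-6))
  expect_equal(filter_hits(he, config = cfg)$subject_id, "s2")

  # short queries dropped entirely
  hs <- make_hits("q1", "s1", query_length = 400L, qend = 100)
  expect_equal(nrow(filter_hits(hs, config = cfg)), 0L)

  # planted control subjects: survivors equal the set-difference oracle
  withr::with_seed(12, {
    h <- do.call(rbind, lapply(1:60, function(i)
      make_hits(paste0("q", sample(6, 1)), paste0("s", sample(10, 1)),
                bitscore = runif(1, 50, 100))))
    ctrl <- c("s3", "s7")
    out <- filter_hits(h, exclusion_set(control_subjects = ctrl), cfg)
    expect_false(any(out$subject_id %in% ctrl))
    # every per-query survivor set equals the oracle difference
    oracle <- h[!(h$subject_id %in% ctrl), ]
    expect_setequal(paste(out$query_id, out$subject_id, out$bitscore),
                    paste(oracle$query_id, oracle$subject_id, oracle$bitscore))
  })
})

test_that("filter_hits is idempotent and flags (not drops) broad taxa", {
  withr::with_seed(21, {
    h <- do.call(rbind, lapply(1:80, function(i)
      make_hits(paste0("q", sample(4, 1)), paste0("s", sample(40, 1)),
                bitscore = runif(1, 40, 300), evalue = 10^-runif(1, 3, 30),
                subject_taxid = sample(c(5L, 6L, 7L, 5000L), 1))))
    ex <- exclusion_set(control_subjects = "s5", broad_taxa = 5000L)
    once <- filter_hits(h, ex, pipeline_config(top_hits = 10))
    twice <- filter_hits(once, ex, pipeline_config(top_hits = 10))
    attr(once, "removed") <- attr(twice, "removed") <- NULL
    expect_equal(twice, once)
    expect_true(any(once$broad_flag))
    expect_true(all(once$broad_flag == (once$subject_taxid == 5000L)))
  })
})

test_that("control_exclusions only blacklists subjects with significant control hits", {
  ctrl <- rbind(make_hits("n1", "ctrl_a", evalue = 1e-30),
                make_hits("n1", "ref_x", evalue = 1e-3))
  ex <- control_exclusions(ctrl)
  expect_equal(ex$control_subjects, "ctrl_a")
})

test_that("cluster_by_taxon computes unweighted means and per-subject breakdown", {
  a2 <- data.frame(query_id = c("q1", "q2"), tax_id = 9L,
                   subject_id = c("sA", "sB"), pident = c(80, 90),
                   query_coverage = c(40, 60), stringsAsFactors = FALSE)
  cl <- cluster_by_taxon(a2)
  expect_equal(cl$n_contigs, 2L)
  expect_equal(cl$mean_identity, 85)
  expect_equal(cl$mean_query_coverage, 50)
  expect_equal(nrow(cl$per_subject[[1]]), 2L)

  # 200 synthetic assignments vs an independent group-by/mean oracle
  withr::with_seed(33, {
    asn <- data.frame(query_id = paste0("q", 1:200),
                      tax_id = sample(1000:1019, 200, TRUE),
                      subject_id = paste0("s", sample(5, 200, TRUE)),
                      pident = runif(200, 60, 100),
                      query_coverage = runif(200, 5, 100),
                      stringsAsFactors = FALSE)
    cl <- cluster_by_taxon(asn)
    oracle_id <- tapply(asn$pident, asn$tax_id, mean)
    oracle_cov <- tapply(asn$query_coverage, asn$tax_id, mean)
    oracle_n <- tapply(asn$query_id, asn$tax_id, length)
    expect_equal(cl$mean_identity, as.numeric(oracle_id[as.character(cl$tax_id)]))
    expect_equal(cl$mean_query_coverage, as.numeric(oracle_cov[as.character(cl$tax_id)]))
    expect_equal(cl$n_contigs, as.vector(as.integer(oracle_n[as.character(cl$tax_id)])))
    expect_equal(sum(cl$n_contigs), nrow(asn))
    # means bounded by member min/max
    for (i in seq_len(nrow(cl))) {
      vals <- asn$pident[asn$tax_id == cl$tax_id[i]]
      expect_gte(cl$mean_identity[i], min(vals))
      expect_lte(cl$mean_identity[i], max(vals))
    }
  })
})
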