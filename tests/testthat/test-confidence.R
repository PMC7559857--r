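fake_clusters <- function(cov, id = 90) {
  cl <- data.frame(tax_id = seq_along(cov) + 1000L, n_contigs = 1L,
                   mean_identity = rep_len(id, length(cov)),
                   mean_query_coverage = cov)
  cl$member_queries <- as.list(paste0("c", seq_along(cov)))
  cl$per_subject <- rep(list(NULL), length(cov))
  cl
}

test_that("classification boundary is strict at 60% coverage", {
  cfg <- pipeline_config()
  calls <- classify(fake_clusters(c(61, 60, 59.999, 60.001)), cfg)
  got <- calls$class[order(calls$tax_id)]
  expect_equal(got, c("high_confidence", "novel", "novel", "high_confidence"))
})

test_that("extreme boundaries collapse the partition; thresholding matches oracle", {
  withr::with_seed(41, {
    cov <- runif(120, 0, 100)
    cl <- fake_clusters(cov)
    expect_true(all(classify(cl, pipeline_config(coverage_boundary = 0))$class ==
                      "high_confidence"))
    expect_true(all(classify(cl, pipeline_config(coverage_boundary = 100))$class ==
                      "novel"))
    calls <- classify(cl, pipeline_config())
    expect_equal(sum(calls$class == "high_confidence"), sum(cov > 60))
    # invariance to input order
    perm <- sample(nrow(cl))
    calls2 <- classify(cl[perm, ], pipeline_config())
    expect_equal(calls2[order(calls2$tax_id), ], calls[order(calls$tax_id), ],
                 ignore_attr = TRUE)
  })
})

test_that("calls are sorted by descending rpkm and scatter_table echoes fields", {
  cl <- fake_clusters(c(80, 40, 95))
  rpkm <- stats::setNames(c(5, 20, 0), cl$tax_id)
  calls <- classify(cl, pipeline_config(), taxon_rpkm = rpkm)
  expect_equal(calls$rpkm, c(20, 5, 0))
  sc <- scatter_table(calls)
  expect_equal(nrow(sc), 3L)
  expect_equal(sc$x, calls$mean_query_coverage)
  expect_equal(sc$y, calls$mean_identity)
  expect_true(any(sc$size == 0))  # zero-abundance taxa retained
})

test_that("chi_square_2x2 matches the hand formula, chisq.test, and is transpose-invariant", {
  # identical row proportions -> independence
  eq <- chi_square_2x2(matrix(c(30, 70, 60, 140), 2, byrow = TRUE))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  tab <- matrix(c(30, 70, 10, 90), 2, byrow = TRUE)
  r <- chi_square_2x2(tab)
  # hand computation: E from margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - E)^2 / E))
  expect_equal(r$statistic, unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  expect_equal(r$p_value, unname(stats::chisq.test(tab, correct = FALSE)$p.value))
  rt <- chi_square_2x2(t(tab))
  expect_equal(rt$statistic, r$statistic)
  # Yates option agrees with chisq.test default
  expect_equal(chi_square_2x2(tab, correct = TRUE)$statistic,
               unname(stats::chisq.test(tab, correct = TRUE)$statistic))
  expect_error(chi_square_2x2(matrix(c(5, 5, 0, 0), 2)), "degenerate")
})

test_that("chi-square p-values match quadrature of the df-1 density", {
  withr::with_seed(52, {
    for (i in 1:60) {
      tab <- matrix(rpois(4, 40) + 1, 2)
      r <- chi_square_2x2(tab)
      if (r$statistic == 0) next
      quad <- stats::integrate(function(x) stats::dchisq(x, df = 1),
                               lower = r$statistic, upper = Inf,
                               rel.tol = 1e-12)$value
      expect_equal(r$p_value, quad, tolerance = 1e-8)
    }
  })
})

test_that("cress_enrichment builds the right table and detects planted enrichment", {
  calls <- classify(fake_clusters(c(80, 85, 30, 20)), pipeline_config())
  # all taxa CRESS -> zero margin
  expect_error(cress_enrichment(calls, calls$tax_id), "degenerate")

  # planted effect (0.8 among novel vs 0.3 among high-confidence, n = 200)
  withr::with_seed(63, {
    sig <- logical(40)
    for (i in seq_along(sig)) {
      n_nov <- 100; n_hc <- 100
      cl <- fake_clusters(c(runif(n_nov, 5, 55), runif(n_hc, 65, 100)))
      cress <- cl$tax_id[c(which(rbinom(n_nov, 1, 0.8) == 1),
                           n_nov + which(rbinom(n_hc, 1, 0.3) == 1))]
      er <- cress_enrichment(classify(cl, pipeline_config()), cress)
      sig[i] <- er$p_value < 0.05 &&
        (er$table["novel", "cress"] / sum(er$table["novel", ])) >
        (er$table["high_confidence", "cress"] / sum(er$table["high_confidence", ]))
    }
    expect_gte(mean(sig), 0.95)
  })

  # equal planted fractions: statistic behaves like a df-1 chi-square (mean ~ 1)
  withr::with_seed(64, {
    stats_null <- replicate(150, {
      cl <- fake_clusters(c(runif(100, 5, 55), runif(100, 65, 100)))
      cress <- cl$tax_id[rbinom(200, 1, 0.5) == 1]
      cress_enrichment(classify(cl, pipeline_config()), cress)$statistic
    })
    expect_lt(abs(mean(stats_null) - 1), 0.35)
  })
})

test_that("cress_fractions emits taxon- and abundance-weighted summaries", {
  cl <- fake_clusters(c(80, 30, 20, 90))
  calls <- classify(cl, pipeline_config(),
                    taxon_rpkm = stats::setNames(c(1, 3, 1, 5), cl$tax_id))
  fr <- cress_fractions(calls, cress_taxa = cl$tax_id[c(2, 3)])
  expect_equal(fr$frac_taxa[fr$group == "novel"], 1)
  expect_equal(fr$frac_taxa[fr$group == "high_confidence"], 0)
  expect_equal(fr$frac_taxa[fr$group == "overall"], 0.5)
  expect_equal(fr$frac_rpkm[fr$group == "overall"], 4 / 10)
})
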