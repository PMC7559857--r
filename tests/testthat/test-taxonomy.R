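test_that("taxonomy TSV round-trips and validates structure", {
  tree <- fixture_tree()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tree, f)
  tree2 <- read_taxonomy(f)
  expect_equal(tree2$nodes, tree$nodes)
  expect_equal(tree2$root, 1L)

  # minimal 3-node file
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tax_id\tparent_id\trank\tname",
               "1\t1\troot\troot", "2\t1\tspecies\ta", "3\t1\tspecies\tb"), f3)
  t3 <- read_taxonomy(f3)
  expect_equal(nrow(t3$nodes), 3L)
  expect_equal(t3$root, 1L)

  # broken parent reference
  fb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tax_id\tparent_id\trank\tname",
               "1\t1\troot\troot", "2\t9\tspecies\ta"), fb)
  expect_error(read_taxonomy(fb), "structure error")

  # duplicate id, cycle
  expect_error(taxonomy(data.frame(tax_id = c(1L, 2L, 2L),
                                   parent_id = c(1L, 1L, 1L),
                                   rank = "no_rank", name = "x")),
               "duplicate")
  expect_error(taxonomy(data.frame(tax_id = 1:3,
                                   parent_id = c(1L, 3L, 2L),
                                   rank = c("root", "no_rank", "no_rank"),
                                   name = "x")),
               "cycle|root")
})

test_that("node depths equal explicit parent-walk on a 3-level fixture", {
  tree <- fixture_tree()
  walk_depth <- function(id) {
    d <- 0L
    while (id != tree$root) { id <- tree$parent[[as.character(id)]]; d <- d + 1L }
    d
  }
  for (id in tree$nodes$tax_id) {
    expect_equal(tree$depth[[as.character(id)]], walk_depth(id))
  }
  expect_true(all(vapply(c(5L, 6L, 7L), walk_depth, 1L) == 3L))
})

test_that("lca handles singleton, siblings, and matches brute force on random trees", {
  tree <- fixture_tree()
  expect_equal(lca(tree, 5L), 5L)
  expect_equal(lca(tree, c(5L, 6L)), 3L)   # siblings -> genus
  expect_equal(lca(tree, c(5L, 7L)), 2L)   # across genera -> family
  expect_error(lca(tree, integer(0)), "empty")
  expect_error(lca(tree, 99L), "unknown")

  tree50 <- random_taxonomy(50, seed = 101)
  withr::with_seed(202, {
    for (i in 1:40) {
      taxa <- sample(tree50$nodes$tax_id, 5)
      expect_equal(lca(tree50, taxa), lca_oracle(tree50, taxa))
    }
  })
})

test_that("lca is idempotent, order-invariant, and an ancestor of every input", {
  tree <- random_taxonomy(50, seed = 7)
  withr::with_seed(8, {
    for (i in 1:20) {
      taxa <- sample(tree$nodes$tax_id, sample(2:6, 1))
      anc <- lca(tree, taxa)
      expect_equal(lca(tree, sample(taxa)), anc)
      expect_equal(lca(tree, anc), anc)
      for (t in taxa) expect_true(anc %in% tax_path(tree, t))
    }
  })
})

test_that("assign_taxon best-hit and LCA modes behave per the score window", {
  tree <- fixture_tree()
  cfg <- pipeline_config()
  one <- make_hits("q1", "s1", bitscore = 50, subject_taxid = 5L)
  expect_equal(assign_taxon(one, tree, "best_hit", cfg), 5L)
  expect_equal(assign_taxon(one, tree, "lca", cfg), 5L)
  expect_true(is.na(assign_taxon(one[0, ], tree, "best_hit", cfg)))

  # equal-bitscore sibling species collapse to their genus under LCA
  sib <- rbind(make_hits("q1", "s1", bitscore = 50, subject_taxid = 5L),
               make_hits("q1", "s2", bitscore = 50, subject_taxid = 6L))
  expect_equal(assign_taxon(sib, tree, "best_hit", cfg), 5L) # tie -> lowest tax_id
  expect_equal(assign_taxon(sib, tree, "lca", cfg), 3L)

  # staggered bitscores against a composed filter-then-LCA oracle
  withr::with_seed(31, {
    for (i in 1:15) {
      n <- 10
      taxa <- sample(c(5L, 6L, 7L), n, replace = TRUE)
      bits <- sort(runif(n, 50, 100), decreasing = TRUE)
      h <- do.call(rbind, lapply(seq_len(n), function(j)
        make_hits("q", paste0("s", j), bitscore = bits[j],
                  subject_taxid = taxa[j])))
      keep <- h$bitscore >= 0.9 * max(h$bitscore)
      expect_equal(assign_taxon(h, tree, "lca", cfg),
                   lca_oracle(tree, h$subject_taxid[keep]))
    }
  })

  # window 0 equals best hit when the top bitscore is unique
  cfg0 <- pipeline_config(lca_score_window = 0)
  h <- rbind(make_hits("q", "s1", bitscore = 90, subject_taxid = 7L),
             make_hits("q", "s2", bitscore = 80, subject_taxid = 5L))
  expect_equal(assign_taxon(h, tree, "lca", cfg0),
               assign_taxon(h, tree, "best_hit", cfg0))
})

test_that("host map resolves labels and defaults to unassigned", {
  hm <- host_map(c(`5` = "mosquito", `6` = "bat"))
  expect_equal(host_group(hm, c(5L, 6L, 7L)), c("mosquito", "bat", "unassigned"))
  expect_error(host_map(c(`5` = "dragon")), "unknown host group")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_host_map(hm, f)
  expect_equal(host_group(read_host_map(f), 5L), "mosquito")
})

test_that("config files parse with defaults and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# thresholds", "evalue_max = 1e-4", "top_hits = 10",
               "coverage_boundary = 50"), f)
  cfg <- read_config(f)
  expect_equal(cfg$evalue_max, 1e-4)
  expect_equal(cfg$top_hits, 10L)
  expect_equal(cfg$coverage_boundary, 50)
  expect_equal(cfg$min_contig_len, 500L)  # untouched default
  fb <- withr::local_tempfile(fileext = ".cfg")
  writeLines("not_a_key = 3", fb)
  expect_error(read_config(fb), "unknown config key")
})
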