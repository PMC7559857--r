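test_that("infeasible designs are rejected", {
  expect_error(simulation_design(
    n_pools = 2L, taxa_per_pool = c(4L, 4L),
    shared_pairs = data.frame(pool_a = 1L, pool_b = 2L, n_shared = 6L)),
    "design error")
})

test_that("reference db is deterministic, complete, and base-balanced", {
  design <- small_design()
  tax <- simulate_taxonomy(10, 10, n_unrelated = 4, n_broad = 1)
  db1 <- simulate_reference_db(design, tax$species)
  db2 <- simulate_reference_db(design, tax$species)
  expect_equal(length(db1), nrow(tax$species))
  expect_identical(vapply(db1, `[[`, "", "sequence"),
                   vapply(db2, `[[`, "", "sequence"))
  expect_setequal(vapply(db1, `[[`, 0L, "tax_id"), tax$species$tax_id)
  gc <- vapply(db1, function(s) {
    b <- strsplit(s$sequence, "")[[1]]
    mean(b %in% c("G", "C"))
  }, 0)
  # uniform base model: GC within binomial bounds of 0.5
  expect_true(all(gc > 0.35 & gc < 0.65))
  lens <- vapply(db1, function(s) nchar(s$sequence), 0L)
  expect_true(all(lens >= design$genome_len_range[1] &
                    lens <= design$genome_len_range[2]))
})

test_that("simulated study recovers planted structure through the pipeline", {
  sim <- get_small_sim()
  pools <- get_small_pools()
  # per-pool taxon sets recovered exactly
  for (p in sim$pool_names) {
    expect_identical(as.integer(sort(unique(pools[[p]]$calls$tax_id))),
                     as.integer(sim$truth$pool_taxa[[p]]))
  }
  # planted shared-taxa count recovered
  sr <- signature_taxa(pools[[1]], pools[[2]], include_broad = TRUE)
  expect_equal(sr$n_shared, 3L)
  expect_setequal(sr$shared_taxa, sim$truth$shared_sets[[1]])
  # contaminant queries are fully excluded by the control-derived rule
  runs <- attr(pools, "runs")
  contam_ids <- sim$truth$contigs$contig_id[sim$truth$contigs$contaminant]
  for (p in sim$pool_names) {
    expect_false(any(runs[[p]]$assigned$query_id %in% contam_ids))
  }
})

test_that("planted classes match realized coverage (generator self-audit holds)", {
  sim <- get_small_sim()
  pools <- get_small_pools()
  for (p in sim$pool_names) {
    calls <- pools[[p]]$calls
    tr <- sim$truth$contigs[sim$truth$contigs$sample_id == p &
                              !sim$truth$contigs$contaminant, ]
    planted <- unique(tr[, c("tax_id", "class")])
    m <- merge(calls, planted, by = "tax_id")
    expect_equal(m$class.x, m$class.y)
  }
})

test_that("circular contigs carry their exact planted terminal repeat", {
  sim <- get_small_sim()
  tr <- sim$truth$contigs[sim$truth$contigs$circular, ]
  expect_equal(nrow(tr), 2L)
  for (i in seq_len(nrow(tr))) {
    ctg <- sim$contigs[[tr$sample_id[i]]][[tr$contig_id[i]]]
    cc <- detect_circularity(ctg, min_overlap = 20)
    expect_true(cc$is_circular)
    expect_equal(cc$overlap_length, tr$overlap_length[i])
  }
  # non-circular contigs stay linear
  lin <- sim$truth$contigs[!sim$truth$contigs$circular, ][1:5, ]
  for (i in seq_len(nrow(lin))) {
    ctg <- sim$contigs[[lin$sample_id[i]]][[lin$contig_id[i]]]
    expect_false(detect_circularity(ctg, min_overlap = 20)$is_circular)
  }
})

test_that("identical seeds give identical simulations; written tree is stable", {
  d <- simulation_design(
    n_pools = 2L, taxa_per_pool = c(5L, 5L),
    shared_pairs = data.frame(pool_a = 1L, pool_b = 2L, n_shared = 2L),
    n_circular_per_pool = 0L, n_contaminants = 1L, n_broad_taxa = 0L,
    genome_len_range = c(1200L, 1500L), rng_seed = 31)
  s1 <- suppressMessages(simulate_pools(d))
  s2 <- suppressMessages(simulate_pools(d))
  expect_identical(lapply(s1$contigs, function(x) lapply(x, `[[`, "sequence")),
                   lapply(s2$contigs, function(x) lapply(x, `[[`, "sequence")))
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$counts, s2$counts)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("written simulation files load back through the package readers", {
  sim <- get_small_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  tree <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tree$nodes, sim$tree$nodes)
  hm <- read_host_map(file.path(dir, "host_map.tsv"))
  expect_equal(host_group(hm, sim$species$tax_id[1]),
               sim$species$host_group[1])
  pool <- sim$pool_names[1]
  h <- read_hit_table(file.path(dir, paste0(pool, "_hits.tsv")))
  expect_equal(nrow(h), nrow(sim$hits[[pool]]))
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(nrow(counts), nrow(sim$counts))
  db <- read_seq_db(file.path(dir, "reference_db.fasta"))
  expect_equal(length(db), length(sim$db))
  expect_equal(db[[1]]$tax_id, sim$db[[1]]$tax_id)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
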