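#!/usr/bin/env Rscript
# Stage 3 — goodness-of-assignment analysis: the two-dimensional scatter
# (query coverage x pairwise identity, bubble size = RPKM) per pool, and
# the CRESS-DNA enrichment test among low-coverage ("novel") hits.
#
# Writes results/confidence/.

library(viromecore)

pools <- readRDS("results/annotate/pools.rds")
truth <- jsonlite::read_json("data/synthetic_study/ground_truth.json",
                             simplifyVector = TRUE)
out_dir <- "results/confidence"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (pool in names(pools)) {
  rep <- run_report(pools[[pool]]$calls,
                    out_dir = file.path(out_dir, pool))
  cat(sprintf("%s: %d taxa (%d high-confidence, %d novel)\n", pool,
              rep$summary$n_taxa, rep$summary$n_high_confidence,
              rep$summary$n_novel))
}

# union of calls (one row per taxon, broad categories dropped)
all_calls <- do.call(rbind, lapply(pools, function(p) p$calls))
all_calls <- all_calls[!duplicated(all_calls$tax_id) & !all_calls$broad_flag, ]
cress <- truth$taxa$tax_id[truth$taxa$cress]
er <- cress_enrichment(all_calls, cress)
fr <- cress_fractions(all_calls, cress)
print(er)
print(fr)
jsonlite::write_json(
  list(table = er$table, statistic = er$statistic, df = er$df,
       p_value = er$p_value),
  file.path(out_dir, "cress_enrichment.json"),
  auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
write.table(fr, file.path(out_dir, "cress_fractions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
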