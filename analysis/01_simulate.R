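#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic four-pool mosquito virome study.
#
# The default design emulates a two-ecosystem field study: two pools per
# ecosystem, 8 taxa shared within the first ecosystem, 4 within the second
# and 1 across, ~45% of taxa planted as "novel" (conserved island + random
# flanks, so hits cover <60% of the query), CRESS-DNA viruses enriched in
# the novel class (0.65 vs 0.35), one circular genome per pool assembled
# with a 141-nt terminal repeat, and control-phage contaminants planted in
# both the pools and the no-template control.
#
# Writes data/synthetic_study/ (FASTA, hit tables, counts, taxonomy, host
# map, ground truth JSON).

library(viromecore)

seed <- 20260926L
out_dir <- "data/synthetic_study"

design <- simulation_design(rng_seed = seed)
sim <- simulate_pools(design)
write_simulation(sim, out_dir)

cat("pools:", paste(sim$pool_names, collapse = ", "), "\n")
cat("contigs per pool:", paste(vapply(sim$contigs, length, 0L), collapse = ", "), "\n")
cat("reference genomes:", length(sim$db), "\n")
cat("planted union taxa:", length(unique(unlist(sim$truth$pool_taxa))), "\n")
cat("written to", out_dir, "\n")
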