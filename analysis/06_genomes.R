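#!/usr/bin/env Rscript
# Stage 6 — genome-level procedures on the simulated circular contigs:
# terminal-repeat circularity detection and trimming, genome-wide identity
# with the <75% circovirus species-demarcation rule, and in-silico PCR
# with the published assay primer pairs on synthetic templates.
#
# Writes results/genomes/.

library(viromecore)

in_dir <- "data/synthetic_study"
out_dir <- "results/genomes"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
truth <- jsonlite::read_json(file.path(in_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
tc <- truth$contigs

calls <- list(); trimmed <- list()
for (pool in unique(tc$sample_id)) {
  contigs <- read_seq_db(file.path(in_dir, paste0(pool, "_contigs.fasta")))
  for (ctg in contigs) {
    cc <- detect_circularity(ctg, min_overlap = 20)
    calls[[ctg$seq_id]] <- data.frame(
      contig_id = ctg$seq_id, is_circular = cc$is_circular,
      overlap_length = cc$overlap_length, trimmed_length = cc$trimmed_length)
    if (cc$is_circular) {
      trimmed[[ctg$seq_id]] <- labeled_sequence(ctg$seq_id, ctg$tax_id,
                                                cc$trimmed_sequence)
    }
  }
}
calls <- do.call(rbind, calls)
write.table(calls, file.path(out_dir, "circularity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
if (length(trimmed)) {
  write_seq_db(trimmed, file.path(out_dir, "circular_trimmed.fasta"),
               extra = "circular=true")
}
planted <- tc$contig_id[tc$circular]
cat(sprintf("circular: %d detected, %d planted, overlaps %s nt\n",
            sum(calls$is_circular), length(planted),
            paste(unique(calls$overlap_length[calls$is_circular]),
                  collapse = "/")))

# species demarcation: each trimmed circular genome against its reference
db <- read_seq_db(file.path(in_dir, "reference_db.fasta"))
names(db) <- vapply(db, `[[`, "", "seq_id")
dem <- do.call(rbind, lapply(trimmed, function(g) {
  ref <- db[[paste0("ref_", g$tax_id)]]
  id <- genome_identity(g, ref$sequence, circular = TRUE)
  data.frame(contig_id = g$seq_id, reference = ref$seq_id,
             identity = id, verdict = demarcate(id))
}))
write.table(dem, file.path(out_dir, "demarcation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(dem, digits = 4)

# in-silico PCR: the published assay primers on synthetic templates with
# one planted product site each (132 nt BatCV, 160 nt CyCV design lengths)
primers <- read_primers(system.file("extdata", "primers.tsv",
                                    package = "viromecore"))
set.seed(20260926L)
pcr <- do.call(rbind, lapply(primers, function(pp) {
  planted <- if (pp$name == "BatCV") 132L else 160L
  gap <- planted - nchar(pp$forward) - nchar(pp$reverse)
  template <- paste0(random_sequence(400), pp$forward, random_sequence(gap),
                     revcomp(pp$reverse), random_sequence(400))
  prod <- insilico_pcr(template, pp, circular = TRUE)
  data.frame(assay = pp$name, planted_length = planted,
             n_products = nrow(prod), product_length = prod$length[1])
}))
write.table(pcr, file.path(out_dir, "insilico_pcr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(pcr)
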