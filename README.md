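# viromecore

Annotation-confidence analysis for mosquito virome metagenomics.

## The problem

Viral metagenomes from field-collected mosquito pools are rich in
sequences with no close database relative. Homology-based annotation of
assembled contigs then splits into two very different situations that a
plain "best BLAST hit" table hides: hits where the alignment spans the
contig (a credible relative of a known virus) and hits where a short
conserved stretch — often a capsid or replicase fragment of a CRESS-DNA
virus — aligns with high identity while the rest of the contig matches
nothing. `viromecore` implements the full workflow for separating these
two regimes and for the downstream comparative and genome-level analyses:

* BLAST outfmt-6-style hit ingestion, e-value/top-N filtering, exclusion
  of control/vector/plasmid hits, best-hit or lowest-common-ancestor
  (LCA) taxon assignment, and clustering by NCBI taxonomy ID;
* RPKM abundance per contig and per taxon
  (reads / ((length/1000) × (total mapped/10⁶)), taxon = mean of members);
* the **goodness-of-assignment** classification: per taxon cluster, mean
  % query coverage (x) versus mean % pairwise identity (y), with a strict
  boundary at coverage > 60% separating the `high_confidence` core virome
  from largely `novel` sequences, and a Pearson chi-square (df = 1) test
  of CRESS-DNA enrichment among the novel class;
* a mutation-drift **calibration**: a 100-nt model sequence mutated at
  rates 10–50% and re-searched, quantifying where annotation becomes
  taxonomically unrelated (misassigned hits show high identity at low
  query coverage — the same geometry the classifier keys on);
* cross-pool **comparison**: species-level richness and singletons,
  ecosystem-signature (shared) taxa per pool pair, host-group summaries;
* **genome analyses** for circular CRESS-DNA-like genomes: terminal
  direct-repeat circularity detection and trimming, genome-wide identity
  with the <75% circovirus species-demarcation rule, and in-silico PCR;
* a ground-truthed **synthetic study generator** (four pools, planted
  shared taxa, divergence classes, circular contigs, no-template-control
  contaminants) so every stage runs and is validated without any external
  database.

## Worked example

```r
library(viromecore)

# A contig assembled from a circular genome carries its start re-assembled
# at its end; detect, measure and trim the terminal repeat:
set.seed(42)
genome <- random_sequence(2000)
contig <- paste0(genome, substr(genome, 1, 141))
cc <- detect_circularity(contig, min_overlap = 20)
cc
#> circularity_call NA : circular (141 nt terminal repeat), trimmed to 2000 nt

# Species demarcation for circoviruses (strict < 75%): a genome sharing
# 78% genome-wide identity with its closest relative is a variant of that
# species, not a new one:
demarcate(78)
#> [1] "variant"

# Is the novel (low-coverage) class enriched in CRESS-DNA viruses?
tab <- matrix(c(24, 13, 16, 32), 2, byrow = TRUE,
              dimnames = list(c("novel", "high_confidence"),
                              c("cress", "non_cress")))
chi_square_2x2(tab)
#> 2x2 chi-square: statistic = 8.338 , df = 1, p = 0.003882
#>                 cress non_cress
#> novel              24        13
#> high_confidence    16        32
```

The counts in that table are what the full synthetic study produces (see
below): 24/37 novel taxa are CRESS (64.9%) versus 16/48 (33.3%) among
high-confidence taxa.

## The analysis workflow

The `analysis/` scripts run the whole study end to end, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic four-pool study -> data/synthetic_study/
Rscript analysis/02_annotate.R    # filter/assign/cluster/RPKM/classify per pool
Rscript analysis/03_confidence.R  # scatter tables + CRESS enrichment test
Rscript analysis/04_compare.R     # richness, shared taxa, host groups
Rscript analysis/05_calibrate.R   # mutation-drift calibration curve
Rscript analysis/06_genomes.R     # circularity, demarcation, in-silico PCR
```

Stage 2 prints, for each pool, whether the annotation recovered exactly
the planted taxon set (it does), stage 4 reports the planted 8/4/1 shared
taxa between pool pairs, and stage 5 prints the calibration curve —
assignments stay correct through 30% mutation and drift to unrelated taxa
at 40–50%, with misassigned hits covering a median 16% of the query
versus 97% for correct ones.

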