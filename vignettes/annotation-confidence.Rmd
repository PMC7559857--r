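---
title: "Annotation confidence in mosquito virome metagenomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation confidence in mosquito virome metagenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromecore)
```

## The problem

Shotgun metagenomes of field-collected mosquito pools are dominated by
viral sequences with no close database relative. When an assembled contig
is annotated by homology search (BLASTN-style), the best hit may be a
genuine relative of the underlying virus — or a short, conserved stretch
of an otherwise unrelated genome. Taking hit tables at face value
therefore inflates both richness and host-range claims. This package
implements a workflow that separates a *core virome* of well-supported
assignments from largely novel sequences, using only two quantities that
every tabular hit already carries:

* **percent query coverage** — the fraction of the contig spanned by the
  alignment, $100 \cdot (q_{end} - q_{start} + 1) / L_q$, and
* **percent pairwise identity** — matching positions over aligned columns.

Plotted against each other per taxon, biologically implausible hits
separate cleanly from plausible ones: spurious assignments align with high
identity over only a minor fraction of the query. A single boundary on
mean query coverage (default 60%, strict `>`), classifies each taxon
cluster as `high_confidence` or `novel`. The strictness matters: it makes
the verbal descriptions ">60%" and "0–60%" a true partition, with 60.0
falling in the novel class.

## The pipeline

For each pool the stages are:

1. **Filter** (`filter_hits`): e-value ≤ `evalue_max` (default $10^{-5}$);
   at most `top_hits` (default 25) hits per query, ranked by bitscore with
   deterministic subject-id tie-breaks; hits to subjects detected in the
   no-template control (see `control_exclusions`), to vector or plasmid
   sequences, removed; queries shorter than `min_contig_len` (default
   500 nt) dropped. Hits to broad categories (uncultured/unclassified
   bins) are *flagged*, not dropped: richness summaries exclude them but
   the confidence analysis keeps them. The whole filter is idempotent.
   BLAST tabular output does not state whether "first N hits" orders by
   e-value or bitscore; we fix bitscore order, which is BLAST's default
   output order.
2. **Assign** (`assign_taxa`): either the best hit's taxon (ties broken by
   bitscore, then e-value, then lowest tax_id, for reproducibility), or a
   lowest-common-ancestor assignment over all hits scoring at least
   $(1 - w)$ times the top bitscore. The window $w$ (default 0.10) is a
   single-tunable reduction of the MEGAN "top percent" idea; with $w = 0$
   and a unique top hit the two modes coincide.
3. **Cluster** (`cluster_by_taxon`): contigs assigned to the same NCBI
   taxonomy ID form one cluster carrying unweighted means of identity and
   query coverage, plus a per-subject breakdown when members hit
   different database sequences of the same taxon. Coverage is the
   single-HSP span over the query length; since clustering operates on
   best hits only, HSP merging is not applied (a multi-HSP union would
   only matter for queries whose best subject is hit in several pieces,
   and is deliberately out of the default path).
   The wording "% subject coverage" appears once in the field literature
   describing this step while every other use (axes, thresholds) is query
   coverage; we use query coverage throughout.
4. **Quantify** (`rpkm_contig`, `rpkm_taxon`): RPKM per contig,
   $r = \frac{\text{reads}}{(L/1000)(T/10^6)}$, with $T$ the per-sample
   total of reads *mapped to contigs* (the natural denominator when only
   mapping summaries are available; raw-read totals would scale all
   values by a common factor). Taxon abundance is the unweighted mean of
   member-contig RPKM.
5. **Classify** (`classify`) and test (`cress_enrichment`): the 2×2 table
   class × CRESS membership is tested with a Pearson chi-square
   ($\sum (O-E)^2/E$, df = 1, p from the survival function; Yates
   correction available but off by default since a planned single test on
   ample counts does not need it). Because "fraction of CRESS viruses"
   can be read per-taxon or abundance-weighted, `cress_fractions` emits
   both.

## Mutation-drift calibration

`calibration_curve` re-creates the model-sequence experiment in a fully
controlled setting: a 100-nt sequence drawn from a database genome is
mutated at rates 0.1–0.5 (exactly $\mathrm{round}(rL)$ positions
substituted, each to a uniformly chosen different base, so the Hamming
identity to the source is forced to $100(1-r)$), re-searched against the
database, and the best hit compared to the truth. A replicate is
*misassigned* when the best hit shares no ancestor with the source taxon
at or below `related_rank` (default family — conservative, since observed
drift in practice crosses kingdoms). The curve reports, per rate:

* `mean_best_identity` / `mean_best_coverage` — from the best local
  alignment. Note that a local aligner sheds mismatching ends, so at high
  rates the best-hit identity sits *above* $100(1-r)$ while coverage
  collapses — exactly the diagnostic geometry of spurious annotation.
* `mean_source_identity` — ungapped identity against the source
  region, recomputed per replicate; equals $100(1-r)$ by construction of
  the mutation operator.
* `misassignment_fraction` and a `borderline_flag` marking rates where
  replicates split between correct and drifted calls.

With 30 replicates per rate against a database of 26 synthetic genomes,
assignments are stable through 30% mutation and drift sets in at 40–50%,
with misassigned hits showing high identity but low query coverage.
Because this runs against a synthetic database rather than the live NCBI
nt, the precise drift-onset rate is qualitative, not a constant to
reproduce.

## The synthetic study generator

`simulate_pools` builds a complete, ground-truthed four-pool study so
that every stage runs and can be *validated* offline:

* a fixed taxonomy skeleton (three CRESS-DNA virus families, seven other
  viral families including two phage families, plus one bacterial and one
  plant family as unrelated calibration targets), with species leaves
  allocated to families round-robin and host groups attached per family;
* one random (uniform base) genome of 2000–3000 nt per species;
* four pools in two "ecosystems": the first pair shares 8 taxa, the
  second 4, and one taxon bridges ecosystems — pool-exclusive taxa make
  up the rest (pool sizes 26/25/23/22, so ~83 distinct taxa, most of them
  singletons, matching the scale of a small field study);
* per-taxon confidence classes (45% novel) and CRESS membership planted
  at 0.65 among novel vs 0.35 among high-confidence taxa, so the novel
  class is genuinely CRESS-enriched;
* **high-confidence contigs**: genome fragments of 800–1600 nt mutated at
  2–10% — full-length homology, coverage ≈ 100%;
* **novel contigs**: a conserved island (15–45% of an 800–1400 nt contig,
  mutated at 2–8%) embedded in random flanks. This geometry — not
  uniformly diverged sequence — is what produces hits with high local
  identity and low query coverage, the hallmark the classifier keys on;
* **circular contigs**: one complete (mutated) genome per pool with its
  first 141 nt re-appended, the terminal direct repeat an assembler
  produces for a circular template;
* **contaminants**: fragments of "control phage" genomes planted in every
  pool *and* in the no-template control table, exercising the exclusion
  rule end to end;
* read counts drawn negative-binomial (mean 200, dispersion 2) — a
  standard overdispersed count model; the study this emulates reports no
  abundance model, so the choice is ours and only affects RPKM spread.

Hit tables are produced by running the package's own search engine
(vectorized Smith–Waterman via Biostrings with a k-mer seeding prefilter,
word size 14) against the reference database, with bitscores on a
Karlin–Altschul-like scale and e-values $E = mN2^{-b}$ — so weak chance
alignments genuinely fail the e-value filter, as in real BLAST output. A
generator self-audit re-checks every contig's realized coverage against
its planted class before the simulation is returned.

What the generator does *not* emulate: read-level sequencing error,
assembly chimeras/fragmentation, uneven coverage within contigs, shared
homology between related species (genomes are independent), codon
structure, and database redundancy. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct and lossless under
known truth — not that a real nt-scale search would reach the same
accuracy.

## Genome-level procedures

* `detect_circularity` finds the longest exact, non-self-overlapping
  prefix that equals a suffix (at least `min_terminal_repeat`, default
  20 nt) and trims it; matching is exact because the repeat arises from
  the assembler copying the same sequence. Re-appending the detected
  overlap reconstructs the input (round-trip property).
* `genome_identity` is global-alignment identity; for circular genomes
  the rotation is anchored by the best local alignment before the global
  pass (a full rotation scan is available via `exhaustive = TRUE` but is
  quadratic and unnecessary at desk scale).
* `demarcate` applies the circovirus species rule: identity < 75%
  (strict) means a distinct species; the worked 78% case is a *variant*.
* `insilico_pcr` matches the forward primer and the reverse-complemented
  reverse primer exactly (the assays it models were validated by real PCR
  and Sanger sequencing; mismatch/degenerate annealing models are out of
  scope), measures products 5'-to-5' inclusive, caps them at
  `max_amplicon`, and wraps across the origin of circular templates, so
  the product set is rotation-invariant.

## Numerical choices

* **Alignment scoring**: match +2, mismatch −3, gap open 5, gap extend 2
  (megablast-like). A gap of length $L$ costs $5 + 2L$ — the Biostrings
  affine convention, and the convention the test-suite's independent DP
  oracle implements. Scores are orientation-symmetric; identities of
  co-optimal alignments need not be, which the tests account for.
* **Zero-score local alignments** (no positive path) return score 0 with
  empty spans rather than an error.
* **Tie-breaks** are deterministic everywhere (bitscore → e-value →
  tax_id for best hit; subject_id for equal-score search results), so
  identical inputs and seeds give byte-identical outputs.
* **Seeds**: every stochastic entry point takes an explicit seed and
  restores the caller's RNG state (`mutate_sequence`, `simulate_pools`,
  `calibration_curve`).
* **Problem sizes** used by the analysis scripts and acceptance checks —
  4 pools, ~110 contigs, 93 reference genomes, 30 calibration replicates
  per rate, 200 oracle alignment pairs, 1000 chi-square quadrature
  checks — were chosen as the smallest sizes at which every property is
  exercised with comfortable statistical margins.

## Known limitations

* The aligner is exhaustive (plus optional exact-k-mer seeding); it is a
  search-engine stand-in for desk-scale synthetic databases, not a
  replacement for BLAST on nt.
* Protein-space search (BLASTP-style annotation of predicted ORFs) is
  not implemented; the confidence analytic operates on nucleotide hits.
* LCA assignment requires all subject taxa in the supplied taxonomy;
  there is no fuzzy matching of merged/deleted NCBI tax_ids.
* The e-value model in the generator is a calibrated approximation used
  to make filtering realistic, not a fitted Karlin–Altschul statistic.
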