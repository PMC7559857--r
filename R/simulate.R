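#' @title Ground-truthed synthetic virome generator
#' @description Emulates the structure of a multi-pool mosquito virome
#'   study so the whole annotation-confidence workflow runs, and can be
#'   validated against known truth, without any external database: four
#'   mosquito pools from two ecosystems with planted shared ("ecosystem
#'   signature") taxa, a divergence gradient producing both high-confidence
#'   and novel hits, CRESS-DNA enrichment among the novel class, circular
#'   genomes assembled with terminal direct repeats, and no-template
#'   control contaminants exercising the exclusion rule. Novel-class
#'   contigs are built as a conserved island inside otherwise-random
#'   sequence, reproducing the diagnostic geometry of novel viruses: high
#'   local identity over only a minor fraction of the query.
#' @name synthetic_data
NULL

#' Simulation design
#'
#' Defaults emulate a four-pool, two-ecosystem study: the two pools of the
#' first ecosystem share 8 taxa, the two pools of the second share 4, and
#' one taxon bridges the ecosystems; the remaining taxa are pool-exclusive.
#' Roughly 45% of taxa are planted as novel, and the CRESS-DNA fraction is
#' 0.65 among novel versus 0.35 among high-confidence taxa, so the novel
#' class is genuinely enriched in CRESS viruses. One circular genome per
#' pool is assembled with a 141-nt terminal repeat.
#'
#' @param n_pools number of pools (the default design fixes 4).
#' @param taxa_per_pool integer vector of planted taxa per pool.
#' @param shared_pairs data.frame (pool_a, pool_b, n_shared).
#' @param novel_fraction fraction of union taxa planted as novel class.
#' @param cress_fraction_by_class named numeric: CRESS fraction among
#'   novel and high_confidence taxa.
#' @param n_circular_per_pool circular contigs per pool.
#' @param terminal_repeat_len exact terminal repeat length (nt).
#' @param n_contaminants contaminant subjects planted in pools and in the
#'   no-template control.
#' @param n_broad_taxa broad-category (uncultured-like) taxa planted.
#' @param genome_len_range reference genome length range (nt).
#' @param highconf_mut_range,novel_mut_range mutation-rate ranges applied
#'   to high-confidence contigs and to novel-contig islands.
#' @param island_frac_range fraction of a novel contig occupied by the
#'   conserved island.
#' @param count_mu,count_size negative-binomial read-count model.
#' @param seed_k k-mer word size of the search prefilter.
#' @param rng_seed master seed.
#' @export
simulation_design <- function(n_pools = 4L,
                              taxa_per_pool = c(26L, 25L, 23L, 22L),
                              shared_pairs = data.frame(
                                pool_a = c(1L, 3L, 1L),
                                pool_b = c(2L, 4L, 3L),
                                n_shared = c(8L, 4L, 1L)),
                              novel_fraction = 0.45,
                              cress_fraction_by_class = c(novel = 0.65,
                                                          high_confidence = 0.35),
                              n_circular_per_pool = 1L,
                              terminal_repeat_len = 141L,
                              n_contaminants = 2L,
                              n_broad_taxa = 2L,
                              genome_len_range = c(2000L, 3000L),
                              highconf_mut_range = c(0.02, 0.10),
                              novel_mut_range = c(0.02, 0.08),
                              island_frac_range = c(0.15, 0.45),
                              count_mu = 200, count_size = 2,
                              seed_k = 14L,
                              rng_seed = 1L) {
  d <- list(n_pools = as.integer(n_pools),
            taxa_per_pool = as.integer(taxa_per_pool),
            shared_pairs = shared_pairs,
            novel_fraction = novel_fraction,
            cress_fraction_by_class = cress_fraction_by_class,
            n_circular_per_pool = as.integer(n_circular_per_pool),
            terminal_repeat_len = as.integer(terminal_repeat_len),
            n_contaminants = as.integer(n_contaminants),
            n_broad_taxa = as.integer(n_broad_taxa),
            genome_len_range = as.integer(genome_len_range),
            highconf_mut_range = highconf_mut_range,
            novel_mut_range = novel_mut_range,
            island_frac_range = island_frac_range,
            count_mu = count_mu, count_size = count_size,
            seed_k = as.integer(seed_k),
            rng_seed = as.integer(rng_seed))
  stopifnot(length(d$taxa_per_pool) == d$n_pools,
            all(d$taxa_per_pool >= 1L),
            d$novel_fraction >= 0, d$novel_fraction <= 1,
            all(d$cress_fraction_by_class >= 0 & d$cress_fraction_by_class <= 1),
            d$terminal_repeat_len >= 20L,
            d$genome_len_range[1] <= d$genome_len_range[2])
  # shared allocations must fit inside both pools of every pair
  for (i in seq_len(nrow(d$shared_pairs))) {
    pa <- d$shared_pairs$pool_a[i]; pb <- d$shared_pairs$pool_b[i]
    load_a <- sum(d$shared_pairs$n_shared[d$shared_pairs$pool_a == pa |
                                            d$shared_pairs$pool_b == pa])
    load_b <- sum(d$shared_pairs$n_shared[d$shared_pairs$pool_a == pb |
                                            d$shared_pairs$pool_b == pb])
    if (load_a > d$taxa_per_pool[pa] || load_b > d$taxa_per_pool[pb]) {
      stop("simulation design error: planted shared taxa exceed pool size for pair ",
           pa, "-", pb)
    }
  }
  structure(d, class = "simulation_design")
}

# Fixed synthetic taxonomy skeleton: families with host groups and CRESS flag.
SIM_FAMILIES <- data.frame(
  name = c("Circoviridae", "Genomoviridae", "Smacoviridae",
           "Mesoniviridae", "Dicistroviridae", "Phenuiviridae",
           "Parvoviridae", "Anelloviridae", "Microviridae", "Myoviridae",
           "Enterobacteriaceae", "Poaceae"),
  kingdom = c(rep("Viruses", 10), "Bacteria", "Eukaryota"),
  cress = c(TRUE, TRUE, TRUE, rep(FALSE, 9)),
  host_group = c("bat", "mosquito", "other_mammal",
                 "mosquito", "other_invertebrate", "mosquito",
                 "mosquito", "human", "bacteriophage", "bacteriophage",
                 "environmental", "plant"),
  stringsAsFactors = FALSE)

#' Generate the synthetic taxonomy tree
#'
#' Root, three superkingdoms, a fixed panel of CRESS and non-CRESS virus
#' families (plus one bacterial and one plant family for taxonomically
#' unrelated calibration targets), one genus per family, and species
#' leaves allocated round-robin: CRESS species across the CRESS families,
#' non-CRESS across the viral non-CRESS families. Broad-category taxa
#' ("uncultured virus"-like) attach directly under the virus superkingdom
#' with rank no_rank.
#'
#' @param n_cress,n_noncress species leaf counts per category.
#' @param n_unrelated species under the bacterial/plant families.
#' @param n_broad broad-category taxa.
#' @param n_contam contaminant species (phiX-like control phages under
#'   Microviridae) whose subjects are planted into the no-template control.
#' @return list: tree (a \code{taxonomy}), species (data.frame tax_id,
#'   family, cress, broad, contaminant, host_group), host_map.
#' @export
simulate_taxonomy <- function(n_cress, n_noncress, n_unrelated = 6L,
                              n_broad = 2L, n_contam = 0L) {
  fam <- SIM_FAMILIES
  rows <- list(data.frame(tax_id = 1L, parent_id = 1L, rank = "root",
                          name = "root"))
  sk <- data.frame(tax_id = c(10L, 11L, 12L), parent_id = 1L,
                   rank = "superkingdom",
                   name = c("Viruses", "Bacteria", "Eukaryota"))
  rows <- c(rows, list(sk))
  sk_id <- stats::setNames(sk$tax_id, sk$name)
  fam$tax_id <- 100L + seq_len(nrow(fam))
  rows <- c(rows, list(data.frame(tax_id = fam$tax_id,
                                  parent_id = unname(sk_id[fam$kingdom]),
                                  rank = "family", name = fam$name)))
  gen_id <- 200L + seq_len(nrow(fam))
  rows <- c(rows, list(data.frame(tax_id = gen_id, parent_id = fam$tax_id,
                                  rank = "genus",
                                  name = paste0(fam$name, "_genus"))))
  alloc <- function(n, fam_idx) {
    if (n == 0L) return(integer(0))
    fam_idx[((seq_len(n) - 1L) %% length(fam_idx)) + 1L]
  }
  cress_idx <- which(fam$cress)
  viral_idx <- which(!fam$cress & fam$kingdom == "Viruses")
  unrel_idx <- which(fam$kingdom != "Viruses")
  species_fam <- c(alloc(n_cress, cress_idx), alloc(n_noncress, viral_idx),
                   alloc(n_unrelated, unrel_idx))
  n_sp <- length(species_fam)
  sp_id <- 1000L + seq_len(n_sp)
  rows <- c(rows, list(data.frame(
    tax_id = sp_id, parent_id = gen_id[species_fam], rank = "species",
    name = paste0(fam$name[species_fam], "_sp", sp_id))))
  broad_id <- integer(0)
  if (n_broad > 0L) {
    broad_id <- 5000L + seq_len(n_broad)
    rows <- c(rows, list(data.frame(
      tax_id = broad_id, parent_id = sk_id[["Viruses"]], rank = "no_rank",
      name = paste0("uncultured virus ", seq_len(n_broad)))))
  }
  contam_id <- integer(0)
  if (n_contam > 0L) {
    contam_id <- 9000L + seq_len(n_contam)
    micro_gen <- gen_id[match("Microviridae", fam$name)]
    rows <- c(rows, list(data.frame(
      tax_id = contam_id, parent_id = micro_gen, rank = "species",
      name = paste0("control phage ", seq_len(n_contam)))))
  }
  nodes <- do.call(rbind, rows)
  tree <- taxonomy(nodes)
  species <- data.frame(
    tax_id = c(sp_id, broad_id, contam_id),
    family = c(fam$name[species_fam], rep(NA_character_, n_broad),
               rep("Microviridae", n_contam)),
    cress = c(fam$cress[species_fam], rep(FALSE, n_broad + n_contam)),
    unrelated = c(fam$kingdom[species_fam] != "Viruses",
                  rep(FALSE, n_broad + n_contam)),
    broad = c(rep(FALSE, n_sp), rep(TRUE, n_broad), rep(FALSE, n_contam)),
    contaminant = c(rep(FALSE, n_sp + n_broad), rep(TRUE, n_contam)),
    host_group = c(fam$host_group[species_fam],
                   rep("environmental", n_broad),
                   rep("bacteriophage", n_contam)),
    stringsAsFactors = FALSE)
  hm <- host_map(stats::setNames(species$host_group, species$tax_id))
  list(tree = tree, species = species, host_map = hm)
}

#' Simulate the reference genome database
#'
#' One random (uniform base model) genome per species-level taxon, lengths
#' uniform over the design's range; deterministic given the design seed.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param species species table from \code{\link{simulate_taxonomy}}.
#' @return list of \code{labeled_seq} named by seq_id.
#' @export
simulate_reference_db <- function(design, species) {
  with_seed(design$rng_seed + 1L, {
    lapply(seq_len(nrow(species)), function(i) {
      len <- sample(design$genome_len_range[1]:design$genome_len_range[2], 1L)
      labeled_sequence(paste0("ref_", species$tax_id[i]),
                       species$tax_id[i], random_sequence(len))
    })
  })
}

runif1 <- function(range) stats::runif(1L, range[1], range[2])

#' Simulate the full multi-pool study
#'
#' Plants taxa into pools per the design (shared pairs first, then
#' exclusive taxa), assigns each union taxon a confidence class and a
#' CRESS/non-CRESS category at the planted fractions, builds contigs per
#' class (full low-divergence fragments for high-confidence taxa;
#' conserved-island-plus-random-flank contigs for novel taxa; complete
#' genomes with a terminal direct repeat for circular contigs), injects
#' contaminant contigs into pools and the no-template control, generates
#' hit tables by searching every contig against the reference database
#' with the built-in aligner, and draws negative-binomial read counts.
#' A self-audit checks every contig's realized coverage and identity
#' against its planted class before returning.
#'
#' @param design a \code{\link{simulation_design}}.
#' @return list of class \code{virome_simulation}: tree, species, host_map,
#'   db, contigs (per-pool list of \code{labeled_seq}), hits (per-pool hit
#'   tables), control_hits, counts, exclusions, truth.
#' @export
simulate_pools <- function(design = simulation_design()) {
  n_union <- sum(design$taxa_per_pool) - sum(design$shared_pairs$n_shared)
  n_novel <- round(design$novel_fraction * n_union)
  n_high <- n_union - n_novel
  n_novel_cress <- round(design$cress_fraction_by_class[["novel"]] * n_novel)
  n_high_cress <- round(design$cress_fraction_by_class[["high_confidence"]] * n_high)
  n_cress <- n_novel_cress + n_high_cress
  n_noncress <- n_union - n_cress

  tax <- simulate_taxonomy(n_cress, n_noncress, n_unrelated = 6L,
                           n_broad = design$n_broad_taxa,
                           n_contam = design$n_contaminants)
  db <- simulate_reference_db(design, tax$species)
  names(db) <- vapply(db, function(s) s$seq_id, "")

  sim <- with_seed(design$rng_seed + 3L, {
    plant <- plant_taxa(design, tax$species,
                        n_novel, n_novel_cress, n_high, n_high_cress)
    build_pools(design, tax, db, plant)
  })
  sim$tree <- tax$tree
  sim$species <- tax$species
  sim$host_map <- tax$host_map
  sim$db <- db
  sim$design <- design
  class(sim) <- "virome_simulation"
  audit_simulation(sim)
  sim
}

# Allocate union taxa to pools, classes and CRESS categories.
plant_taxa <- function(design, species, n_novel, n_novel_cress,
                       n_high, n_high_cress) {
  cress_pool_ids <- species$tax_id[species$cress & !species$broad &
                                     !species$contaminant]
  noncress_pool_ids <- species$tax_id[!species$cress & !species$unrelated &
                                        !species$broad & !species$contaminant]
  taxon <- data.frame(
    tax_id = c(sample(cress_pool_ids), sample(noncress_pool_ids)),
    cress = c(rep(TRUE, length(cress_pool_ids)),
              rep(FALSE, length(noncress_pool_ids))))
  cl <- character(nrow(taxon))
  cl[taxon$cress] <- c(rep("novel", n_novel_cress),
                       rep("high_confidence", n_high_cress))
  cl[!taxon$cress] <- c(rep("novel", n_novel - n_novel_cress),
                        rep("high_confidence", n_high - n_high_cress))
  taxon$class <- cl
  # shuffle so shared slots draw a mixture of classes/categories
  taxon <- taxon[sample.int(nrow(taxon)), ]

  pool_sets <- rep(list(integer(0)), design$n_pools)
  cursor <- 0L
  take <- function(n) {
    ids <- taxon$tax_id[cursor + seq_len(n)]
    cursor <<- cursor + n
    ids
  }
  shared_sets <- vector("list", nrow(design$shared_pairs))
  for (i in seq_len(nrow(design$shared_pairs))) {
    ids <- take(design$shared_pairs$n_shared[i])
    shared_sets[[i]] <- ids
    pa <- design$shared_pairs$pool_a[i]; pb <- design$shared_pairs$pool_b[i]
    pool_sets[[pa]] <- c(pool_sets[[pa]], ids)
    pool_sets[[pb]] <- c(pool_sets[[pb]], ids)
  }
  for (p in seq_len(design$n_pools)) {
    ids <- take(design$taxa_per_pool[p] - length(pool_sets[[p]]))
    pool_sets[[p]] <- c(pool_sets[[p]], ids)
  }
  stopifnot(cursor == nrow(taxon))
  list(taxon = taxon, pool_sets = pool_sets, shared_sets = shared_sets)
}

# Build contigs, hit tables, counts and truth for every pool.
build_pools <- function(design, tax, db, plant) {
  half <- ceiling(design$n_pools / 2)
  site <- rep(c("AUT", "BRB"), times = c(half, design$n_pools - half))
  pool_names <- paste0(site, "_",
                       sprintf("%02d", stats::ave(seq_len(design$n_pools),
                                                  site, FUN = seq_along)))
  class_of <- stats::setNames(plant$taxon$class, plant$taxon$tax_id)
  total_db_len <- sum(vapply(db, function(s) nchar(s$sequence), 0L))
  contam_taxa <- tax$species$tax_id[tax$species$contaminant]
  search_db <- db
  index <- kmer_index(search_db, design$seed_k)
  search_ss <- Biostrings::DNAStringSet(vapply(search_db, function(s)
    s$sequence, ""))

  contigs <- list(); hits <- list(); truth_contigs <- list()
  counts <- list()
  control_rows <- list()

  for (p in seq_len(design$n_pools)) {
    pool <- pool_names[p]
    taxa <- plant$pool_sets[[p]]
    # broad taxa ride along in the first two pools
    broad_here <- tax$species$tax_id[tax$species$broad]
    broad_here <- if (p <= 2L && length(broad_here) >= p) broad_here[p] else integer(0)
    circ_taxa <- integer(0)
    hc_taxa <- taxa[class_of[as.character(taxa)] == "high_confidence"]
    if (design$n_circular_per_pool > 0L && length(hc_taxa) > 0L) {
      circ_taxa <- hc_taxa[seq_len(min(design$n_circular_per_pool, length(hc_taxa)))]
    }
    pool_contigs <- list(); pool_truth <- list()
    ci <- 0L
    emit <- function(tid, kind) {
      ci <<- ci + 1L
      id <- paste0(pool, "_c", sprintf("%03d", ci))
      g <- db[[paste0("ref_", tid)]]$sequence
      glen <- nchar(g)
      if (kind == "circular") {
        rate <- runif1(design$highconf_mut_range)
        gm <- mutate_sequence(g, rate)
        seqs <- paste0(gm, substr(gm, 1L, design$terminal_repeat_len))
        cls <- "high_confidence"; mrate <- rate
        circ <- TRUE; overlap <- design$terminal_repeat_len
      } else if (kind == "high_confidence") {
        flen <- sample(800:min(1600L, glen), 1L)
        st <- sample.int(glen - flen + 1L, 1L)
        rate <- runif1(design$highconf_mut_range)
        seqs <- mutate_sequence(substr(g, st, st + flen - 1L), rate)
        cls <- "high_confidence"; mrate <- rate; circ <- FALSE; overlap <- 0L
      } else { # novel: conserved island inside random flanks
        clen <- sample(800:1400, 1L)
        ifrac <- runif1(design$island_frac_range)
        ilen <- max(150L, round(ifrac * clen))
        st <- sample.int(nchar(g) - ilen + 1L, 1L)
        rate <- runif1(design$novel_mut_range)
        island <- mutate_sequence(substr(g, st, st + ilen - 1L), rate)
        off <- sample.int(clen - ilen + 1L, 1L)
        seqs <- paste0(random_sequence(off - 1L), island,
                       random_sequence(clen - ilen - off + 1L))
        cls <- "novel"; mrate <- rate; circ <- FALSE; overlap <- 0L
      }
      pool_contigs[[id]] <<- labeled_sequence(id, tid, seqs)
      pool_truth[[id]] <<- data.frame(
        contig_id = id, sample_id = pool, tax_id = tid, class = cls,
        mutation_rate = mrate, circular = circ, overlap_length = overlap,
        contaminant = FALSE, broad = tid %in% tax$species$tax_id[tax$species$broad],
        stringsAsFactors = FALSE)
    }
    for (tid in taxa) {
      kind <- if (tid %in% circ_taxa) "circular" else class_of[[as.character(tid)]]
      emit(tid, kind)
      # a second contig for a couple of taxa exercises cluster means
      if (match(tid, taxa) <= 2L && !(tid %in% circ_taxa)) emit(tid, kind)
    }
    for (tid in broad_here) emit(tid, "high_confidence")

    # contaminant contigs: fragments of control-phage genomes, whose
    # subjects also show up in the no-template control
    for (tid in contam_taxa) {
      ci <- ci + 1L
      id <- paste0(pool, "_c", sprintf("%03d", ci))
      cg <- db[[paste0("ref_", tid)]]$sequence
      frag <- mutate_sequence(substr(cg, 1L, 900L), 0.02)
      pool_contigs[[id]] <- labeled_sequence(id, tid, frag)
      pool_truth[[id]] <- data.frame(
        contig_id = id, sample_id = pool, tax_id = tid,
        class = "contaminant", mutation_rate = 0.02, circular = FALSE,
        overlap_length = 0L, contaminant = TRUE, broad = FALSE,
        stringsAsFactors = FALSE)
    }

    # hit tables via the built-in search engine
    pool_hits <- do.call(rbind, lapply(pool_contigs, function(ctg) {
      res <- search_database(ctg, search_db, top_n = 30L, index = index,
                             .stringset = search_ss)
      if (nrow(res) == 0L) return(NULL)
      as_hit_rows(ctg, res, total_db_len)
    }))
    rownames(pool_hits) <- NULL

    # read counts (negative binomial), depth denominator = mapped total
    counts[[pool]] <- data.frame(
      sample_id = pool,
      contig_id = names(pool_contigs),
      length = vapply(pool_contigs, function(s) nchar(s$sequence), 0L),
      mapped_reads = stats::rnbinom(length(pool_contigs),
                                    mu = design$count_mu,
                                    size = design$count_size),
      stringsAsFactors = FALSE)

    contigs[[pool]] <- pool_contigs
    hits[[pool]] <- pool_hits
    truth_contigs[[pool]] <- do.call(rbind, pool_truth)
  }

  # no-template control: the contaminant subjects show up there too
  control_hits <- do.call(rbind, lapply(seq_along(contam_taxa), function(j) {
    cg <- db[[paste0("ref_", contam_taxa[j])]]$sequence
    frag <- labeled_sequence(paste0("NTC_c", j), contam_taxa[j],
                             mutate_sequence(substr(cg, 101L, 1000L), 0.02))
    res <- search_database(frag, search_db, top_n = 5L, index = index,
                           .stringset = search_ss)
    if (nrow(res) == 0L) return(NULL)
    as_hit_rows(frag, res, total_db_len)
  }))
  rownames(control_hits) <- NULL

  truth_df <- do.call(rbind, truth_contigs)
  rownames(truth_df) <- NULL
  list(
    pool_names = pool_names,
    contigs = contigs,
    hits = hits,
    control_hits = control_hits,
    counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
    exclusions = control_exclusions(
      control_hits, broad_taxa = tax$species$tax_id[tax$species$broad]),
    truth = list(
      contigs = truth_df,
      pool_taxa = stats::setNames(
        lapply(seq_along(pool_names), function(p)
          sort(unique(truth_df$tax_id[truth_df$sample_id == pool_names[p] &
                                        !truth_df$contaminant]))),
        pool_names),
      shared_sets = plant$shared_sets,
      shared_pairs = design$shared_pairs,
      taxon_class = stats::setNames(plant$taxon$class, plant$taxon$tax_id),
      taxon_cress = stats::setNames(plant$taxon$cress, plant$taxon$tax_id)))
}

# Convert ranked alignment results into BLAST-like tabular rows.
# Bitscore uses a megablast-like Karlin-Altschul transform and the e-value
# follows E = m * N * 2^-bits.
as_hit_rows <- function(ctg, res, total_db_len) {
  qlen <- nchar(ctg$sequence)
  bits <- (0.625 * res$score - log(0.41)) / log(2)
  evalue <- qlen * total_db_len * 2^(-bits)
  data.frame(
    query_id = ctg$seq_id,
    subject_id = res$subject_id,
    pident = round(res$identity, 3),
    align_length = res$align_length,
    mismatch = pmax(0L, round(res$align_length * (1 - res$identity / 100))),
    gapopen = 0L,
    qstart = res$q_start, qend = res$q_end,
    sstart = res$s_start, send = res$s_end,
    evalue = evalue,
    bitscore = round(bits, 2),
    query_length = qlen,
    subject_taxid = res$subject_taxid,
    stringsAsFactors = FALSE)
}

# Self-audit: every contig's realized best-hit coverage/identity against its
# source genome must match its planted class.
audit_simulation <- function(sim) {
  boundary <- 60
  for (pool in sim$pool_names) {
    tr <- sim$truth$contigs[sim$truth$contigs$sample_id == pool, ]
    h <- sim$hits[[pool]]
    for (i in seq_len(nrow(tr))) {
      if (tr$contaminant[i]) next
      src <- paste0("ref_", tr$tax_id[i])
      hh <- h[h$query_id == tr$contig_id[i] & h$subject_id == src, , drop = FALSE]
      if (nrow(hh) == 0L) {
        stop("simulation self-audit: contig ", tr$contig_id[i],
             " has no hit to its source genome ", src)
      }
      cov <- max(query_coverage(hh))
      ok <- if (tr$class[i] == "high_confidence") cov > boundary else cov <= boundary
      if (!ok) {
        stop("simulation self-audit: contig ", tr$contig_id[i],
             " realized coverage ", round(cov, 1),
             " inconsistent with planted class ", tr$class[i])
      }
    }
  }
  invisible(TRUE)
}

#' Write a simulation to disk in the dialects the pipeline consumes
#'
#' Per pool: \code{<pool>_contigs.fasta} and \code{<pool>_hits.tsv};
#' plus \code{control_hits.tsv}, \code{counts.tsv}, \code{taxonomy.tsv},
#' \code{host_map.tsv}, \code{reference_db.fasta} and
#' \code{ground_truth.json}.
#'
#' @param sim a \code{virome_simulation}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pool in sim$pool_names) {
    write_seq_db(unname(sim$contigs[[pool]]),
                 file.path(dir, paste0(pool, "_contigs.fasta")))
    write_hit_table(sim$hits[[pool]], file.path(dir, paste0(pool, "_hits.tsv")))
  }
  write_hit_table(sim$control_hits, file.path(dir, "control_hits.tsv"))
  utils::write.table(sim$counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_taxonomy(sim$tree, file.path(dir, "taxonomy.tsv"))
  write_host_map(sim$host_map, file.path(dir, "host_map.tsv"))
  write_seq_db(unname(sim$db), file.path(dir, "reference_db.fasta"))
  truth <- sim$truth
  truth$pool_taxa <- lapply(truth$pool_taxa, as.integer)
  # named vectors do not survive JSON: emit per-taxon truth as a table
  truth$taxa <- data.frame(tax_id = as.integer(names(truth$taxon_class)),
                           class = unname(truth$taxon_class),
                           cress = unname(truth$taxon_cress[names(truth$taxon_class)]))
  truth$taxon_class <- NULL
  truth$taxon_cress <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
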