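# Synthetic diploid genome panel with planted ground truth.
#
# The generator emulates a panel of related grapevine-like genomes: two
# haplotypes per genome carrying planted SNPs, small indels and SVs
# (including gene-deleting deletions), conserved gene order with shared /
# lineage-specific / translocated gene content, tandem-free inter-
# chromosomal segmental duplications, NLR domain assignments, upstream TE
# insertions with a planted negative effect on expression, and a trio
# pedigree with known hemizygous-gene origins.  Inter-genome homology and
# alignment blocks are emitted from construction bookkeeping, so every
# truth record is exact.  A fixed seed yields byte-identical output trees.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.rand_chars <- function(n) sample(.BASES, n, replace = TRUE)
.revcomp_chars <- function(x) unname(rev(.COMP[x]))

.GENE_LEN <- 1500L       # exon1 [0,300) + intron [300,600) + exon2 [600,1500)
.EXON1 <- c(0L, 300L)
.INTRON <- c(300L, 600L)
.EXON2 <- c(600L, 1500L)
.CDS_LEN <- 1200L        # 400 codons including start and stop

#' Simulation configuration
#'
#' Validates and assembles the full set of knobs of the synthetic panel.
#' Defaults describe the study conditions exercised by the pipeline: five
#' genomes (two wild, three cultivated), two 500-kb chromosomes, 200 genes
#' per genome, per-genome inter-haplotype variation at realistic rates,
#' five gene-deleting deletions, twenty protein-changing and thirty
#' gene-body-only heterozygous genes, ten segmentally duplicated source
#' genes, and a trio pedigree with the last cultivated genome as
#' offspring.
#'
#' @param seed Integer seed fixing every random draw.
#' @param wild_labels,cultivated_labels Genome names per group.
#' @param chrom_count,chrom_length,gene_count Panel dimensions (genes per
#'   genome).
#' @param snp_rate,small_indel_rate Per-base background rates between the
#'   two haplotypes (intergenic space).
#' @param sv_deletion_count Total SV deletions per genome;
#'   `gene_deleting_fraction` of them are placed over whole genes and
#'   create hemizygous loci.
#' @param gene_deleting_fraction Fraction of SV deletions spanning whole
#'   genes.
#' @param sv_insertion_count,sv_inversion_count Background SV counts.
#' @param protein_het_count,gene_het_count Genes given one exonic missense
#'   SNP / one intronic SNP.
#' @param te_density Probability that a collinear gene group carries a
#'   constant (non-polymorphic) upstream TE.
#' @param te_polymorphic_fraction Probability that a group is TE-insertion
#'   polymorphic across the panel.
#' @param sd_count Segmentally duplicated source genes per genome.
#' @param nlr_fraction Fraction of genes given NLR domain sets.
#' @param expression_noise_sd Log2-scale Gaussian noise per replicate.
#' @param te_effect Log2 expression units lost per unit of upstream TE
#'   proportion (must be non-negative).
#' @param n_replicates RNA-seq replicates per genome.
#' @param read_depth Read depth for simulated locus evidence.
#' @param trio_offspring,trio_parent_a Panel genomes acting as trio
#'   offspring and sequenced parent; the second parent is represented by
#'   a read-coverage track only.
#' @param flank Upstream/downstream window width in bases.
#' @return A validated list of class "sim_config".
#' @export
sim_config <- function(seed = 1L,
                       wild_labels = c("wildA", "wildB"),
                       cultivated_labels = c("cultA", "cultB", "cultC"),
                       chrom_count = 2L, chrom_length = 500000L,
                       gene_count = 200L,
                       snp_rate = 0.0012, small_indel_rate = 2e-4,
                       sv_deletion_count = 25L,
                       gene_deleting_fraction = 0.2,
                       sv_insertion_count = 15L, sv_inversion_count = 2L,
                       protein_het_count = 20L, gene_het_count = 30L,
                       te_density = 0.30, te_polymorphic_fraction = 0.15,
                       sd_count = 10L, nlr_fraction = 0.08,
                       expression_noise_sd = 0.25, te_effect = 4,
                       n_replicates = 3L, read_depth = 40L,
                       trio_offspring = "cultC", trio_parent_a = "cultA",
                       flank = 1000L) {
  rates <- c(snp_rate = snp_rate, small_indel_rate = small_indel_rate,
             gene_deleting_fraction = gene_deleting_fraction,
             te_density = te_density,
             te_polymorphic_fraction = te_polymorphic_fraction,
             nlr_fraction = nlr_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  counts <- c(chrom_count, chrom_length, gene_count, sv_deletion_count,
              sv_insertion_count, sv_inversion_count, protein_het_count,
              gene_het_count, sd_count, n_replicates, read_depth, flank)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (te_effect < 0) {
    stop("negative te_effect magnitude rejected; suppression is applied ",
         "with a minus sign internally")
  }
  if (expression_noise_sd < 0) stop("expression_noise_sd must be >= 0")
  genomes <- c(wild_labels, cultivated_labels)
  if (anyDuplicated(genomes)) stop("genome labels must be distinct")
  if (!trio_offspring %in% genomes || !trio_parent_a %in% genomes) {
    stop("trio genomes must be panel members")
  }
  cfg <- list(seed = as.integer(seed), wild_labels = wild_labels,
              cultivated_labels = cultivated_labels, genomes = genomes,
              labels = setNames(c(rep("wild", length(wild_labels)),
                                  rep("cultivated", length(cultivated_labels))),
                                genomes),
              chrom_count = as.integer(chrom_count),
              chrom_length = as.integer(chrom_length),
              gene_count = as.integer(gene_count),
              snp_rate = snp_rate, small_indel_rate = small_indel_rate,
              sv_deletion_count = as.integer(sv_deletion_count),
              gene_deleting_fraction = gene_deleting_fraction,
              sv_insertion_count = as.integer(sv_insertion_count),
              sv_inversion_count = as.integer(sv_inversion_count),
              protein_het_count = as.integer(protein_het_count),
              gene_het_count = as.integer(gene_het_count),
              te_density = te_density,
              te_polymorphic_fraction = te_polymorphic_fraction,
              sd_count = as.integer(sd_count), nlr_fraction = nlr_fraction,
              expression_noise_sd = expression_noise_sd,
              te_effect = te_effect,
              n_replicates = as.integer(n_replicates),
              read_depth = as.integer(read_depth),
              trio_offspring = trio_offspring,
              trio_parent_a = trio_parent_a, flank = as.integer(flank))
  class(cfg) <- "sim_config"
  cfg
}

# ---- slot design -----------------------------------------------------------

# A "slot" is an ancestral gene locus shared (or not) across the panel.
# Membership quotas guarantee every genome receives exactly gene_count
# slot genes; realised sharing classes are derived from membership, never
# assumed.
.design_slots <- function(cfg) {
  genomes <- cfg$genomes
  ng <- length(genomes)
  gc <- cfg$gene_count
  n_all <- round(0.75 * gc)
  n_cw <- max(1L, round(0.05 * gc))
  n_spec <- max(1L, round(0.04 * gc))
  rem <- gc - n_all - n_cw - n_spec
  if (rem < 0) {
    stop("capacity error: gene_count too small for the sharing-class quotas")
  }
  memberships <- list()
  add <- function(members) memberships[[length(memberships) + 1L]] <<- members
  for (i in seq_len(n_all)) add(genomes)
  cult <- cfg$cultivated_labels; wild <- cfg$wild_labels
  for (i in seq_len(n_cw)) add(cult)
  for (i in seq_len(n_cw)) add(wild)
  for (g in genomes) for (i in seq_len(n_spec)) add(g)
  remaining <- setNames(rep(rem, ng), genomes)
  it <- 0L
  while (sum(remaining) > 0) {
    it <- it + 1L
    s <- names(sort(remaining[remaining > 0], decreasing = TRUE))
    if (length(s) == 1L) {
      members <- s
    } else {
      m <- min(length(s), 2L + it %% 2L)
      members <- s[seq_len(m)]
      if (setequal(members, cult) || setequal(members, wild) ||
          setequal(members, genomes)) {
        members <- members[-length(members)]
      }
    }
    add(members)
    remaining[members] <- remaining[members] - 1L
  }
  n_slots <- length(memberships)
  mem <- matrix(FALSE, n_slots, ng, dimnames = list(NULL, genomes))
  for (i in seq_len(n_slots)) mem[i, memberships[[i]]] <- TRUE
  slot_id <- sprintf("s%04d", seq_len(n_slots))
  rownames(mem) <- slot_id
  all_shared <- rowSums(mem) == ng

  # shuffle, then deal slots onto chromosomes round-robin
  ord <- sample(n_slots)
  chrom_of <- setNames(rep(NA_integer_, n_slots), slot_id)
  order_of <- setNames(rep(NA_integer_, n_slots), slot_id)
  per_chrom <- vector("list", cfg$chrom_count)
  for (k in seq_along(ord)) {
    ch <- (k - 1L) %% cfg$chrom_count + 1L
    per_chrom[[ch]] <- c(per_chrom[[ch]], slot_id[ord[k]])
  }
  for (ch in seq_len(cfg$chrom_count)) {
    chrom_of[per_chrom[[ch]]] <- ch
    order_of[per_chrom[[ch]]] <- seq_along(per_chrom[[ch]])
  }

  strand <- setNames(sample(c("+", "-"), n_slots, replace = TRUE), slot_id)

  list(slot_id = slot_id, membership = mem, all_shared = all_shared,
       chrom = chrom_of, order = order_of, strand = strand,
       per_chrom = per_chrom)
}

# Deterministic NLR layout: one dense cluster and one small cluster on the
# last chromosome, isolated receptors on the first; wild genomes get extra
# TNLs via their genome-specific slots.
.design_nlr <- function(cfg, slots) {
  n_core <- max(4L, round(cfg$nlr_fraction * cfg$gene_count))
  ch_last <- cfg$chrom_count
  seq_last <- slots$per_chrom[[ch_last]]
  seq_first <- slots$per_chrom[[1L]]
  all_last <- seq_last[slots$all_shared[seq_last]]
  all_first <- seq_first[slots$all_shared[seq_first]]
  n_small <- min(3L, max(0L, n_core - 8L))
  n_iso <- min(2L, max(0L, n_core - 8L - n_small))
  n_big <- n_core - n_small - n_iso                   # dense cluster
  big <- all_last[seq_len(min(n_big, length(all_last) - n_small))]
  small <- if (n_small) rev(all_last)[seq_len(n_small)] else character()
  iso <- if (n_iso) all_first[c(2L, length(all_first) - 2L)][seq_len(n_iso)]
         else character()
  core <- unique(c(big, small, iso))
  # core receptor set shared by the whole panel, TNL:(non-TNL) near 1:4
  # as in cultivated genomes; the wild-specific expansion below raises
  # the wild-genome ratio toward 1:2
  subgroup <- setNames(rep("CNL", length(core)), core)
  subgroup[big] <- rep(c("TNL", "TNL", "CNL", "CNL", "CNL", "NL", "NL",
                         "NL", "CNL", "NL", "CNL"),
                       length.out = length(big))
  if (length(small) == 3) subgroup[small] <- c("RNL", "CNL", "TNL")
  if (length(iso) >= 2) subgroup[iso] <- c("CNL", "NL")
  # wild-specific TNL expansion through genome-specific slots
  extra <- character()
  for (g in cfg$wild_labels) {
    spec <- rownames(slots$membership)[
      slots$membership[, g] & rowSums(slots$membership) == 1]
    take <- head(spec, 4L)
    extra <- c(extra, take)
    subgroup[take] <- "TNL"
  }
  # integrated domains: (slot, genome) -> ID name
  ids <- list()
  add_id <- function(slot, genomes, id) {
    for (g in genomes) {
      ids[[length(ids) + 1L]] <<- data.frame(slot = slot, genome = g,
                                             id = id,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(big) >= 5) {
    add_id(big[1], cfg$genomes, "PKinase")
    add_id(big[2], cfg$genomes, "PKinase")
    add_id(big[3], cfg$wild_labels, "Jacalin")
    add_id(big[4], cfg$wild_labels, "Jacalin")
    add_id(big[5], cfg$genomes[1], "BED_zf")
  }
  for (s in extra) add_id(s, intersect(cfg$wild_labels, cfg$genomes[
    slots$membership[s, ]]), "WRKY")
  ids <- if (length(ids)) do.call(rbind, ids) else
    data.frame(slot = character(), genome = character(), id = character(),
               stringsAsFactors = FALSE)
  list(core = core, extra = extra, subgroup = subgroup, ids = ids,
       cluster_big = big, cluster_small = small, isolated = iso)
}

.domain_set <- function(subgroup) {
  switch(subgroup,
         TNL = c("TIR", "NB-ARC", "LRR"),
         CNL = c("CC", "NB-ARC", "LRR"),
         RNL = c("CC_R", "NB-ARC"),
         NL = c("NB-ARC", "LRR"))
}

# Upstream TE pattern per slot: none / constant / polymorphic, realised as
# an exact TE length so that the recorded proportion is exact.
.design_te <- function(cfg, slots, nlr, blocked_slots) {
  n <- length(slots$slot_id)
  genomes <- cfg$genomes
  prop <- matrix(0, n, length(genomes),
                 dimnames = list(slots$slot_id, genomes))
  pattern <- setNames(rep("none", n), slots$slot_id)
  eligible <- slots$all_shared & !(slots$slot_id %in% blocked_slots)
  for (i in which(eligible)) {
    u <- runif(1)
    if (u < cfg$te_polymorphic_fraction) {
      pattern[i] <- "polymorphic"
      p <- ifelse(runif(length(genomes)) < 0.5, 0,
                  round(runif(length(genomes), 0.25, 0.60), 3))
      if (all(p == 0)) p[1] <- round(runif(1, 0.25, 0.60), 3)
      if (all(p > 0)) p[length(p)] <- 0
      prop[i, ] <- p
    } else if (u < cfg$te_polymorphic_fraction + cfg$te_density) {
      pattern[i] <- "constant"
      prop[i, ] <- round(runif(1, 0.25, 0.45), 3)
    }
  }
  list(prop = prop, pattern = pattern)
}

#' Simulate read alignments over a locus
#'
#' Over a hemizygous locus half the reads come from the haplotype still
#' carrying the allele (they span the locus) and half from the haplotype
#' that lost it (they are split at the boundary), so the split count is a
#' Binomial(depth, 0.5) draw; over a homozygous locus every read spans.
#'
#' @param zygosity "hemizygous" or anything else (treated as two-allele).
#' @param depth Total read count (> 0).
#' @param seed Optional seed fixing the draw.
#' @return List with `spanning` and `split` counts summing to `depth`.
#' @export
simulate_read_alignments <- function(zygosity, depth, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  split <- if (identical(zygosity, "hemizygous")) rbinom(1, depth, 0.5) else 0L
  list(spanning = as.integer(depth - split), split = as.integer(split))
}

#' Generate an expression count table from TE profiles
#'
#' The expected log2 expression of a gene is its slot baseline minus
#' `te_effect` times the planted upstream TE proportion; replicate counts
#' add Gaussian log-scale noise and are rounded to non-negative integers
#' on a TPM-like scale.
#'
#' @param te_profiles Data.frame with columns gene_id, genome, base
#'   (baseline log2 expression) and proportion (upstream TE fraction).
#' @param config A [sim_config()] (fields te_effect,
#'   expression_noise_sd, n_replicates are used).
#' @return List: `counts` (named list genome -> genes x replicates integer
#'   matrix), `expected` (te_profiles plus an `mu` column of expected
#'   log2 expression), `length` (effective gene length in bases).
#' @export
generate_expression <- function(te_profiles, config) {
  if (config$te_effect < 0) stop("negative te_effect magnitude rejected")
  mu <- te_profiles$base - config$te_effect * te_profiles$proportion
  te_profiles$mu <- mu
  lib_scale <- 30
  len_kb <- .GENE_LEN / 1000
  counts <- lapply(split(seq_len(nrow(te_profiles)), te_profiles$genome),
                   function(idx) {
    m <- matrix(0L, length(idx), config$n_replicates,
                dimnames = list(te_profiles$gene_id[idx],
                                paste0("rep", seq_len(config$n_replicates))))
    for (r in seq_len(config$n_replicates)) {
      noisy <- mu[idx] + rnorm(length(idx), 0, config$expression_noise_sd)
      m[, r] <- as.integer(round(pmax(0, 2^noisy - 1) * len_kb * lib_scale))
    }
    m
  })
  list(counts = counts[unique(te_profiles$genome)],
       expected = te_profiles, length = .GENE_LEN)
}

# ---- per-genome assembly ---------------------------------------------------

# gene tables, coordinates, haplotypes, variants, blocks for one genome;
# returns everything the writers and the truth tables need
.build_genome <- function(cfg, slots, nlr, plan, g) {
  L <- cfg$chrom_length
  gene_zone_end <- floor(0.88 * L)
  zone_start <- floor(0.90 * L)

  # ordered slot genes per chromosome (translocations move to the other
  # chromosome's tail zone)
  genes <- list()
  trans_here <- names(plan$translocated_in)[plan$translocated_in == g]
  for (ch in seq_len(cfg$chrom_count)) {
    ids <- slots$per_chrom[[ch]]
    ids <- ids[slots$membership[ids, g]]
    ids <- setdiff(ids, trans_here)
    if (!length(ids)) next
    w <- floor(gene_zone_end / length(ids))
    if (w < .GENE_LEN + 1200L) {
      stop("capacity error: chromosome ", ch, " too short for ",
           length(ids), " genes")
    }
    genes[[ch]] <- data.frame(
      slot = ids, chrom = paste0("chr", ch),
      start = (seq_along(ids) - 1L) * w + 1100L,
      strand = unname(slots$strand[ids]),
      origin = "slot", stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, genes)
  # translocated genes: tail zone of the "other" chromosome
  if (length(trans_here)) {
    target <- vapply(trans_here, function(s) {
      cfg$chrom_count - slots$chrom[s] + 1L  # mirror chromosome
    }, integer(1))
    tdf <- data.frame(
      slot = trans_here, chrom = paste0("chr", target),
      start = L - 2200L - (seq_along(trans_here) - 1L) * 2200L,
      strand = unname(slots$strand[trans_here]),
      origin = "translocated", stringsAsFactors = FALSE)
    gdf <- rbind(gdf, tdf)
  }
  gdf$end <- gdf$start + .GENE_LEN
  gdf$gene_id <- paste0(g, "_", gdf$slot)
  stopifnot(nrow(gdf) == cfg$gene_count)

  # primary haplotype sequences
  chrom_names <- paste0("chr", seq_len(cfg$chrom_count))
  primary <- lapply(chrom_names, function(ch) .rand_chars(L))
  names(primary) <- chrom_names
  for (i in seq_len(nrow(gdf))) {
    tpl <- plan$template[[gdf$slot[i]]]
    chars <- if (gdf$strand[i] == "+") tpl$plus else tpl$minus
    primary[[gdf$chrom[i]]][(gdf$start[i] + 1L):gdf$end[i]] <- chars
  }

  # segmental duplications: source genes on chr1, copies in the chr2 zone
  sd_sources <- plan$sd_sources
  sd_rows <- list(); sd_blocks <- list(); copy_genes <- list()
  zone_cursor <- zone_start
  ci <- 0L
  for (si in seq_along(sd_sources)) {
    s <- sd_sources[si]
    src <- gdf[gdf$slot == s, ]
    n_copies <- plan$sd_n_copies[[si]]
    for (k in seq_len(n_copies)) {
      ci <- ci + 1L
      intact <- plan$sd_intact[[si]][k]
      positive <- plan$sd_positive[[si]][k]
      full_len <- .GENE_LEN + 200L
      copy_len <- full_len
      copy_start <- zone_cursor
      zone_cursor <- zone_cursor + copy_len + 120L
      if (zone_cursor > L) {
        stop("capacity error: segmental-duplication zone exhausted")
      }
      seg <- primary[[src$chrom]][(src$start - 100L + 1L):
                                    (src$start - 100L + copy_len)]
      ident <- runif(1, 0.93, 0.985)
      nsub <- max(1L, round((1 - ident) * copy_len))
      # substitutions inside the copied CDS at codon positions chosen by
      # the selection regime; avoid creating stop codons
      seg <- .mutate_copy(seg, nsub, src$strand, positive)
      if (!intact) {
        # disrupted copy: premature stop at transcript codon 20, and no
        # gene model is annotated over it
        if (src$strand == "+") {
          seg[158:160] <- c("T", "A", "A")
        } else {
          seg[1541:1543] <- c("T", "T", "A")
        }
      }
      primary[["chr2"]][(copy_start + 1L):(copy_start + copy_len)] <- seg
      realized_ident <- 1 - nsub / copy_len
      sd_blocks[[length(sd_blocks) + 1L]] <- data.frame(
        qchrom = "chr2", qstart = copy_start, qend = copy_start + copy_len,
        rchrom = src$chrom, rstart = src$start - 100L,
        rend = src$start - 100L + copy_len, strand = "+",
        identity = realized_ident, mismatches = nsub,
        stringsAsFactors = FALSE)
      copy_id <- paste0(src$gene_id, "_sd", k)
      if (intact) {
        copy_genes[[length(copy_genes) + 1L]] <- data.frame(
          slot = s, chrom = "chr2", start = copy_start + 100L,
          strand = src$strand, origin = "sd_copy",
          end = copy_start + 100L + .GENE_LEN, gene_id = copy_id,
          stringsAsFactors = FALSE)
      }
      sd_rows[[length(sd_rows) + 1L]] <- data.frame(
        genome = g, source_gene_id = src$gene_id, copy_gene_id =
          if (intact) copy_id else NA_character_,
        copy_chrom = "chr2", copy_start = copy_start,
        copy_end = copy_start + copy_len, intact = intact,
        positive_selection = positive, identity = realized_ident,
        stringsAsFactors = FALSE)
    }
  }
  # decoy alignment blocks that must fail the SD thresholds
  sd_blocks[[length(sd_blocks) + 1L]] <- data.frame(
    qchrom = "chr2", qstart = 1000L, qend = 1800L, rchrom = "chr1",
    rstart = 5000L, rend = 5800L, strand = "+", identity = 0.97,
    mismatches = 24L, stringsAsFactors = FALSE)
  sd_blocks[[length(sd_blocks) + 1L]] <- data.frame(
    qchrom = "chr2", qstart = 12000L, qend = 13600L, rchrom = "chr1",
    rstart = 52000L, rend = 53600L, strand = "+", identity = 0.85,
    mismatches = 240L, stringsAsFactors = FALSE)
  if (length(copy_genes)) {
    gdf <- rbind(gdf, do.call(rbind, copy_genes)[, names(gdf)])
  }
  gdf <- gdf[order(gdf$chrom, gdf$start), , drop = FALSE]
  rownames(gdf) <- NULL

  list(genes = gdf, primary = primary,
       sd_pairs = if (length(sd_rows)) do.call(rbind, sd_rows) else NULL,
       sd_blocks = do.call(rbind, sd_blocks))
}

# substitutions on a copied segment; `positive` steers most CDS
# substitutions to 2nd codon positions (nonsynonymous, with a synonymous
# minority so Ka/Ks stays defined), otherwise 3rd positions (mostly
# synonymous); never creates a stop codon
.mutate_copy <- function(seg, nsub, strand, positive) {
  n <- length(seg)
  # CDS footprint within the copy (gene starts at offset 100)
  cds_rel <- c((100L + .EXON1[1] + 1L):(100L + .EXON1[2]),
               (100L + .EXON2[1] + 1L):(100L + .EXON2[2]))
  cds_rel <- cds_rel[cds_rel <= n]
  # codon position of each CDS base in transcript orientation
  tx_pos <- seq_along(cds_rel)
  if (strand == "-") tx_pos <- rev(tx_pos)
  codon_pos <- (tx_pos - 1L) %% 3L + 1L
  pool2 <- cds_rel[codon_pos == 2L]
  pool3 <- cds_rel[codon_pos == 3L]
  pool2 <- pool2[pool2 > 103L]  # keep the start codon intact
  pool3 <- pool3[pool3 > 103L]
  pool <- if (positive) {
    # mostly nonsynonymous with a synonymous minority: Ka >> Ks > 0
    c(sample(pool2, min(ceiling(0.8 * nsub), length(pool2))),
      sample(pool3, min(max(1L, floor(0.2 * nsub)), length(pool3))))
  } else {
    sample(pool3, min(nsub, length(pool3)))
  }
  if (length(pool) < nsub) {
    pool <- unique(c(pool, sample(cds_rel[cds_rel > 103L],
                                  min(nsub, length(cds_rel)))))
  }
  picks <- unique(pool)[seq_len(min(nsub, length(unique(pool))))]
  stops <- c("TAA", "TAG", "TGA")
  for (p in picks) {
    old <- seg[p]
    cand <- setdiff(.BASES, old)
    for (b in sample(cand)) {
      seg[p] <- b
      ci <- (match(p, cds_rel) - 1L) %/% 3L
      idx <- cds_rel[(ci * 3L + 1L):(ci * 3L + 3L)]
      idx <- idx[!is.na(idx) & idx <= n]
      codon <- paste0(seg[idx], collapse = "")
      if (strand == "-") codon <- paste0(.revcomp_chars(strsplit(codon, "")[[1]]),
                                         collapse = "")
      if (!codon %in% stops) break
      seg[p] <- old
    }
  }
  remaining <- nsub - length(picks)
  if (remaining > 0) {  # overflow onto non-CDS copy bases
    noncds <- setdiff(seq_len(n), cds_rel)
    extra <- sample(noncds, min(remaining, length(noncds)))
    for (p in extra) seg[p] <- sample(setdiff(.BASES, seg[p]), 1)
  }
  seg
}
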