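# generate_panel(): orchestrates slot design, per-genome assembly, variant
# planting, associate-haplotype construction and file emission, and builds
# the truth tables that downstream stages are scored against.

# place one interval of each requested length into the free runs
# (data.frame start/end, 0-based half-open), splitting runs as used
.place_intervals <- function(runs, lengths) {
  starts <- integer(length(lengths))
  for (k in seq_along(lengths)) {
    len <- lengths[k]
    ok <- which(runs$end - runs$start >= len + 2L)
    if (!length(ok)) {
      stop("capacity error: no free interval of length ", len,
           " left for planted features")
    }
    w <- runs$end[ok] - runs$start[ok]
    i <- ok[sample.int(length(ok), 1L, prob = w)]
    s <- runs$start[i] + sample.int(runs$end[i] - runs$start[i] - len, 1L) - 1L
    starts[k] <- s
    left <- data.frame(start = runs$start[i], end = s)
    right <- data.frame(start = s + len, end = runs$end[i])
    runs <- rbind(runs[-i, , drop = FALSE],
                  left[left$end - left$start > 0, , drop = FALSE],
                  right[right$end - right$start > 0, , drop = FALSE])
  }
  list(starts = starts, runs = runs)
}

# genomic position + ref/alt of a planted CDS or intron SNP for one gene
.plant_gene_snp <- function(gene, template, kind) {
  if (kind == "intron") {
    pos <- gene$start + 450L
    ref <- if (gene$strand == "+") template$plus[451L] else template$minus[451L]
    alt <- .BASES[(match(ref, .BASES)) %% 4L + 1L]
    return(list(pos = pos, ref = ref, alt = alt))
  }
  # missense: transcript codon 50, middle position (2nd-position changes
  # are always nonsynonymous); avoid creating a stop codon
  t <- (50L - 1L) * 3L + 2L  # transcript coordinate, 1-based
  codon <- substr(template$cds, 149L - 1L, 149L + 1L)
  ref_tx <- substr(template$cds, t, t)
  stops <- c("TAA", "TAG", "TGA")
  alt_tx <- NA_character_
  for (b in setdiff(.BASES, ref_tx)) {
    cand <- codon
    substr(cand, 2L, 2L) <- b
    if (!cand %in% stops) { alt_tx <- b; break }
  }
  # transcript -> genome coordinate (exon1 = transcript 1..300)
  if (gene$strand == "+") {
    g0 <- if (t <= 300L) gene$start + t - 1L else gene$start + 600L + (t - 301L)
    ref <- ref_tx; alt <- alt_tx
  } else {
    g0 <- if (t <= 900L) gene$start + .GENE_LEN - t else gene$start + 1200L - t
    ref <- unname(.COMP[ref_tx]); alt <- unname(.COMP[alt_tx])
  }
  list(pos = g0, ref = ref, alt = alt)
}

# plant all inter-haplotype variants for one genome; returns the variant
# table (primary coordinates) plus per-chromosome bookkeeping
.plant_variants <- function(cfg, gb, roles, plan, g) {
  L <- cfg$chrom_length
  zone_start <- floor(0.90 * L)
  genes <- gb$genes
  vl <- list()
  add <- function(chrom, pos, ref, alt, svtype, len, role, slot = NA_character_) {
    vl[[length(vl) + 1L]] <<- data.frame(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      svtype = svtype, length = as.integer(len), role = role, slot = slot,
      stringsAsFactors = FALSE)
  }
  pchar <- gb$primary
  slot_gene <- function(s) genes[genes$slot == s & genes$origin != "sd_copy", ][1, ]

  for (s in roles$hemi) {
    gn <- slot_gene(s)
    dstart <- gn$start - 20L
    dend <- gn$end + 20L
    pos <- dstart - 1L
    ref <- paste0(pchar[[gn$chrom]][(pos + 1L):dend], collapse = "")
    add(gn$chrom, pos, ref, substr(ref, 1L, 1L), "DEL", dend - dstart,
        "hemizygous_deletion", s)
  }
  for (s in roles$phet) {
    gn <- slot_gene(s)
    sv <- .plant_gene_snp(gn, plan$template[[s]], "missense")
    add(gn$chrom, sv$pos, sv$ref, sv$alt, "SNP", 0L, "missense_snp", s)
  }
  for (s in roles$ghet) {
    gn <- slot_gene(s)
    sv <- .plant_gene_snp(gn, plan$template[[s]], "intron")
    add(gn$chrom, sv$pos, sv$ref, sv$alt, "SNP", 0L, "intron_snp", s)
  }

  # background variants live outside gene spans and the duplication zone
  planted <- if (length(vl)) do.call(rbind, vl) else NULL
  n_hemi <- length(roles$hemi)
  n_bg_del <- max(0L, cfg$sv_deletion_count - n_hemi)
  for (ch_i in seq_len(cfg$chrom_count)) {
    ch <- paste0("chr", ch_i)
    mask <- IRanges::IRanges(start = c(1L, L - 49L), end = c(50L, L))
    gsub <- genes[genes$chrom == ch, ]
    if (nrow(gsub)) {
      mask <- c(mask, IRanges::IRanges(gsub$start + 1L - 25L,
                                       gsub$end + 25L))
    }
    mask <- c(mask, IRanges::IRanges(zone_start + 1L, L))
    if (!is.null(planted)) {
      psub <- planted[planted$chrom == ch, ]
      if (nrow(psub)) {
        mask <- c(mask, IRanges::IRanges(
          psub$pos + 1L, psub$pos + pmax(1L, psub$length + 1L)))
      }
    }
    free <- IRanges::gaps(IRanges::reduce(mask), start = 1L, end = L)
    runs <- data.frame(start = IRanges::start(free) - 1L,
                       end = IRanges::end(free))
    free_bases <- sum(runs$end - runs$start)

    # structural background first (they consume runs), SNPs afterwards
    sv_del_len <- sample(100:800, ceiling(n_bg_del / cfg$chrom_count),
                         replace = TRUE)
    sv_ins_len <- sample(50:500, ceiling(cfg$sv_insertion_count /
                                           cfg$chrom_count), replace = TRUE)
    inv_len <- rep(200L, ceiling(cfg$sv_inversion_count / cfg$chrom_count))
    n_indel <- rbinom(1, free_bases, cfg$small_indel_rate)
    indel_len <- sample(2:30, n_indel, replace = TRUE)
    all_len <- c(sv_del_len + 1L, sv_ins_len, inv_len, indel_len + 1L)
    placed <- .place_intervals(runs, all_len)
    runs <- placed$runs
    idx <- 0L
    for (len in sv_del_len) {
      idx <- idx + 1L
      pos <- placed$starts[idx]
      ref <- paste0(pchar[[ch]][(pos + 1L):(pos + 1L + len)], collapse = "")
      add(ch, pos, ref, substr(ref, 1L, 1L), "DEL", len, "background_sv")
    }
    for (len in sv_ins_len) {
      idx <- idx + 1L
      pos <- placed$starts[idx]
      ref <- pchar[[ch]][pos + 1L]
      add(ch, pos, ref, paste0(c(ref, .rand_chars(len)), collapse = ""),
          "INS", len, "background_sv")
    }
    for (len in inv_len) {
      idx <- idx + 1L
      pos <- placed$starts[idx]
      add(ch, pos, pchar[[ch]][pos + 1L], "<INV>", "INV", len,
          "background_sv")
    }
    half <- length(indel_len) %/% 2L
    for (j in seq_along(indel_len)) {
      idx <- idx + 1L
      pos <- placed$starts[idx]
      len <- indel_len[j]
      if (j <= half) {
        ref <- paste0(pchar[[ch]][(pos + 1L):(pos + 1L + len)], collapse = "")
        add(ch, pos, ref, substr(ref, 1L, 1L), "DEL", len, "background_indel")
      } else {
        ref <- pchar[[ch]][pos + 1L]
        add(ch, pos, ref, paste0(c(ref, .rand_chars(len)), collapse = ""),
            "INS", len, "background_indel")
      }
    }
    # SNPs on remaining free positions
    n_snp <- rbinom(1, free_bases, cfg$snp_rate)
    pos_pool <- unlist(lapply(seq_len(nrow(runs)), function(i)
      seq.int(runs$start[i], runs$end[i] - 1L)))
    snp_pos <- sort(sample(pos_pool, min(n_snp, length(pos_pool))))
    for (pos in snp_pos) {
      ref <- pchar[[ch]][pos + 1L]
      add(ch, pos, ref, .BASES[match(ref, .BASES) %% 4L + 1L], "SNP", 0L,
          "background_snp")
    }
  }
  if (!length(vl)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      svtype = character(), length = integer(),
                      role = character(), slot = character(),
                      id = character(), stringsAsFactors = FALSE))
  }
  variants <- do.call(rbind, vl)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  variants$id <- paste0(g, "_v", sprintf("%05d", seq_len(nrow(variants))))
  rownames(variants) <- NULL
  variants
}

# apply the planted variants to the primary haplotype of one chromosome;
# emits the associate sequence, the inter-haplotype alignment blocks and
# the associate-side coordinate of every variant
.build_associate <- function(primary, variants) {
  L <- length(primary)
  template <- primary
  snps <- variants[variants$svtype == "SNP", ]
  if (nrow(snps)) template[snps$pos + 1L] <- snps$alt
  parts <- list()
  blocks <- list()
  r <- 0L; q <- 0L
  b_rstart <- 0L; b_qstart <- 0L; b_mm <- 0L
  apos <- rep(NA_integer_, nrow(variants))
  push_seg <- function(upto) {
    if (upto > r) {
      parts[[length(parts) + 1L]] <<- template[(r + 1L):upto]
      q <<- q + (upto - r); r <<- upto
    }
  }
  close_block <- function() {
    len <- r - b_rstart
    if (len > 0L) {
      blocks[[length(blocks) + 1L]] <<- data.frame(
        qstart = b_qstart, qend = q, rstart = b_rstart, rend = r,
        strand = "+", mismatches = b_mm, identity = 1 - b_mm / len)
    }
    b_mm <<- 0L
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$svtype == "SNP") {
      push_seg(v$pos + 1L)
      apos[i] <- q - 1L
      b_mm <- b_mm + 1L
    } else if (v$svtype == "DEL") {
      push_seg(v$pos + 1L)
      apos[i] <- q - 1L
      close_block()
      r <- r + v$length
      b_rstart <- r; b_qstart <- q
    } else if (v$svtype == "INS") {
      push_seg(v$pos + 1L)
      apos[i] <- q - 1L
      close_block()
      ins <- strsplit(substring(v$alt, 2L), "")[[1]]
      parts[[length(parts) + 1L]] <- ins
      q <- q + length(ins)
      b_rstart <- r; b_qstart <- q
    } else if (v$svtype == "INV") {
      push_seg(v$pos)
      close_block()
      apos[i] <- q
      seg <- .revcomp_chars(primary[(v$pos + 1L):(v$pos + v$length)])
      parts[[length(parts) + 1L]] <- seg
      q <- q + v$length; r <- r + v$length
      b_rstart <- r; b_qstart <- q
    }
  }
  push_seg(L)
  close_block()
  list(assoc = unlist(parts),
       blocks = if (length(blocks)) do.call(rbind, blocks) else
         data.frame(qstart = integer(), qend = integer(), rstart = integer(),
                    rend = integer(), strand = character(),
                    mismatches = integer(), identity = numeric()),
       apos = apos)
}

#' Generate the synthetic genome panel
#'
#' Emits, for every genome of the panel, a primary and an associate
#' haplotype (FASTA), gene models (GFF3), TE and protein-domain
#' annotations, an inter-haplotype VCF, haplotype and inter-chromosomal
#' alignment blocks, homology hit tables, read-evidence counts and an
#' expression count table -- plus machine-readable ground truth for every
#' downstream stage.  All inter-genome relations come from construction
#' bookkeeping, not from running an aligner.  Identical config and seed
#' give byte-identical output trees.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `dir`, `genomes`, and `truth` (a list of
#'   data.frames: genes, variants, heterozygosity, te_groups, trio,
#'   sd_pairs, nlr, expression, plus the realised config).
#' @export
generate_panel <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  slots <- .design_slots(cfg)
  n_slots <- length(slots$slot_id)

  # ancestral gene templates (shared across genomes)
  nonstop <- setdiff(.all_codons(), c("TAA", "TAG", "TGA"))
  template <- lapply(seq_len(n_slots), function(i) {
    cds <- paste0(c("ATG", sample(nonstop, 398, replace = TRUE), "TAA"),
                  collapse = "")
    intron <- .rand_chars(300L)
    cdsc <- strsplit(cds, "")[[1]]
    plus <- c(cdsc[1:300], intron, cdsc[301:1200])
    minus <- c(.revcomp_chars(cdsc[901:1200]), intron,
               .revcomp_chars(cdsc[1:900]))
    list(cds = cds, plus = plus, minus = minus)
  })
  names(template) <- slots$slot_id

  # translocated slots: all-shared slots moved in one genome each
  all_ids <- slots$slot_id[slots$all_shared]
  n_trans <- min(6L, length(all_ids))
  trans_slots <- sample(all_ids, n_trans)
  translocated_in <- setNames(
    cfg$genomes[(seq_len(n_trans) - 1L) %% length(cfg$genomes) + 1L],
    trans_slots)

  nlr <- .design_nlr(cfg, slots)

  # duplicate-origin genome-specific slots: most specific slots descend
  # from an all-shared source by duplication
  spec_ids <- slots$slot_id[rowSums(slots$membership) == 1]
  dup_take <- spec_ids[seq_len(floor(0.8 * length(spec_ids)))]
  dup_take <- setdiff(dup_take, nlr$extra)
  dup_source <- setNames(
    sample(setdiff(all_ids, c(trans_slots, nlr$core)), length(dup_take),
           replace = length(all_ids) < length(dup_take)),
    dup_take)

  # SD plan: source genes on chr1, shared by construction across genomes
  sd_pool <- setdiff(slots$per_chrom[[1]][
    slots$all_shared[slots$per_chrom[[1]]]],
    c(nlr$core, trans_slots, unname(dup_source)))
  if (length(sd_pool) < cfg$sd_count) {
    stop("capacity error: not enough eligible source genes for sd_count")
  }
  sd_sources <- sample(sd_pool, cfg$sd_count)
  m_multi <- floor(cfg$sd_count / 2)
  sd_n_copies <- as.list(c(rep(2L, m_multi),
                           rep(1L, cfg$sd_count - m_multi)))
  sd_intact <- lapply(seq_len(cfg$sd_count), function(i) {
    if (i <= m_multi) {
      if (i == m_multi) c(TRUE, TRUE) else c(TRUE, FALSE)
    } else TRUE
  })
  sd_positive <- lapply(seq_len(cfg$sd_count), function(i) {
    p <- rep(FALSE, sd_n_copies[[i]])
    if (i %% 5 == 1) p[1] <- TRUE
    p
  })

  te <- .design_te(cfg, slots, nlr, blocked_slots = trans_slots)

  # genotyping demonstration slots (hom TE / het TE / no TE upstream)
  const_slots <- names(te$pattern)[te$pattern == "constant"]
  none_slots <- setdiff(slots$slot_id[slots$all_shared],
                        c(names(te$pattern)[te$pattern != "none"],
                          trans_slots, sd_sources))
  genotype_status <- c(
    setNames(rep("hom_te", min(2L, length(const_slots))),
             head(const_slots, 2L)),
    setNames(rep("het_te", min(2L, max(0L, length(const_slots) - 2L))),
             head(const_slots[-(1:2)], 2L)),
    setNames(rep("hom_no_te", min(2L, length(none_slots))),
             head(none_slots, 2L)))

  base_expr <- setNames(round(runif(n_slots, 4, 8), 3), slots$slot_id)

  plan <- list(template = template, translocated_in = translocated_in,
               dup_source = dup_source, sd_sources = sd_sources,
               sd_n_copies = sd_n_copies, sd_intact = sd_intact,
               sd_positive = sd_positive, base = base_expr,
               genotype_status = genotype_status)

  n_hemi <- round(cfg$sv_deletion_count * cfg$gene_deleting_fraction)

  truth_genes <- list(); truth_vars <- list(); truth_het <- list()
  truth_sd <- list(); trio_rows <- list()
  genome_out <- list()

  for (g in cfg$genomes) {
    gb <- .build_genome(cfg, slots, nlr, plan, g)
    genes <- gb$genes

    # role selection (hemizygous / protein-het / gene-het-only)
    member_slots <- genes$slot[genes$origin == "slot"]
    blocked <- c(sd_sources, names(genotype_status), trans_slots,
                 unname(dup_source))
    eligible_all <- intersect(member_slots,
                              setdiff(all_ids, c(blocked, nlr$core)))
    if (g == cfg$trio_offspring) {
      notA <- member_slots[!slots$membership[member_slots,
                                             cfg$trio_parent_a]]
      notA <- setdiff(notA, blocked)
      origins <- rep(c("from_parentA", "from_parentB", "both_present",
                       "unexplained"), length.out = n_hemi)
      n_inA <- sum(origins %in% c("from_parentA", "both_present"))
      n_notA <- n_hemi - n_inA
      if (length(eligible_all) < n_inA || length(notA) < n_notA) {
        stop("capacity error: not enough eligible genes for the trio plan")
      }
      pickA <- sample(eligible_all, n_inA)
      pickN <- sample(notA, n_notA)
      hemi <- character(n_hemi)
      hemi[origins %in% c("from_parentA", "both_present")] <- pickA
      hemi[!origins %in% c("from_parentA", "both_present")] <- pickN
      trio_origin <- setNames(origins, hemi)
      eligible_all <- setdiff(eligible_all, hemi)
    } else {
      if (length(eligible_all) < n_hemi + cfg$protein_het_count +
          cfg$gene_het_count) {
        stop("capacity error: not enough eligible genes for planted classes")
      }
      hemi <- sample(eligible_all, n_hemi)
      trio_origin <- NULL
      eligible_all <- setdiff(eligible_all, hemi)
    }
    phet <- sample(eligible_all, cfg$protein_het_count)
    eligible_all <- setdiff(eligible_all, phet)
    ghet <- sample(eligible_all, cfg$gene_het_count)
    roles <- list(hemi = hemi, phet = phet, ghet = ghet)

    variants <- .plant_variants(cfg, gb, roles, plan, g)

    # associate haplotype + alignment blocks per chromosome
    assoc <- list(); hblocks <- list()
    apos <- rep(NA_integer_, nrow(variants))
    for (ch in names(gb$primary)) {
      sel <- which(variants$chrom == ch)
      ba <- .build_associate(gb$primary[[ch]], variants[sel, , drop = FALSE])
      assoc[[ch]] <- ba$assoc
      if (nrow(ba$blocks)) {
        ba$blocks <- cbind(qchrom = ch, ba$blocks[, c("qstart", "qend")],
                           rchrom = ch, ba$blocks[, c("rstart", "rend",
                                                      "strand", "identity",
                                                      "mismatches")])
        hblocks[[ch]] <- ba$blocks
      }
      apos[sel] <- ba$apos
      vsub <- variants[sel, ]
      ins_b <- sum(vsub$length[vsub$svtype == "INS"])
      inv_b <- sum(vsub$length[vsub$svtype == "INV"])
      nsnp <- sum(vsub$svtype == "SNP")
      truth_het[[paste(g, ch)]] <- data.frame(
        genome = g, chrom = ch, assoc_length = length(ba$assoc),
        unaligned_planted = ins_b + inv_b, snps_planted = nsnp,
        expected_pct = 100 * (ins_b + inv_b + nsnp) / length(ba$assoc),
        stringsAsFactors = FALSE)
    }
    variants$apos <- apos
    hblocks <- do.call(rbind, hblocks)

    # planted zygosity truth
    zy <- setNames(rep("homozygous", nrow(genes)), genes$gene_id)
    # paste0() maps zero-length inputs to "", so guard empty role sets
    if (length(roles$hemi)) zy[paste0(g, "_", roles$hemi)] <- "hemizygous"
    if (length(roles$phet)) zy[paste0(g, "_", roles$phet)] <- "protein_het"
    if (length(roles$ghet)) zy[paste0(g, "_", roles$ghet)] <- "gene_het_only"

    # shared-class truth from membership and translocation bookkeeping
    others <- setdiff(cfg$genomes, g)
    shared <- vapply(seq_len(nrow(genes)), function(i) {
      if (genes$origin[i] != "slot") return("genome_specific")
      s <- genes$slot[i]
      if (!is.na(translocated_in[s]) && translocated_in[s] == g &&
          s %in% names(translocated_in)) return("genome_specific")
      pres <- vapply(others, function(o) {
        slots$membership[s, o] &&
          !(s %in% names(translocated_in) && translocated_in[s] == o)
      }, logical(1))
      p <- sort(others[pres])
      wild_o <- sort(intersect(others, cfg$wild_labels))
      cult_o <- sort(intersect(others, cfg$cultivated_labels))
      if (length(p) == length(others)) "all_shared"
      else if (!length(p)) "genome_specific"
      else if (length(cult_o) && identical(p, cult_o)) "cultivated_shared"
      else if (length(wild_o) && identical(p, wild_o)) "wild_shared"
      else "other_pattern"
    }, character(1))

    is_nlr_slot <- genes$slot %in% c(nlr$core, nlr$extra) &
      genes$origin != "sd_copy"
    nlr_sub <- ifelse(is_nlr_slot, nlr$subgroup[genes$slot], NA_character_)

    te_up <- ifelse(genes$origin == "slot", te$prop[genes$slot, g], 0)
    gt <- plan$genotype_status[genes$slot]
    te_up_assoc <- ifelse(!is.na(gt) & gt == "het_te", 0, te_up)

    truth_genes[[g]] <- data.frame(
      genome = g, gene_id = genes$gene_id, slot = genes$slot,
      chrom = genes$chrom, start = genes$start, end = genes$end,
      strand = genes$strand, origin = genes$origin,
      planted_class = unname(zy),
      final_class = ifelse(zy == "gene_het_only", "homozygous", unname(zy)),
      shared_class = shared, is_nlr = is_nlr_slot, nlr_subgroup = nlr_sub,
      te_up_primary = te_up, te_up_associate = te_up_assoc,
      te_genotype = ifelse(is.na(gt), NA_character_, gt),
      base_expr = unname(base_expr[genes$slot]),
      stringsAsFactors = FALSE)

    variants$size_class <- ifelse(
      variants$svtype == "SNP", "SNP",
      ifelse(variants$svtype == "INV" | variants$length > 30, "SV",
             "small_indel"))
    truth_vars[[g]] <- cbind(genome = rep(g, nrow(variants)), variants)
    if (!is.null(gb$sd_pairs)) truth_sd[[g]] <- gb$sd_pairs

    if (!is.null(trio_origin)) {
      for (s in names(trio_origin)) {
        gn <- genes[genes$slot == s & genes$origin != "sd_copy", ][1, ]
        trio_rows[[s]] <- data.frame(
          gene_id = gn$gene_id, slot = s, chrom = gn$chrom,
          start = gn$start, end = gn$end, origin_truth = trio_origin[[s]],
          stringsAsFactors = FALSE)
      }
    }

    genome_out[[g]] <- list(genes = genes, primary = gb$primary,
                            assoc = assoc, variants = variants,
                            hblocks = hblocks, sd_blocks = gb$sd_blocks,
                            roles = roles, zygosity = zy)
  }

  truth <- list(
    genes = do.call(rbind, truth_genes),
    variants = do.call(rbind, truth_vars),
    heterozygosity = do.call(rbind, truth_het),
    sd_pairs = do.call(rbind, truth_sd),
    trio = if (length(trio_rows)) do.call(rbind, trio_rows) else NULL,
    nlr = data.frame(slot = names(nlr$subgroup),
                     subgroup = unname(nlr$subgroup),
                     stringsAsFactors = FALSE),
    te_groups = .truth_te_groups(cfg, slots, te, trans_slots),
    config = cfg)
  rownames(truth$genes) <- rownames(truth$variants) <- NULL

  # expression
  prof <- do.call(rbind, lapply(cfg$genomes, function(g) {
    tg <- truth_genes[[g]]
    data.frame(gene_id = tg$gene_id, genome = g, base = tg$base_expr,
               proportion = tg$te_up_primary, stringsAsFactors = FALSE)
  }))
  expr <- generate_expression(prof, cfg)
  truth$expression <- expr$expected

  .write_panel(cfg, out_dir, slots, nlr, te, plan, genome_out, truth, expr)
  invisible(list(dir = out_dir, genomes = cfg$genomes, truth = truth))
}

.truth_te_groups <- function(cfg, slots, te, trans_slots) {
  ok <- slots$all_shared & !(slots$slot_id %in% trans_slots)
  ids <- slots$slot_id[ok]
  df <- data.frame(slot = ids, pattern = te$pattern[ids],
                   stringsAsFactors = FALSE)
  props <- te$prop[ids, , drop = FALSE]
  colnames(props) <- paste0("prop_", colnames(props))
  df <- cbind(df, as.data.frame(props))
  df$is_polymorphic <- apply(te$prop[ids, , drop = FALSE], 1, function(p)
    min(p) == 0 && max(p) >= 0.20)
  rownames(df) <- NULL
  df
}
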