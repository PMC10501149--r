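# File emission for the synthetic panel: FASTA haplotypes, GFF3 gene
# models, TE/domain annotations, VCF, alignment blocks, homology hits,
# expression counts, read evidence, trio coverage and truth tables.

.gene_models_df <- function(genes) {
  feats <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]
    data.frame(
      gene_id = genes$gene_id[i],
      type = c("exon", "exon", "CDS", "CDS"),
      start = c(s + .EXON1[1], s + .EXON2[1], s + .EXON1[1], s + .EXON2[1]),
      end = c(s + .EXON1[2], s + .EXON2[2], s + .EXON1[2], s + .EXON2[2]),
      phase = c(NA_integer_, NA_integer_, 0L, 0L),
      stringsAsFactors = FALSE)
  }))
  list(genes = data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                          strand = genes$strand, start = genes$start,
                          end = genes$end, stringsAsFactors = FALSE),
       features = feats)
}

.te_annotations <- function(cfg, slots, te, genes, g) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    if (genes$origin[i] != "slot") next
    s <- genes$slot[i]
    p <- te$prop[s, g]
    num <- as.integer(substring(s, 2))
    if (p > 0) {
      len <- as.integer(round(cfg$flank * p))
      if (genes$strand[i] == "+") {
        st <- genes$start[i] - cfg$flank + 50L
      } else {
        st <- genes$end[i] + 50L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = st, end = st + len,
        name = if (num %% 2 == 0) "LTR" else "MITE", score = 0L,
        strand = "+", stringsAsFactors = FALSE)
    }
    if (num %% 9 == 0) {  # occasional intronic TE
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = genes$start[i] + 320L,
        end = genes$start[i] + 470L, name = "MITE", score = 0L,
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

.domain_annotations <- function(slots, nlr, genes) {
  coords <- list(TIR = c(5L, 180L), CC = c(5L, 150L), CC_R = c(5L, 160L),
                 `NB-ARC` = c(200L, 500L), LRR = c(520L, 700L))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    if (genes$origin[i] == "sd_copy") next
    s <- genes$slot[i]
    if (!s %in% names(nlr$subgroup)) next
    doms <- .domain_set(nlr$subgroup[[s]])
    for (d in doms) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], domain = d,
        start = coords[[d]][1], end = coords[[d]][2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), domain = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

.write_panel <- function(cfg, out_dir, slots, nlr, te, plan, genome_out,
                         truth, expr) {
  for (g in cfg$genomes) {
    go <- genome_out[[g]]
    gdir <- file.path(out_dir, g)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    prim <- Biostrings::DNAStringSet(vapply(go$primary, paste0,
                                            character(1), collapse = ""))
    names(prim) <- names(go$primary)
    .write_fasta(prim, file.path(gdir, "primary.fasta"))
    assoc <- Biostrings::DNAStringSet(vapply(go$assoc, paste0,
                                             character(1), collapse = ""))
    names(assoc) <- names(go$assoc)
    .write_fasta(assoc, file.path(gdir, "associate.fasta"))

    write_gene_models(.gene_models_df(go$genes),
                      file.path(gdir, "genes.gff3"))
    write_variant_calls(go$variants[, c("chrom", "pos", "id", "ref", "alt",
                                        "svtype", "length")],
                        file.path(gdir, "variants.vcf"),
                        reference = paste0(g, "_primary"))
    write_alignment_blocks(go$hblocks,
                           file.path(gdir, "haplotype_blocks.tsv"))
    write_alignment_blocks(go$sd_blocks, file.path(gdir, "sd_blocks.tsv"))

    tes <- .te_annotations(cfg, slots, te, go$genes, g)
    write_bed(tes, file.path(gdir, "te.bed"))

    tg <- truth$genes[truth$genes$genome == g, ]
    .write_tsv(data.frame(gene_id = tg$gene_id,
                          prop_up_primary = tg$te_up_primary,
                          prop_up_associate = tg$te_up_associate,
                          stringsAsFactors = FALSE),
               file.path(gdir, "te_haplotype.tsv"),
               "upstream TE proportion per haplotype")

    doms <- .domain_annotations(slots, nlr, go$genes)
    # integrated domains planted per (slot, genome)
    idg <- nlr$ids[nlr$ids$genome == g, , drop = FALSE]
    if (nrow(idg)) {
      present <- go$genes$slot[go$genes$origin != "sd_copy"]
      idg <- idg[idg$slot %in% present, , drop = FALSE]
      if (nrow(idg)) {
        doms <- rbind(doms, data.frame(
          gene_id = paste0(g, "_", idg$slot), domain = idg$id,
          start = 720L, end = 800L, stringsAsFactors = FALSE))
      }
    }
    # a receptor-like decoy without NB-ARC
    decoy <- go$genes$gene_id[go$genes$origin == "slot" &
                                !go$genes$slot %in% names(nlr$subgroup)][1]
    doms <- rbind(doms, data.frame(gene_id = decoy, domain = "LRR",
                                   start = 10L, end = 200L,
                                   stringsAsFactors = FALSE))
    doms <- doms[order(doms$gene_id, doms$domain), , drop = FALSE]
    .write_tsv(doms, file.path(gdir, "domains.tsv"),
               "protein domain annotations (protein coordinates, 1-based)")

    cm <- expr$counts[[g]]
    .write_tsv(cbind(data.frame(gene_id = rownames(cm),
                                stringsAsFactors = FALSE),
                     as.data.frame(cm)),
               file.path(gdir, "counts.tsv"), "raw RNA-seq counts")

    ev <- do.call(rbind, lapply(seq_len(nrow(go$genes)), function(i) {
      z <- go$zygosity[go$genes$gene_id[i]]
      ra <- simulate_read_alignments(
        if (identical(unname(z), "hemizygous")) "hemizygous" else "homozygous",
        cfg$read_depth)
      data.frame(gene_id = go$genes$gene_id[i], spanning = ra$spanning,
                 split = ra$split, stringsAsFactors = FALSE)
    }))
    .write_tsv(ev, file.path(gdir, "read_evidence.tsv"),
               "simulated spanning/split read counts per gene locus")

    # unplaced-contig genes: low homology to placed genes by construction
    unp <- Biostrings::DNAStringSet(vapply(1:3, function(i)
      paste0(.rand_chars(900L), collapse = ""), character(1)))
    names(unp) <- paste0(g, "_unplaced", 1:3)
    .write_fasta(unp, file.path(gdir, "unplaced.fasta"))
    .write_tsv(data.frame(
      gene_id = go$genes$gene_id[1:2],
      unplaced_id = names(unp)[1:2],
      identity = c(0.32, 0.40), coverage = c(0.50, 0.30),
      stringsAsFactors = FALSE),
      file.path(gdir, "unplaced_hits.tsv"),
      "alignments of placed genes against unplaced-contig genes")
  }

  # homology hits (one best hit per query) and within-genome paralog hits
  hdir <- file.path(out_dir, "hits")
  sdir <- file.path(out_dir, "self_hits")
  dir.create(hdir, showWarnings = FALSE)
  dir.create(sdir, showWarnings = FALSE)
  for (a in cfg$genomes) {
    ga <- genome_out[[a]]$genes
    for (b in setdiff(cfg$genomes, a)) {
      keep <- ga$origin != "sd_copy" & slots$membership[ga$slot, b]
      sub <- ga[keep, , drop = FALSE]
      num <- as.integer(substring(sub$slot, 2))
      hits <- data.frame(
        geneA = sub$gene_id, geneB = paste0(b, "_", sub$slot),
        bitscore = 600L + num %% 90L,
        evalue = 10^-(60L + num %% 40L), stringsAsFactors = FALSE)
      write_homology_hits(hits, file.path(hdir, paste0(a, "__", b, ".tsv")))
    }
    rows <- list()
    dup_here <- ga$slot %in% names(plan$dup_source) & ga$origin == "slot"
    for (i in which(dup_here)) {
      src <- plan$dup_source[[ga$slot[i]]]
      src_gene <- ga$gene_id[ga$slot == src & ga$origin == "slot"]
      if (length(src_gene)) {
        rows[[length(rows) + 1L]] <- data.frame(
          geneA = ga$gene_id[i], geneB = src_gene[1], bitscore = 420L,
          evalue = 1e-60, stringsAsFactors = FALSE)
      }
    }
    for (i in which(ga$origin == "sd_copy")) {
      src_gene <- ga$gene_id[ga$slot == ga$slot[i] & ga$origin == "slot"]
      rows[[length(rows) + 1L]] <- data.frame(
        geneA = ga$gene_id[i], geneB = src_gene[1], bitscore = 500L,
        evalue = 1e-80, stringsAsFactors = FALSE)
    }
    self <- if (length(rows)) do.call(rbind, rows) else
      data.frame(geneA = character(), geneB = character(),
                 bitscore = numeric(), evalue = numeric(),
                 stringsAsFactors = FALSE)
    write_homology_hits(self, file.path(sdir, paste0(a, ".tsv")))
  }

  # RPV loci on the wild reference genome, anchored to the dense NLR
  # cluster plus one unlinked locus
  ref_g <- cfg$wild_labels[1]
  refg <- genome_out[[ref_g]]$genes
  big <- refg[refg$slot %in% nlr$cluster_big, , drop = FALSE]
  if (nrow(big)) {
    span <- range(c(big$start, big$end))
    mid <- floor(mean(span))
    rpv <- data.frame(
      chrom = c(big$chrom[1], big$chrom[1], "chr1"),
      start = c(max(0L, span[1] - 5000L), mid, 200000L),
      end = c(mid, span[2] + 5000L, 260000L),
      name = c("RPV1", "RPV2", "RPV3"), stringsAsFactors = FALSE)
    write_bed(rpv, file.path(out_dir, "rpv.bed"))
  }

  # parent-B read coverage over the offspring's hemizygous loci
  if (!is.null(truth$trio)) {
    rows <- list()
    for (i in seq_len(nrow(truth$trio))) {
      tr <- truth$trio[i, ]
      full <- tr$origin_truth %in% c("from_parentB", "both_present")
      s <- tr$start - 50L; e <- tr$end + 50L
      if (full) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = tr$chrom, start = s, end = e, name = tr$gene_id,
          score = 30L, stringsAsFactors = FALSE)
      } else {
        mid <- floor((tr$start + tr$end) / 2)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = tr$chrom, start = c(s, mid + 10L), end = c(mid, e),
          name = tr$gene_id, score = 30L, stringsAsFactors = FALSE)
      }
    }
    write_bed(do.call(rbind, rows), file.path(out_dir, "trio_coverage.bed"))
  }

  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  .write_tsv(truth$genes, file.path(tdir, "genes.tsv"),
             "planted per-gene ground truth")
  .write_tsv(truth$variants, file.path(tdir, "variants.tsv"),
             "planted variants (primary coordinates, 0-based)")
  .write_tsv(truth$heterozygosity, file.path(tdir, "heterozygosity.tsv"),
             "expected intragenomic variation per chromosome")
  .write_tsv(truth$te_groups, file.path(tdir, "te_groups.tsv"),
             "upstream TE proportions per collinear group")
  if (!is.null(truth$trio)) {
    .write_tsv(truth$trio, file.path(tdir, "trio.tsv"),
               "planted parental origin of offspring hemizygous genes")
  }
  .write_tsv(truth$sd_pairs, file.path(tdir, "sd_pairs.tsv"),
             "planted segmental duplications")
  invisible(NULL)
}

#' Fraction of each gene body covered by a depth track
#'
#' @param genes Gene span data.frame (gene_id, chrom, start, end).
#' @param coverage Data.frame (chrom, start, end) of intervals covered at
#'   depth >= 1 (0-based half-open).
#' @return Named numeric vector of covered fractions in \[0,1\].
#' @export
gene_covered_fraction <- function(genes, coverage) {
  gr_c <- GenomicRanges::reduce(GenomicRanges::GRanges(
    coverage$chrom, IRanges::IRanges(coverage$start + 1L, coverage$end)))
  out <- setNames(numeric(nrow(genes)), genes$gene_id)
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_g, gr_c)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    inter <- pmin(GenomicRanges::end(gr_g)[qh],
                  GenomicRanges::end(gr_c)[sh]) -
      pmax(GenomicRanges::start(gr_g)[qh],
           GenomicRanges::start(gr_c)[sh]) + 1L
    agg <- tapply(inter, qh, sum)
    out[as.integer(names(agg))] <- as.numeric(agg) /
      (genes$end - genes$start)[as.integer(names(agg))]
  }
  out
}
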