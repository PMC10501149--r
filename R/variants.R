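# Variant size classes, gene-relative location, and coding effects of
# exonic SNPs via codon comparison with the standard genetic code.

#' Assign the size class of each variant
#'
#' Single-base substitutions are SNPs; insertions/deletions of 1-30 bases
#' are small indels (1-base indels are below the usual caller minimum of 2
#' and are flagged); indels longer than 30 bases, and all inversions,
#' duplications, inverted duplications and breakends, are structural
#' variants.
#'
#' @param variants Data.frame with columns svtype (SNP, DEL, INS, INV,
#'   DUP, INVDUP, BND) and length (absolute REF/ALT length difference).
#' @return Input with columns `size_class` ("SNP", "small_indel", "SV")
#'   and `flagged` (logical, 1-base indels).
#' @export
classify_variant <- function(variants) {
  stopifnot(all(c("svtype", "length") %in% names(variants)))
  always_sv <- c("INV", "DUP", "INVDUP", "BND")
  bad <- !(variants$svtype %in% c("SNP", always_sv)) & variants$length == 0
  if (any(bad)) {
    stop("malformed record: zero-length allele difference for non-SNP type at row(s) ",
         paste(which(bad), collapse = ","))
  }
  size_class <- ifelse(
    variants$svtype == "SNP", "SNP",
    ifelse(variants$svtype %in% always_sv | variants$length > 30, "SV",
           "small_indel"))
  variants$size_class <- size_class
  variants$flagged <- variants$svtype %in% c("DEL", "INS") &
    variants$length == 1
  variants
}

#' Locate variants relative to gene structure
#'
#' A variant overlapping any exon is "exon"; otherwise, if it lies within
#' a gene span, "intron"; otherwise "intergenic".  Variants spanning a
#' boundary take the highest-priority region (exon > intron > intergenic),
#' the most consequential placement.  Multi-gene overlaps report all gene
#' ids.
#'
#' @param variants Data.frame with chrom, pos (0-based) and length; the
#'   affected reference footprint is `[pos, pos + max(1, ref span))`.
#' @param models Gene models list as from [read_gene_models()].
#' @return Input with `region` and comma-separated `gene_ids` columns.
#' @export
locate_variant <- function(variants, models) {
  genes <- models$genes
  exons <- models$features[models$features$type == "exon", , drop = FALSE]
  ref_span <- pmax(1L, ifelse(variants$svtype %in% c("DEL", "INV", "DUP"),
                              variants$length, 1L))
  vr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos + 1L,
                                     variants$pos + ref_span))
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_exon <- GenomicRanges::GRanges(
    genes$chrom[match(exons$gene_id, genes$gene_id)],
    IRanges::IRanges(exons$start + 1L, exons$end))
  ov_gene <- GenomicRanges::findOverlaps(vr, gr_gene)
  ov_exon <- GenomicRanges::findOverlaps(vr, gr_exon)
  in_exon <- unique(S4Vectors::queryHits(ov_exon))
  in_gene <- unique(S4Vectors::queryHits(ov_gene))
  region <- rep("intergenic", nrow(variants))
  region[in_gene] <- "intron"
  region[in_exon] <- "exon"
  ids <- rep("", nrow(variants))
  if (length(ov_gene)) {
    agg <- tapply(genes$gene_id[S4Vectors::subjectHits(ov_gene)],
                  S4Vectors::queryHits(ov_gene),
                  function(x) paste(sort(unique(x)), collapse = ","))
    ids[as.integer(names(agg))] <- unname(agg)
  }
  variants$region <- region
  variants$gene_ids <- ids
  variants
}

#' Coding effect of exonic SNPs by codon comparison
#'
#' For each SNP falling inside a CDS, the reference and alternate codons
#' are translated with the standard genetic code (minus-strand genes via
#' reverse complement): identical amino acids are synonymous, stop gained
#' is nonsense, stop lost is stop_loss, anything else is missense.  SNPs
#' outside all CDS are noncoding.  Genes whose CDS length is not a
#' multiple of 3 are skipped with a warning (effect NA).
#'
#' @param snps Data.frame with chrom, pos (0-based), ref, alt, and ideally
#'   an `id` column.
#' @param models Gene models list (needs CDS features).
#' @param genome `DNAStringSet` of the reference haplotype.
#' @return `snps` with columns `effect` and `effect_gene`.
#' @export
snp_effect <- function(snps, models, genome) {
  genes <- models$genes
  cds <- models$features[models$features$type == "CDS", , drop = FALSE]
  effect <- rep("noncoding", nrow(snps))
  effect_gene <- rep(NA_character_, nrow(snps))

  cds_by_gene <- split(cds, cds$gene_id)
  for (gid in names(cds_by_gene)) {
    gcds <- cds_by_gene[[gid]]
    gi <- match(gid, genes$gene_id)
    chrom <- genes$chrom[gi]
    strand <- genes$strand[gi]
    gcds <- gcds[order(gcds$start), , drop = FALSE]
    total <- sum(gcds$end - gcds$start)
    # genomic positions of the CDS in transcript order (0-based)
    gpos <- unlist(lapply(seq_len(nrow(gcds)),
                          function(i) seq(gcds$start[i], gcds$end[i] - 1L)))
    if (strand == "-") gpos <- rev(gpos)
    cand <- which(snps$chrom == chrom & snps$pos %in% gpos &
                  nchar(snps$ref) == 1L & nchar(snps$alt) == 1L)
    if (!length(cand)) next
    if (total %% 3 != 0) {
      warning("CDS length of ", gid, " not divisible by 3; gene skipped")
      effect[cand] <- NA_character_
      effect_gene[cand] <- gid
      next
    }
    seq <- genome[[chrom]]
    cds_seq <- as.character(seq[sort(gpos) + 1L])
    if (strand == "-") {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
      # gpos already reversed above: gpos[k] is genomic pos of transcript
      # base k, so complement each base when substituting below
    }
    for (i in cand) {
      k <- match(snps$pos[i], gpos)  # 1-based transcript coordinate
      ref_base <- snps$ref[i]
      alt_base <- snps$alt[i]
      if (strand == "-") {
        comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
        ref_base <- comp[[ref_base]]
        alt_base <- comp[[alt_base]]
      }
      if (substr(cds_seq, k, k) != ref_base) {
        warning("reference base mismatch for SNP at ", snps$chrom[i], ":",
                snps$pos[i], " in ", gid)
      }
      codon_i <- (k - 1L) %/% 3L
      codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      off <- (k - 1L) %% 3L + 1L
      alt_codon <- codon
      substr(alt_codon, off, off) <- alt_base
      aa_ref <- .translate_codon(codon)
      aa_alt <- .translate_codon(alt_codon)
      effect[i] <- if (is.na(aa_ref) || is.na(aa_alt)) NA_character_
      else if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else if (aa_ref == "*") "stop_loss"
      else "missense"
      effect_gene[i] <- gid
    }
  }
  snps$effect <- effect
  snps$effect_gene <- effect_gene
  snps
}

.translate_codon <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[[codon]])
}
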