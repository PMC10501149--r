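# Gene zygosity: hemizygous / protein-level heterozygous / homozygous
# classification from inter-haplotype variant calls, with read-evidence
# verdicts and cross-genome comparison at collinear loci.

#' Call hemizygous genes from SV deletions
#'
#' A gene is hemizygous when its full span is contained in a single
#' deletion interval (deletions are not chained).  Genes with a
#' high-homology counterpart among unplaced-contig genes are excluded from
#' the hemizygous set and flagged ambiguous, since the "missing" allele
#' may merely be unassembled.
#'
#' @param deletions Data.frame of SV deletions (chrom, start, end,
#'   0-based half-open; size_class "SV", svtype "DEL").
#' @param genes Data.frame of gene spans (gene_id, chrom, start, end).
#' @param unplaced_hits Optional data.frame (gene_id, identity, coverage)
#'   of alignments between placed genes and unplaced-contig genes.
#' @param homology_identity,homology_coverage Exclusion thresholds
#'   (default 0.90 / 0.90).
#' @return Data.frame: gene_id, hemizygous, ambiguous, deletion index
#'   evidence.
#' @export
call_hemizygous_genes <- function(deletions, genes, unplaced_hits = NULL,
                                  homology_identity = 0.90,
                                  homology_coverage = 0.90) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in input")
  hemi <- logical(nrow(genes))
  evid <- rep(NA_integer_, nrow(genes))
  if (!is.null(deletions) && nrow(deletions) > 0) {
    gr_g <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    gr_d <- GenomicRanges::GRanges(
      deletions$chrom, IRanges::IRanges(deletions$start + 1L, deletions$end))
    ov <- GenomicRanges::findOverlaps(gr_g, gr_d, type = "within")
    hemi[unique(S4Vectors::queryHits(ov))] <- TRUE
    first <- tapply(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov), min)
    evid[as.integer(names(first))] <- as.integer(first)
  }
  ambiguous <- logical(nrow(genes))
  if (!is.null(unplaced_hits) && nrow(unplaced_hits) > 0) {
    strong <- unplaced_hits$identity >= homology_identity &
      unplaced_hits$coverage >= homology_coverage
    amb_ids <- unique(unplaced_hits$gene_id[strong])
    amb <- genes$gene_id %in% amb_ids & hemi
    ambiguous[amb] <- TRUE
    hemi[amb] <- FALSE
  }
  data.frame(gene_id = genes$gene_id, hemizygous = hemi,
             ambiguous = ambiguous, deletion = evid,
             stringsAsFactors = FALSE)
}

#' Read-evidence verdict over a locus
#'
#' Over a hemizygous locus roughly half the reads span the gene (from the
#' haplotype still carrying it) and half are split at its boundary (from
#' the haplotype that lost it), so a split fraction near 0.5 supports
#' hemizygosity; a split fraction near 0 supports homozygosity.  This is a
#' validation layer, not a gate.
#'
#' @param spanning,split Read counts.
#' @param min_depth Total reads required for any verdict (default 10).
#' @param balance_window Half-width of the window around 0.5 that supports
#'   hemizygosity (default 0.2).
#' @param zero_tol Split fraction at or below this supports homozygosity
#'   (default 0.05).
#' @return Character vector of verdicts: supports_hemizygous,
#'   supports_homozygous, or inconclusive (vectorised).
#' @export
evaluate_read_evidence <- function(spanning, split, min_depth = 10L,
                                   balance_window = 0.2, zero_tol = 0.05) {
  stopifnot(all(spanning >= 0), all(split >= 0))
  depth <- spanning + split
  frac <- ifelse(depth > 0, split / depth, NA_real_)
  verdict <- rep("inconclusive", length(depth))
  ok <- depth >= min_depth
  verdict[ok & abs(frac - 0.5) <= balance_window] <- "supports_hemizygous"
  verdict[ok & frac <= zero_tol] <- "supports_homozygous"
  verdict
}

#' Classify every gene's zygosity
#'
#' Hemizygous (full-span containment in a deletion) takes precedence;
#' otherwise a gene is protein-level heterozygous if any exonic indel/SV
#' overlaps it or any exonic SNP changes the protein (missense, nonsense,
#' stop loss); otherwise gene-level heterozygous if any variant overlaps
#' the gene body.  The final three-way class folds gene-level-only genes
#' into homozygous, so hemizygous + protein_het + homozygous always
#' partition the gene set.
#'
#' @param models Gene models list.
#' @param variants Data.frame of classified+located variants (from
#'   [classify_variant()] and [locate_variant()]; SNPs annotated by
#'   [snp_effect()] carry an `effect` column).
#' @param hemi Result of [call_hemizygous_genes()] (or NULL to derive it
#'   from the DEL SVs in `variants`).
#' @return Data.frame: gene_id, hemizygous, protein_het, gene_het,
#'   final_class, evidence (comma-separated variant ids).
#' @export
classify_gene_zygosity <- function(models, variants, hemi = NULL) {
  genes <- models$genes
  if (is.null(hemi)) {
    dels <- variants[variants$size_class == "SV" & variants$svtype == "DEL", ,
                     drop = FALSE]
    dels$end <- dels$pos + dels$length
    dels$start <- dels$pos
    hemi <- call_hemizygous_genes(dels, genes)
  }
  hemi_flag <- setNames(hemi$hemizygous, hemi$gene_id)[genes$gene_id]

  n <- nrow(genes)
  protein <- logical(n); genebody <- logical(n)
  evidence <- vector("list", n)
  names(evidence) <- genes$gene_id
  if (nrow(variants) > 0) {
    vid <- if ("id" %in% names(variants)) variants$id else
      paste0("v", seq_len(nrow(variants)))
    hit_lists <- strsplit(variants$gene_ids, ",", fixed = TRUE)
    is_exonic <- variants$region == "exon"
    protein_causing <- is_exonic &
      (variants$size_class %in% c("small_indel", "SV") |
         (variants$size_class == "SNP" &
            !is.na(variants$effect) &
            variants$effect %in% c("missense", "nonsense", "stop_loss")))
    for (v in seq_len(nrow(variants))) {
      gids <- hit_lists[[v]]
      if (!length(gids) || identical(gids, "")) next
      idx <- match(gids, genes$gene_id)
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      genebody[idx] <- TRUE
      if (protein_causing[v]) protein[idx] <- TRUE
      for (i in idx) evidence[[i]] <- c(evidence[[i]], vid[v])
    }
  }
  final <- ifelse(hemi_flag, "hemizygous",
                  ifelse(protein, "protein_het", "homozygous"))
  data.frame(
    gene_id = genes$gene_id,
    hemizygous = unname(hemi_flag),
    protein_het = !hemi_flag & protein,
    gene_het = !hemi_flag & genebody,
    final_class = unname(final),
    evidence = vapply(evidence, function(e)
      paste(unique(e), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Compare gene zygosity between two genomes at collinear loci
#'
#' For each final class in genome A, counts collinear genes with the same
#' class in B, collinear genes with a different class, and non-collinear
#' genes, plus the derived percentages.
#'
#' @param records_a,records_b Zygosity records (final_class per gene_id).
#' @param pairs Data.frame (gene_a, gene_b) of collinear gene pairs.
#' @return Data.frame per class: n_total, n_same, n_different,
#'   n_noncollinear, pct_same, pct_specific (different + non-collinear,
#'   the genome-specific share).
#' @export
compare_zygosity <- function(records_a, records_b, pairs) {
  if (nrow(pairs)) {
    unknown <- setdiff(c(pairs$gene_a, pairs$gene_b),
                       c(records_a$gene_id, records_b$gene_id))
    if (length(unknown)) {
      stop("collinear pair references unknown gene id(s): ",
           paste(head(unknown, 5), collapse = ", "))
    }
  }
  partner <- setNames(pairs$gene_b, pairs$gene_a)
  class_b <- setNames(records_b$final_class, records_b$gene_id)
  out <- lapply(c("hemizygous", "protein_het", "homozygous"), function(cl) {
    ga <- records_a$gene_id[records_a$final_class == cl]
    p <- partner[ga]
    collinear <- !is.na(p)
    same <- collinear & class_b[p] == cl
    n_total <- length(ga)
    n_same <- sum(same, na.rm = TRUE)
    n_nc <- sum(!collinear)
    n_diff <- n_total - n_same - n_nc
    data.frame(class = cl, n_total = n_total, n_same = n_same,
               n_different = n_diff, n_noncollinear = n_nc,
               pct_same = if (n_total) 100 * n_same / n_total else NA_real_,
               pct_specific = if (n_total)
                 100 * (n_diff + n_nc) / n_total else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome-specific share of a zygosity class
#'
#' The share of genes in a class that are specific to the focal genome:
#' non-collinear genes plus collinear genes whose partner carries a
#' different class, over the class total, as a percentage.
#'
#' @param n_total,n_noncollinear,n_different Class counts.
#' @return Percentage.
#' @export
class_specific_share <- function(n_total, n_noncollinear, n_different) {
  stopifnot(n_total > 0)
  100 * (n_noncollinear + n_different) / n_total
}
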