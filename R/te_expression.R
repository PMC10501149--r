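# TE coverage proportions around genes, the TE-insertion-polymorphism
# rule, TPM normalisation, TE/expression correlation, and per-allele
# upstream genotyping.

#' TE coverage proportions around a set of genes
#'
#' For each gene, the fraction of the strand-aware 1-kb upstream window,
#' the gene body, and the 1-kb downstream window covered by the interval
#' union of the supplied TE annotations.  Windows are truncated at
#' chromosome edges and the truncated length is the denominator.
#'
#' @param genes Gene span data.frame (gene_id, chrom, strand, start, end).
#' @param tes TE annotation data.frame (chrom, start, end, optionally
#'   te_class); pre-filter by class to get per-class proportions, or pass
#'   the combined LTR+MITE set.
#' @param flank Flank width in bases (default 1000); must be positive.
#' @param chrom_lengths Named vector of chromosome lengths for edge
#'   truncation (optional; no right truncation if missing).
#' @return Data.frame: gene_id, proportion_up1kb, proportion_body,
#'   proportion_down1kb.
#' @export
te_proportion <- function(genes, tes, flank = 1000L, chrom_lengths = NULL) {
  if (flank <= 0) stop("flank must be positive")
  n <- nrow(genes)
  up_start <- ifelse(genes$strand == "-", genes$end, genes$start - flank)
  up_end <- ifelse(genes$strand == "-", genes$end + flank, genes$start)
  dn_start <- ifelse(genes$strand == "-", genes$start - flank, genes$end)
  dn_end <- ifelse(genes$strand == "-", genes$start, genes$end + flank)
  clamp <- function(s, e, chrom) {
    s <- pmax(s, 0L)
    if (!is.null(chrom_lengths)) e <- pmin(e, chrom_lengths[chrom])
    list(start = s, end = pmax(e, s))
  }
  up <- clamp(up_start, up_end, genes$chrom)
  dn <- clamp(dn_start, dn_end, genes$chrom)
  te_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    tes$chrom, IRanges::IRanges(tes$start + 1L, tes$end)))
  cov_frac <- function(s, e) {
    len <- e - s
    out <- numeric(n)
    ok <- len > 0
    if (any(ok)) {
      gr <- GenomicRanges::GRanges(genes$chrom[ok],
                                   IRanges::IRanges(s[ok] + 1L, e[ok]))
      ov <- GenomicRanges::findOverlaps(gr, te_gr)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        inter <- pmin(GenomicRanges::end(gr)[qh],
                      GenomicRanges::end(te_gr)[sh]) -
          pmax(GenomicRanges::start(gr)[qh],
               GenomicRanges::start(te_gr)[sh]) + 1L
        agg <- tapply(inter, qh, sum)
        covered <- numeric(sum(ok))
        covered[as.integer(names(agg))] <- as.numeric(agg)
        out[ok] <- covered / len[ok]
      }
    }
    out
  }
  data.frame(gene_id = genes$gene_id,
             proportion_up1kb = cov_frac(up$start, up$end),
             proportion_body = cov_frac(genes$start, genes$end),
             proportion_down1kb = cov_frac(dn$start, dn$end),
             stringsAsFactors = FALSE)
}

#' TE insertion polymorphism rule for one collinear group
#'
#' A collinear gene group is TE-insertion polymorphic when at least one
#' genome has no upstream TE (proportion exactly 0) and at least one
#' genome has an upstream TE proportion of at least 0.20 (inclusive).
#'
#' @param proportions Numeric vector of upstream TE proportions, one per
#'   genome (length >= 2).
#' @param min_proportion Insertion threshold, default 0.20.
#' @return Logical scalar.
#' @export
call_te_polymorphism <- function(proportions, min_proportion = 0.20) {
  if (length(proportions) < 2) {
    stop("a collinear group needs at least 2 genomes")
  }
  min(proportions) == 0 && max(proportions) >= min_proportion
}

#' TPM normalisation
#'
#' `rate = count / length`, `TPM = 1e6 * rate / sum(rate)` per sample.
#'
#' @param counts Matrix (genes x samples) of raw counts.
#' @param lengths Effective gene lengths in bases (> 0).
#' @return Matrix of TPM values with the input dimnames.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(which(zero), collapse = ","), "; TPM set to 0")
    denom[zero] <- 1
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Replicate-averaged log expression
#'
#' TPM per replicate, then the mean of log2(TPM + 1) across replicates.
#'
#' @param counts Matrix (genes x replicates).
#' @param lengths Gene lengths.
#' @return Named numeric vector of mean log2(TPM+1) per gene.
#' @export
mean_log_expression <- function(counts, lengths) {
  rowMeans(log2(tpm(counts, lengths) + 1))
}

#' Correlate upstream TE proportion with expression across genomes
#'
#' Pearson correlation, per collinear group, between the combined
#' upstream TE proportion and log2(TPM+1) across the genomes of the
#' panel; groups with fewer than 3 paired observations or zero variance
#' in either variable are undefined.  A polymorphic group with r below
#' -0.9 is a regulatory candidate.
#'
#' @param te_props Matrix (groups x genomes) of upstream TE proportions.
#' @param log_expr Matrix (groups x genomes) of log2(TPM+1).
#' @param candidate_r Candidate threshold, default -0.9 (strict <).
#' @param min_proportion Passed to [call_te_polymorphism()].
#' @return Data.frame: group, n, is_polymorphic, pearson_r, candidate,
#'   reason (why r is undefined, if it is).
#' @export
te_expression_correlation <- function(te_props, log_expr,
                                      candidate_r = -0.9,
                                      min_proportion = 0.20) {
  stopifnot(all(dim(te_props) == dim(log_expr)))
  groups <- rownames(te_props)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(te_props)))
  out <- lapply(seq_len(nrow(te_props)), function(i) {
    x <- te_props[i, ]; y <- log_expr[i, ]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    poly <- length(x) >= 2 && call_te_polymorphism(x, min_proportion)
    r <- NA_real_; reason <- ""
    if (length(x) < 3) {
      reason <- "fewer than 3 genomes"
    } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      reason <- "zero variance"
    } else {
      r <- stats::cor(x, y, method = "pearson")
    }
    data.frame(group = groups[i], n = length(x), is_polymorphic = poly,
               pearson_r = r,
               candidate = poly & !is.na(r) & r < candidate_r,
               reason = reason, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genotype the upstream TE insertion of the two alleles
#'
#' TE presence per haplotype follows the 0.20-proportion rule on the 1-kb
#' upstream window: both absent is hom_no_te, one present is het_te, both
#' present is hom_te.  An unresolvable allele (NA proportion) yields a
#' partial genotype with a flag.
#'
#' @param prop_primary,prop_associate Upstream TE proportions of the two
#'   haplotypes (vectorised).
#' @param min_proportion Presence threshold, default 0.20.
#' @return Data.frame: genotype (hom_no_te/het_te/hom_te/partial),
#'   resolved (logical).
#' @export
genotype_upstream <- function(prop_primary, prop_associate,
                              min_proportion = 0.20) {
  p1 <- prop_primary >= min_proportion
  p2 <- prop_associate >= min_proportion
  genotype <- ifelse(is.na(p1) | is.na(p2), "partial",
                     ifelse(p1 & p2, "hom_te",
                            ifelse(p1 | p2, "het_te", "hom_no_te")))
  data.frame(genotype = genotype, resolved = !(is.na(p1) | is.na(p2)),
             stringsAsFactors = FALSE)
}
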