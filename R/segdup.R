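# Segmental duplication detection from inter-chromosomal alignment blocks,
# gene retention, and Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
# correction for the positive-selection screen.

#' Detect segmental duplications
#'
#' Every inter-chromosomal alignment block longer than `min_len` aligned
#' bases with identity above `min_identity` becomes a segmental
#' duplication; (A,B)/(B,A) duplicates of the same pair are collapsed.
#' Intra-chromosomal blocks are skipped with a warning (tandem SDs are out
#' of scope).
#'
#' @param blocks Alignment block data.frame (qchrom, qstart, qend, rchrom,
#'   rstart, rend, identity).
#' @param min_len Minimum aligned length, default 1000 (strict >).
#' @param min_identity Minimum identity, default 0.90 (strict >); 0.92 is
#'   the recently-originated-SD preset.
#' @return Data.frame of SDs: chromA, startA, endA, chromB, startB, endB,
#'   length, identity.
#' @export
detect_segmental_duplications <- function(blocks, min_len = 1000,
                                          min_identity = 0.90) {
  intra <- blocks$qchrom == blocks$rchrom
  if (any(intra)) {
    warning(sum(intra), " intra-chromosomal block(s) skipped")
    blocks <- blocks[!intra, , drop = FALSE]
  }
  len <- blocks$qend - blocks$qstart
  keep <- len > min_len & blocks$identity > min_identity
  blocks <- blocks[keep, , drop = FALSE]
  len <- len[keep]
  if (!nrow(blocks)) {
    return(data.frame(chromA = character(), startA = integer(),
                      endA = integer(), chromB = character(),
                      startB = integer(), endB = integer(),
                      length = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  a <- data.frame(chrom = blocks$rchrom, start = blocks$rstart,
                  end = blocks$rend, stringsAsFactors = FALSE)
  b <- data.frame(chrom = blocks$qchrom, start = blocks$qstart,
                  end = blocks$qend, stringsAsFactors = FALSE)
  # orient each pair canonically so (A,B) and (B,A) records collapse
  flip <- paste(a$chrom, a$start) > paste(b$chrom, b$start)
  tmp <- a[flip, ]; a[flip, ] <- b[flip, ]; b[flip, ] <- tmp
  sd <- data.frame(chromA = a$chrom, startA = a$start, endA = a$end,
                   chromB = b$chrom, startB = b$start, endB = b$end,
                   length = len, identity = blocks$identity,
                   stringsAsFactors = FALSE)
  key <- sprintf("%s:%d-%d|%s:%d-%d", sd$chromA, sd$startA, sd$endA,
                 sd$chromB, sd$startB, sd$endB)
  sd <- sd[!duplicated(key), , drop = FALSE]
  sd <- sd[order(sd$chromA, sd$startA, sd$chromB, sd$startB), , drop = FALSE]
  rownames(sd) <- NULL
  sd
}

#' Gene-retaining SDs and the retention summary
#'
#' A gene is carried by an SD when its full span lies inside one of the
#' two SD intervals; the interval containing the gene is the source side
#' and the mate interval is checked for an intact gene copy.  Among source
#' genes duplicated multiple times, the retention summary is the fraction
#' whose duplications kept exactly one intact gene copy.
#'
#' @param sds SD data.frame from [detect_segmental_duplications()].
#' @param genes Gene span data.frame (gene_id, chrom, start, end).
#' @return List: `pairs` (source_gene_id, copy interval, copy_gene_id or
#'   NA, copy_has_intact_gene) and `retention` (n_multi_source,
#'   n_single_retained, fraction_single_retained).
#' @export
sd_gene_coverage <- function(sds, genes) {
  levels <- unique(c(genes$chrom, sds$chromA, sds$chromB))
  gr_g <- GenomicRanges::GRanges(
    factor(genes$chrom, levels), IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  contained <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(factor(chrom, levels),
                                 IRanges::IRanges(start + 1L, end))
    GenomicRanges::findOverlaps(gr_g, gr, type = "within")
  }
  ovA <- contained(sds$chromA, sds$startA, sds$endA)
  ovB <- contained(sds$chromB, sds$startB, sds$endB)
  rows <- list()
  add_pairs <- function(ov, src_side) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in seq_along(qh)) {
      i <- sh[k]  # SD row
      g <- qh[k]  # source gene
      if (src_side == "A") {
        copy <- c(sds$chromB[i], sds$startB[i], sds$endB[i])
        mate_ov <- if (length(ovB)) which(S4Vectors::subjectHits(ovB) == i) else integer()
        mate_genes <- S4Vectors::queryHits(ovB)[mate_ov]
      } else {
        copy <- c(sds$chromA[i], sds$startA[i], sds$endA[i])
        mate_ov <- if (length(ovA)) which(S4Vectors::subjectHits(ovA) == i) else integer()
        mate_genes <- S4Vectors::queryHits(ovA)[mate_ov]
      }
      mate_genes <- setdiff(mate_genes, g)
      rows[[length(rows) + 1L]] <<- data.frame(
        source_gene_id = genes$gene_id[g],
        sd_index = i,
        copy_chrom = copy[1],
        copy_start = as.integer(copy[2]),
        copy_end = as.integer(copy[3]),
        copy_gene_id = if (length(mate_genes))
          genes$gene_id[mate_genes[1]] else NA_character_,
        copy_has_intact_gene = length(mate_genes) > 0,
        stringsAsFactors = FALSE)
    }
  }
  add_pairs(ovA, "A")
  add_pairs(ovB, "B")
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_gene_id = character(), sd_index = integer(),
               copy_chrom = character(), copy_start = integer(),
               copy_end = integer(), copy_gene_id = character(),
               copy_has_intact_gene = logical(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source_gene_id, pairs$sd_index), , drop = FALSE]
  rownames(pairs) <- NULL
  per_src <- tapply(pairs$copy_has_intact_gene, pairs$source_gene_id, sum)
  n_dups <- tapply(pairs$copy_has_intact_gene, pairs$source_gene_id, length)
  multi <- n_dups >= 2
  n_multi <- sum(multi)
  n_single <- sum(per_src[multi] == 1)
  list(pairs = pairs,
       retention = data.frame(
         n_multi_source = n_multi,
         n_single_retained = n_single,
         fraction_single_retained = if (n_multi) n_single / n_multi else NA_real_))
}

# --- NG86 machinery ---------------------------------------------------------

.codon_bases <- c("T", "C", "A", "G")

.all_codons <- function() {
  as.vector(outer(outer(.codon_bases, .codon_bases, paste0), .codon_bases,
                  paste0))
}

#' @noRd
.ng86_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::GENETIC_CODE
    codons <- .all_codons()
    syn_sites <- setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      aa <- code[[cd]]
      if (aa == "*") next  # stop codons carry no countable sites
      s <- 0
      for (p in 1:3) {
        for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
          mut <- cd
          substr(mut, p, p) <- b
          # mutations creating a stop codon count as nonsynonymous
          if (code[[mut]] == aa) s <- s + 1 / 3
        }
      }
      syn_sites[cd] <- s
    }
    cache <<- list(code = code, syn_sites = syn_sites)
    cache
  }
})

# pathway-averaged synonymous/nonsynonymous differences for one codon pair;
# pathways passing through a stop codon are excluded (all-blocked pairs fall
# back to averaging over every pathway)
.ng86_pair_diffs <- function(c1, c2) {
  tab <- .ng86_tables()
  code <- tab$code
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(nd),
                  "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  "3" = {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  walk <- function(order) {
    cur <- c1
    s <- 0; n <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[cur]] == "*" || code[[nxt]] == "*") blocked <- TRUE
      if (code[[nxt]] == code[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3))
  ok <- res["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(sd = mean(res["s", ok]), nd = mean(res["n", ok]))
}

#' Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Synonymous/nonsynonymous site counts are averaged over both sequences;
#' substitution counts are averaged over all minimal mutational pathways
#' per codon (pathways through stop codons excluded); proportions are
#' corrected with Jukes-Cantor, d = -(3/4) log(1 - (4/3) p).  Codons
#' containing N in either sequence, and gapped codons, are dropped from
#' both.  The ratio is only defined when Ks > 0.
#'
#' @param cds_a,cds_b Aligned coding sequences (character or DNAString),
#'   equal length, length divisible by 3.
#' @return List: Ka, Ks, ratio (NA when Ks = 0), S, N (site counts), Sd,
#'   Nd (substitution counts), saturated_s, saturated_n.  The correction
#'   diverges as p approaches 3/4: at p = 3/4 the limit Inf is returned,
#'   beyond it NA; both set the saturated flag.
#' @export
ka_ks <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a)); b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("length must be divisible by 3")
  tab <- .ng86_tables()
  n_codons <- nchar(a) / 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n_codons)) {
    ca <- substr(a, (i - 1) * 3 + 1, i * 3)
    cb <- substr(b, (i - 1) * 3 + 1, i * 3)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next  # ambiguity/gap
    if (tab$code[[ca]] == "*" || tab$code[[cb]] == "*") next
    sa <- tab$syn_sites[[ca]]; sb <- tab$syn_sites[[cb]]
    S <- S + (sa + sb) / 2
    N <- N + 3 - (sa + sb) / 2
    d <- .ng86_pair_diffs(ca, cb)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  jc <- function(p) {
    arg <- 1 - 4 / 3 * p
    if (arg > 1e-12) return(-3 / 4 * log(arg))
    if (arg > -1e-12) return(Inf)  # limit at p = 3/4
    NA_real_                       # beyond saturation: undefined
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(Ka = Ka, Ks = Ks, ratio = ratio,
       S = S, N = N, Sd = Sd, Nd = Nd,
       saturated_s = !is.na(Ks) && !is.finite(Ks) || is.na(Ks),
       saturated_n = !is.na(Ka) && !is.finite(Ka) || is.na(Ka))
}

#' Genome-specific SD genes and the positive-selection flag
#'
#' @param sd_gene_pairs Data.frame with source_gene_id and a `ratio`
#'   column (Ka/Ks; NA when Ks = 0).
#' @param shared_class Named character vector: sharing class per gene id.
#' @return Subset of `sd_gene_pairs` whose source gene is genome-specific,
#'   with a `positive_selection` flag (ratio > 1; NA when the ratio is
#'   undefined).
#' @export
genome_specific_sd_genes <- function(sd_gene_pairs, shared_class) {
  cls <- shared_class[sd_gene_pairs$source_gene_id]
  out <- sd_gene_pairs[!is.na(cls) & cls == "genome_specific", , drop = FALSE]
  out$positive_selection <- ifelse(is.na(out$ratio), NA, out$ratio > 1)
  rownames(out) <- NULL
  out
}
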