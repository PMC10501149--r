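# NLR receptor classification from domain annotations, 200-kb clustering,
# integrated-domain comparison between genome groups, and RPV overlap.

.NLR_CANONICAL <- c("TIR", "CC", "CC_R", "NB-ARC", "LRR")

#' Classify genes into NLR subgroups
#'
#' A gene without NB-ARC is not an NLR.  Among NLRs, the N-terminal
#' signature decides the subgroup with precedence TIR > CC_R > CC: TIR
#' gives TNL, CC_R gives RNL, CC gives CNL, and NB-ARC alone or with LRR
#' gives NL.  Non-canonical domains are recorded as integrated domains.
#'
#' @param domains Data.frame (gene_id, domain); free-form names are
#'   integrated domains, canonical names must come from
#'   TIR/CC/CC_R/NB-ARC/LRR.
#' @param strict Error on near-miss canonical spellings such as "NBARC"
#'   or "RPW8" (default TRUE).
#' @return Data.frame: gene_id, subgroup (TNL/CNL/RNL/NL/not_nlr),
#'   integrated_domains (comma-separated).
#' @export
classify_nlr <- function(domains, strict = TRUE) {
  if (strict) {
    aliases <- c("NBARC", "NB_ARC", "NBS", "RPW8", "CCR", "CC-R", "TIR1")
    bad <- unique(domains$domain[toupper(domains$domain) %in% aliases])
    if (length(bad)) {
      stop("unknown canonical-domain label(s): ",
           paste(bad, collapse = ", "),
           " (expected TIR, CC, CC_R, NB-ARC, LRR)")
    }
  }
  per_gene <- split(domains$domain, domains$gene_id)
  subgroup <- vapply(per_gene, function(d) {
    if (!"NB-ARC" %in% d) return("not_nlr")
    if ("TIR" %in% d) return("TNL")
    if ("CC_R" %in% d) return("RNL")
    if ("CC" %in% d) return("CNL")
    "NL"
  }, character(1))
  ids <- vapply(per_gene, function(d) {
    paste(sort(unique(setdiff(d, .NLR_CANONICAL))), collapse = ",")
  }, character(1))
  data.frame(gene_id = names(per_gene), subgroup = unname(subgroup),
             integrated_domains = unname(ids), stringsAsFactors = FALSE)
}

#' Cluster NLR genes within 200-kb windows
#'
#' Single-linkage chaining per chromosome: consecutive NLR genes whose
#' start-to-start distance is at most `window` (inclusive) join one
#' cluster; singletons are clusters of size one.
#'
#' @param positions Data.frame (gene_id, chrom, start).
#' @param window Linking distance in bases, default 200000.
#' @return List: `members` (gene_id, cluster_id) and `clusters`
#'   (cluster_id, chrom, start, end, n_genes).
#' @export
cluster_nlr_genes <- function(positions, window = 200000L) {
  positions <- positions[order(positions$chrom, positions$start), ,
                         drop = FALSE]
  cluster_id <- integer(nrow(positions))
  cid <- 0L
  for (chrom in unique(positions$chrom)) {
    idx <- which(positions$chrom == chrom)
    gaps <- diff(positions$start[idx])
    newc <- c(TRUE, gaps > window)
    cid_local <- cumsum(newc)
    cluster_id[idx] <- cid + cid_local
    cid <- cid + max(cid_local)
  }
  members <- data.frame(gene_id = positions$gene_id,
                        cluster_id = cluster_id, stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(split(seq_len(nrow(positions)),
                                          cluster_id), function(idx) {
    data.frame(cluster_id = cluster_id[idx[1]],
               chrom = positions$chrom[idx[1]],
               start = min(positions$start[idx]),
               end = max(positions$start[idx]),
               n_genes = length(idx), stringsAsFactors = FALSE)
  }))
  rownames(clusters) <- NULL
  list(members = members, clusters = clusters)
}

#' Integrated-domain incidence across genomes
#'
#' Counts, per non-canonical (integrated) domain, how many NLR genes carry
#' it in each genome; flags domains exclusive to one group (wild or
#' cultivated) and applies the display filter of incidence greater than
#' `min_incidence` while retaining the full table.
#'
#' @param nlr_sets Named list (genome -> [classify_nlr()] output).
#' @param group_labels Named character vector genome -> "wild" or
#'   "cultivated".
#' @param min_incidence Display filter; a domain is displayed when its
#'   total incidence exceeds this (default 2, matching the ">2 NLR genes"
#'   rule).
#' @return Data.frame: domain, one count column per genome, total,
#'   group_exclusive ("wild", "cultivated" or ""), displayed.
#' @export
compare_integrated_domains <- function(nlr_sets, group_labels,
                                       min_incidence = 2L) {
  stopifnot(all(names(nlr_sets) %in% names(group_labels)))
  counts <- lapply(names(nlr_sets), function(g) {
    s <- nlr_sets[[g]]
    s <- s[s$subgroup != "not_nlr" & nzchar(s$integrated_domains), ,
           drop = FALSE]
    doms <- unlist(strsplit(s$integrated_domains, ",", fixed = TRUE))
    table(doms)
  })
  names(counts) <- names(nlr_sets)
  all_doms <- sort(unique(unlist(lapply(counts, names))))
  if (!length(all_doms)) {
    return(data.frame(domain = character(), total = integer(),
                      group_exclusive = character(), displayed = logical(),
                      stringsAsFactors = FALSE))
  }
  mat <- vapply(counts, function(tb) {
    out <- integer(length(all_doms))
    out[match(names(tb), all_doms)] <- as.integer(tb)
    out
  }, integer(length(all_doms)))
  mat <- matrix(mat, nrow = length(all_doms),
                dimnames = list(all_doms, names(counts)))
  wild <- names(group_labels)[group_labels == "wild"]
  cult <- names(group_labels)[group_labels == "cultivated"]
  w_tot <- rowSums(mat[, intersect(wild, colnames(mat)), drop = FALSE])
  c_tot <- rowSums(mat[, intersect(cult, colnames(mat)), drop = FALSE])
  excl <- ifelse(w_tot > 0 & c_tot == 0, "wild",
                 ifelse(c_tot > 0 & w_tot == 0, "cultivated", ""))
  out <- data.frame(domain = all_doms, mat,
                    total = rowSums(mat),
                    group_exclusive = excl,
                    displayed = rowSums(mat) > min_incidence,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Overlap NLR clusters with RPV resistance loci
#'
#' @param clusters Cluster data.frame from [cluster_nlr_genes()].
#' @param rpv_loci Data.frame (name, chrom, start, end).
#' @return Data.frame of (cluster_id, rpv_name) span intersections.
#' @export
overlap_rpv <- function(clusters, rpv_loci) {
  if (!nrow(clusters) || !nrow(rpv_loci)) {
    return(data.frame(cluster_id = integer(), rpv_name = character(),
                      stringsAsFactors = FALSE))
  }
  gr_c <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(clusters$start + 1L,
                                     pmax(clusters$end, clusters$start + 1L)))
  gr_r <- GenomicRanges::GRanges(
    rpv_loci$chrom, IRanges::IRanges(rpv_loci$start + 1L, rpv_loci$end))
  ov <- GenomicRanges::findOverlaps(gr_c, gr_r)
  data.frame(cluster_id = clusters$cluster_id[S4Vectors::queryHits(ov)],
             rpv_name = rpv_loci$name[S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' TNL to non-TNL ratio of an NLR set
#'
#' @param nlr Output of [classify_nlr()] (not_nlr rows ignored).
#' @return `|TNL| / (|CNL| + |RNL| + |NL|)`; NA for an empty NLR set, Inf
#'   when only TNLs are present.
#' @export
tnl_ratio <- function(nlr) {
  nlr <- nlr[nlr$subgroup != "not_nlr", , drop = FALSE]
  if (!nrow(nlr)) return(NA_real_)
  n_tnl <- sum(nlr$subgroup == "TNL")
  n_other <- nrow(nlr) - n_tnl
  if (n_other == 0) return(Inf)
  n_tnl / n_other
}
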