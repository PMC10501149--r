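# Collinear block chaining (MCScanX-style dynamic programming over gene
# ranks), gene sharing classes across the panel, loss-vs-translocation
# mechanism calls, and trio-based hemizygous-gene origin inference.

# Best chain among the given points for one orientation.
# Points carry rank_a, rank_b; validity: consecutive pairs satisfy
# 1 <= d_a <= max_gap and 1 <= d_b <= max_gap (d_b measured descending for
# the antiparallel orientation).  Score: one unit per pair minus
# gap_penalty per skipped rank.  Ties resolved toward the
# lexicographically smallest index sequence, so the result is unique and
# an exhaustive oracle can reproduce it.
.best_chain <- function(rank_a, rank_b, max_gap, gap_penalty, orientation) {
  n <- length(rank_a)
  if (n == 0) return(NULL)
  score <- rep(1, n)
  chain <- lapply(seq_len(n), function(i) i)
  ord <- order(rank_a, rank_b)
  better <- function(s1, c1, s2, c2) {
    if (s1 > s2 + 1e-12) return(TRUE)
    if (s1 < s2 - 1e-12) return(FALSE)
    # lexicographic comparison of index sequences
    l <- min(length(c1), length(c2))
    for (k in seq_len(l)) {
      if (c1[k] < c2[k]) return(TRUE)
      if (c1[k] > c2[k]) return(FALSE)
    }
    length(c1) < length(c2)
  }
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    for (jj in seq_len(ii - 1L)) {
      j <- ord[jj]
      da <- rank_a[i] - rank_a[j]
      db <- if (orientation == "+") rank_b[i] - rank_b[j]
            else rank_b[j] - rank_b[i]
      if (da < 1 || da > max_gap || db < 1 || db > max_gap) next
      cand_score <- score[j] + 1 - gap_penalty * ((da - 1) + (db - 1))
      cand_chain <- c(chain[[j]], i)
      if (better(cand_score, cand_chain, score[i], chain[[i]])) {
        score[i] <- cand_score
        chain[[i]] <- cand_chain
      }
    }
  }
  best <- 1L
  for (i in seq_len(n)) {
    if (better(score[i], chain[[i]], score[best], chain[[best]])) best <- i
  }
  list(score = score[best], members = chain[[best]])
}

#' Chain homology hits into collinear blocks
#'
#' Within every chromosome pair, hits are chained by dynamic programming
#' over gene ranks: a chain extends when both rank gaps are at most
#' `max_gap`, with a unit match score and a gap penalty proportional to
#' the skipped rank distance.  Antiparallel (inverted) chains are
#' allowed.  Chains are extracted greedily best-first; chains with at
#' least `min_block_size` pairs become blocks, and blocks overlapping on
#' both rank intervals are deduplicated keeping the lower e-value.
#'
#' @param hits Data.frame (geneA, geneB, bitscore, evalue), one best hit
#'   per query.
#' @param positions Data.frame (gene_id, genome, chrom, rank) covering
#'   every gene referenced by `hits`.
#' @param genome_a,genome_b Genome names of the A and B sides of `hits`.
#' @param min_block_size Minimum pairs per block (default 5).
#' @param max_gap Maximum rank gap (default 25).
#' @param gap_penalty Penalty per skipped rank (default 0.01; small
#'   enough that an extra pair always beats a shorter chain).
#' @return List: `blocks` (block_id, chrom_a, chrom_b, orientation,
#'   n_pairs, score, evalue) and `pairs` (block_id, gene_a, gene_b,
#'   rank_a, rank_b).
#' @export
chain_collinear_blocks <- function(hits, positions, genome_a, genome_b,
                                   min_block_size = 5L, max_gap = 25L,
                                   gap_penalty = 0.01) {
  pos_a <- positions[positions$genome == genome_a, , drop = FALSE]
  pos_b <- positions[positions$genome == genome_b, , drop = FALSE]
  ia <- match(hits$geneA, pos_a$gene_id)
  ib <- match(hits$geneB, pos_b$gene_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("hit references unranked gene(s): ",
         paste(head(c(hits$geneA[is.na(ia)], hits$geneB[is.na(ib)]), 5),
               collapse = ", "))
  }
  pts <- data.frame(gene_a = hits$geneA, gene_b = hits$geneB,
                    chrom_a = pos_a$chrom[ia], chrom_b = pos_b$chrom[ib],
                    rank_a = pos_a$rank[ia], rank_b = pos_b$rank[ib],
                    evalue = hits$evalue, stringsAsFactors = FALSE)
  blocks <- list(); pair_rows <- list()
  bid <- 0L
  combos <- unique(pts[, c("chrom_a", "chrom_b")])
  combos <- combos[order(combos$chrom_a, combos$chrom_b), , drop = FALSE]
  for (ci in seq_len(nrow(combos))) {
    sub <- pts[pts$chrom_a == combos$chrom_a[ci] &
               pts$chrom_b == combos$chrom_b[ci], , drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b, sub$gene_a, sub$gene_b), ,
               drop = FALSE]
    repeat {
      if (nrow(sub) < min_block_size) break
      best <- NULL; best_orient <- NULL
      for (orient in c("+", "-")) {
        cand <- .best_chain(sub$rank_a, sub$rank_b, max_gap, gap_penalty,
                            orient)
        if (is.null(best) || cand$score > best$score + 1e-12) {
          best <- cand; best_orient <- orient
        }
      }
      if (length(best$members) < min_block_size) break
      bid <- bid + 1L
      mem <- sub[best$members, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = bid, chrom_a = mem$chrom_a[1], chrom_b = mem$chrom_b[1],
        orientation = best_orient, n_pairs = nrow(mem), score = best$score,
        evalue = min(mem$evalue), stringsAsFactors = FALSE)
      pair_rows[[bid]] <- data.frame(
        block_id = bid, gene_a = mem$gene_a, gene_b = mem$gene_b,
        rank_a = mem$rank_a, rank_b = mem$rank_b, stringsAsFactors = FALSE)
      sub <- sub[-best$members, , drop = FALSE]
    }
  }
  if (!bid) {
    return(list(
      blocks = data.frame(block_id = integer(), chrom_a = character(),
                          chrom_b = character(), orientation = character(),
                          n_pairs = integer(), score = numeric(),
                          evalue = numeric(), stringsAsFactors = FALSE),
      pairs = data.frame(block_id = integer(), gene_a = character(),
                         gene_b = character(), rank_a = integer(),
                         rank_b = integer(), stringsAsFactors = FALSE)))
  }
  blocks <- do.call(rbind, blocks)
  pairs <- do.call(rbind, pair_rows)
  # e-value deduplication of blocks overlapping on both rank intervals
  drop <- logical(nrow(blocks))
  rng <- function(b, what) {
    p <- pairs[pairs$block_id == b, ]
    range(p[[what]])
  }
  for (i in seq_len(nrow(blocks))) {
    if (drop[i]) next
    for (j in seq_len(nrow(blocks))) {
      if (i == j || drop[j] || drop[i]) next
      if (blocks$chrom_a[i] != blocks$chrom_a[j] ||
          blocks$chrom_b[i] != blocks$chrom_b[j]) next
      ra_i <- rng(blocks$block_id[i], "rank_a")
      ra_j <- rng(blocks$block_id[j], "rank_a")
      rb_i <- rng(blocks$block_id[i], "rank_b")
      rb_j <- rng(blocks$block_id[j], "rank_b")
      if (ra_i[1] <= ra_j[2] && ra_j[1] <= ra_i[2] &&
          rb_i[1] <= rb_j[2] && rb_j[1] <= rb_i[2]) {
        # redundant pair: keep the lower e-value (ties: earlier block)
        if (blocks$evalue[i] < blocks$evalue[j] ||
            (blocks$evalue[i] == blocks$evalue[j] && i < j)) {
          drop[j] <- TRUE
        } else {
          drop[i] <- TRUE
        }
      }
    }
  }
  keep_ids <- blocks$block_id[!drop]
  list(blocks = blocks[!drop, , drop = FALSE],
       pairs = pairs[pairs$block_id %in% keep_ids, , drop = FALSE])
}

#' Collinear gene pairs from chained blocks
#'
#' @param chained Result of [chain_collinear_blocks()].
#' @return Data.frame (gene_a, gene_b), one row per collinear pair.
#' @export
collinear_pairs <- function(chained) {
  unique(chained$pairs[, c("gene_a", "gene_b")])
}

#' Sharing class of every reference gene across the panel
#'
#' A reference gene collinear in every other genome is all_shared;
#' collinear in exactly the other cultivated genomes is cultivated_shared;
#' in exactly the wild genomes is wild_shared; in none is genome_specific;
#' anything else is other_pattern.
#'
#' @param ref_genes Character vector of reference gene ids.
#' @param partner_presence Named list: other genome -> reference gene ids
#'   with a collinear partner there.
#' @param genome_labels Named character vector genome -> "wild" or
#'   "cultivated" covering every genome in `partner_presence`.
#' @return Named character vector of classes per reference gene.
#' @export
classify_shared_genes <- function(ref_genes, partner_presence,
                                  genome_labels) {
  others <- names(partner_presence)
  if (!all(others %in% names(genome_labels))) {
    stop("unlabeled genome(s): ",
         paste(setdiff(others, names(genome_labels)), collapse = ", "))
  }
  if (!all(genome_labels[others] %in% c("wild", "cultivated"))) {
    stop("genome labels must be 'wild' or 'cultivated'")
  }
  wild <- sort(others[genome_labels[others] == "wild"])
  cult <- sort(others[genome_labels[others] == "cultivated"])
  pres <- vapply(partner_presence, function(p) ref_genes %in% p,
                 logical(length(ref_genes)))
  pres <- matrix(pres, nrow = length(ref_genes),
                 dimnames = list(ref_genes, others))
  cls <- apply(pres, 1, function(row) {
    p <- sort(others[row])
    if (length(p) == length(others)) return("all_shared")
    if (length(p) == 0) return("genome_specific")
    if (length(cult) > 0 && identical(p, cult)) return("cultivated_shared")
    if (length(wild) > 0 && identical(p, wild)) return("wild_shared")
    "other_pattern"
  })
  setNames(cls, ref_genes)
}

#' Mechanism behind non-collinear genes
#'
#' For reference genes without a collinear partner in the other genome:
#' a genome-specific gene with a within-genome homolog is
#' duplicate_origin; a gene with no homolog in the other genome is
#' lost_in_other; a gene whose homolog sits outside any collinear block
#' is translocated_in_other.
#'
#' @param gene_ids Non-collinear reference gene ids.
#' @param hits_to_other Data.frame (geneA, geneB, evalue) of hits from the
#'   reference into the other genome.
#' @param self_hits Data.frame (geneA, geneB, evalue) of within-genome
#'   hits (paralogs).
#' @param shared_class Named class vector from [classify_shared_genes()].
#' @param evalue_threshold Homology cutoff, default 1e-4.
#' @return Named character vector of mechanism calls.
#' @export
classify_noncollinear_mechanism <- function(gene_ids, hits_to_other,
                                            self_hits = NULL,
                                            shared_class = NULL,
                                            evalue_threshold = 1e-4) {
  has_other <- gene_ids %in%
    hits_to_other$geneA[hits_to_other$evalue <= evalue_threshold]
  has_self <- if (!is.null(self_hits) && nrow(self_hits)) {
    gene_ids %in% self_hits$geneA[self_hits$evalue <= evalue_threshold]
  } else rep(FALSE, length(gene_ids))
  is_spec <- if (!is.null(shared_class)) {
    !is.na(shared_class[gene_ids]) &
      shared_class[gene_ids] == "genome_specific"
  } else rep(FALSE, length(gene_ids))
  call <- ifelse(is_spec & has_self, "duplicate_origin",
                 ifelse(!has_other, "lost_in_other", "translocated_in_other"))
  setNames(call, gene_ids)
}

#' Parental origin of hemizygous genes in a trio
#'
#' A hemizygous offspring gene is present in parent A when it has a
#' collinear partner there, and present in parent B when every base of
#' its body is covered by parent-B reads (depth >= 1 at 100% of bases,
#' the strict full-coverage rule; relax via `full_coverage`).  A-only
#' genes were inherited from parent A, B-only from parent B; genes
#' present in both are not explained by inheritance and genes in neither
#' are unexplained.
#'
#' @param gene_ids Hemizygous offspring gene ids.
#' @param collinear_in_a Named logical: collinear partner in parent A.
#' @param covered_fraction_b Named numeric in \[0,1\]: fraction of gene
#'   bases covered at depth >= 1 by parent-B reads (NA = missing track).
#' @param full_coverage Presence requires covered fraction >= this
#'   (default 1).
#' @return Data.frame: gene_id, present_a, present_b, call.
#' @export
infer_hemizygote_origin <- function(gene_ids, collinear_in_a,
                                    covered_fraction_b,
                                    full_coverage = 1.0) {
  pa <- collinear_in_a[gene_ids]
  pa[is.na(pa)] <- FALSE
  cb <- covered_fraction_b[gene_ids]
  missing_track <- is.na(cb)
  if (any(missing_track)) {
    warning("missing parent-B coverage for ", sum(missing_track),
            " gene(s); called unexplained")
  }
  pb <- !missing_track & cb >= full_coverage
  call <- ifelse(missing_track, "unexplained",
                 ifelse(pa & pb, "both_present",
                        ifelse(pa, "from_parentA",
                               ifelse(pb, "from_parentB", "unexplained"))))
  data.frame(gene_id = gene_ids, present_a = unname(pa),
             present_b = unname(pb), call = unname(call),
             stringsAsFactors = FALSE)
}
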