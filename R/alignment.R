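# Intragenomic heterozygosity, centromeric monomer search, multi-genome SV
# validation, and the reference-overlap contig reassignment rule.

#' Heterozygosity of one homologous chromosome pair
#'
#' Summarises the divergence between the two haplotypes of one chromosome
#' from their pairwise alignment blocks.  Two sources of difference are
#' counted: associate (query) bases outside the union of aligned intervals,
#' and mismatching bases within alignments.  Where blocks overlap, coverage
#' is counted on the interval union and mismatches for a base are taken
#' from the best-identity block covering it, so dissimilarity is never
#' double counted.
#'
#' @param blocks Data.frame of alignment blocks for a single chromosome
#'   pair (columns qstart, qend, mismatches, identity; 0-based half-open).
#' @param chrom_length Length in bases of the associate (query) chromosome;
#'   this is the denominator of the percentage.
#' @param chrom Optional chromosome label for the output row.
#' @return One-row data.frame: chrom, chrom_length, unaligned_bases,
#'   dissimilar_bases, pct_variation.
#' @export
chromosome_heterozygosity <- function(blocks, chrom_length, chrom = NA_character_) {
  stopifnot(is.numeric(chrom_length), chrom_length >= 0)
  if (nrow(blocks) == 0) {
    return(data.frame(chrom = chrom, chrom_length = chrom_length,
                      unaligned_bases = chrom_length, dissimilar_bases = 0,
                      pct_variation = if (chrom_length > 0) 100 else 0,
                      stringsAsFactors = FALSE))
  }
  if (any(blocks$qstart >= blocks$qend)) {
    stop("alignment block with qstart >= qend")
  }
  if (any(blocks$qend > chrom_length)) {
    stop("alignment block extends past chrom_length")
  }
  ir <- IRanges::IRanges(start = blocks$qstart + 1L, end = blocks$qend)
  covered <- sum(IRanges::width(IRanges::reduce(ir)))
  unaligned <- chrom_length - covered
  # resolve overlaps: per disjoint segment, use the best-identity block
  dj <- IRanges::disjoin(ir)
  ov <- IRanges::findOverlaps(dj, ir)
  dens <- blocks$mismatches / (blocks$qend - blocks$qstart)
  best <- tapply(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov),
                 function(j) j[which.max(blocks$identity[j])])
  seg_idx <- as.integer(names(best))
  dissimilar <- sum(IRanges::width(dj)[seg_idx] * dens[unlist(best)])
  data.frame(chrom = chrom, chrom_length = chrom_length,
             unaligned_bases = unaligned, dissimilar_bases = dissimilar,
             pct_variation = 100 * (unaligned + dissimilar) / chrom_length,
             stringsAsFactors = FALSE)
}

#' Genome-wide heterozygosity from per-chromosome rows
#'
#' Length-weighted aggregate of per-chromosome values:
#' `100 * sum(unaligned + dissimilar) / sum(length)`.
#'
#' @param rows Data.frame of rows from [chromosome_heterozygosity()].
#' @return Percentage (scalar).
#' @export
genome_heterozygosity <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) stop("no chromosome rows supplied")
  100 * sum(rows$unaligned_bases + rows$dissimilar_bases) /
    sum(rows$chrom_length)
}

#' Search a genome for centromeric monomer arrays
#'
#' Full-length ungapped scan of the monomer over every position of both
#' strands (Hamming identity); hits passing the identity and coverage
#' thresholds are merged into regions when separated by at most
#' `merge_gap` bases.
#'
#' @param genome `DNAStringSet` (or path to a FASTA file).
#' @param monomer Monomer sequence (character or `DNAString`), alphabet
#'   ACGTN.
#' @param min_identity,min_coverage Thresholds in (0,1]; a hit must exceed
#'   `min_identity` and `min_coverage` (strict, matching the >90% / >95%
#'   screen).
#' @param merge_gap Hits separated by at most this many bases join one
#'   region (default 10 kb).
#' @return List with data.frames `hits` (chrom, start, end, strand,
#'   identity, coverage) and `regions` (chrom, start, end, n_hits);
#'   0-based half-open.
#' @export
find_centromere_regions <- function(genome, monomer, min_identity = 0.90,
                                    min_coverage = 0.95, merge_gap = 10000L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  monomer <- Biostrings::DNAString(toupper(as.character(monomer)))
  if (length(monomer) == 0) stop("monomer must be non-empty")
  if (!grepl("^[ACGTN]+$", as.character(monomer))) {
    stop("monomer alphabet must be ACGTN")
  }
  if (min_identity <= 0 || min_identity > 1 || min_coverage <= 0 ||
      min_coverage > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  w <- length(monomer)
  max_mm <- floor((1 - min_identity) * w)  # candidate screen; exact filter below
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    if (length(subj) < w) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") monomer else Biostrings::reverseComplement(monomer)
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) next
      st <- Biostrings::start(m)
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                        with.indels = FALSE, fixed = TRUE)
      ident <- (w - mm) / w
      # full-length ungapped hits: monomer coverage is 1 by construction,
      # so only the identity threshold can reject a candidate
      keep <- ident > min_identity
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = st[keep] - 1L, end = st[keep] - 1L + w,
        strand = strand, identity = ident[keep], coverage = 1.0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    hits <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       identity = numeric(), coverage = numeric())
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), n_hits = integer())
    return(list(hits = hits, regions = regions))
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  regions <- do.call(rbind, lapply(split(hits, hits$chrom), function(h) {
    ir <- IRanges::IRanges(h$start + 1L, h$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    ov <- IRanges::countOverlaps(red, ir)
    data.frame(chrom = h$chrom[1], start = IRanges::start(red) - 1L,
               end = IRanges::end(red), n_hits = ov,
               stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  list(hits = hits, regions = regions)
}

#' Cross-validate large structural variants across genome pairs
#'
#' Two SVs of the same type support each other when their reciprocal
#' overlap reaches `reciprocal_overlap`; an SV is retained when supported
#' in at least `min_support` other genome-pair comparisons.
#'
#' @param sv_sets Named list of data.frames (chrom, start, end, sv_type),
#'   one per genome-pair comparison, all on a shared reference.
#' @param reciprocal_overlap Fraction in (0,1]; default 0.5.
#' @param min_support Minimum number of other comparisons confirming the
#'   SV; default 2.
#' @return Data.frame of validated SVs with a `support` column
#'   (comma-separated names of confirming comparisons) and `n_support`.
#' @export
validate_large_svs <- function(sv_sets, reciprocal_overlap = 0.5,
                               min_support = 2L) {
  if (reciprocal_overlap <= 0 || reciprocal_overlap > 1) {
    stop("reciprocal_overlap must lie in (0, 1]")
  }
  stopifnot(is.list(sv_sets), !is.null(names(sv_sets)))
  supports <- function(a, b) {
    if (a$chrom != b$chrom || a$sv_type != b$sv_type) return(FALSE)
    ov <- min(a$end, b$end) - max(a$start, b$start)
    if (ov <= 0) return(FALSE)
    ov / (a$end - a$start) >= reciprocal_overlap &&
      ov / (b$end - b$start) >= reciprocal_overlap
  }
  out <- list()
  for (name in names(sv_sets)) {
    svs <- sv_sets[[name]]
    if (is.null(svs) || nrow(svs) == 0) next
    for (i in seq_len(nrow(svs))) {
      sv <- svs[i, ]
      sup <- character()
      for (other in setdiff(names(sv_sets), name)) {
        osvs <- sv_sets[[other]]
        if (is.null(osvs) || nrow(osvs) == 0) next
        hit <- any(vapply(seq_len(nrow(osvs)),
                          function(j) supports(sv, osvs[j, ]), logical(1)))
        if (hit) sup <- c(sup, other)
      }
      if (length(sup) >= min_support) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = sv$chrom, start = sv$start, end = sv$end,
          sv_type = sv$sv_type, source = name,
          support = paste(sup, collapse = ","),
          n_support = length(sup), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sv_type = character(),
                      source = character(), support = character(),
                      n_support = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference-overlap contig reassignment rule
#'
#' A focal primary contig whose reference footprint overlaps the union of
#' ordered-primary alignments by at least `min_overlap` (inclusive) is a
#' segment of that homologous chromosome and is moved to the associate
#' group; with less overlap it stays primary.
#'
#' @param focal_intervals Data.frame (chrom, start, end) of the focal
#'   contig's reference footprint.
#' @param ordered_union Data.frame (chrom, start, end): union of ordered
#'   primary contig alignments on the reference.
#' @param min_overlap Fraction in [0,1]; default 0.5.
#' @return List: decision ("reassign_to_associate" or "keep_primary") and
#'   overlap_fraction.
#' @export
correct_contig_assignment <- function(focal_intervals, ordered_union,
                                      min_overlap = 0.5) {
  stopifnot(nrow(focal_intervals) >= 1)
  gr_f <- GenomicRanges::GRanges(
    focal_intervals$chrom,
    IRanges::IRanges(focal_intervals$start + 1L, focal_intervals$end))
  gr_f <- GenomicRanges::reduce(gr_f)
  total <- sum(GenomicRanges::width(gr_f))
  frac <- 0
  if (!is.null(ordered_union) && nrow(ordered_union) > 0) {
    gr_u <- GenomicRanges::GRanges(
      ordered_union$chrom,
      IRanges::IRanges(ordered_union$start + 1L, ordered_union$end))
    ov <- GenomicRanges::intersect(gr_f, GenomicRanges::reduce(gr_u))
    frac <- sum(GenomicRanges::width(ov)) / total
  }
  list(decision = if (frac >= min_overlap) "reassign_to_associate" else "keep_primary",
       overlap_fraction = frac)
}
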