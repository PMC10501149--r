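# Haplotype-pair heterozygosity, monomer search, multi-genome SV
# validation, and the contig reassignment rule.

blk <- function(qstart, qend, mismatches, identity = NULL) {
  data.frame(qstart = qstart, qend = qend, mismatches = mismatches,
             identity = if (is.null(identity))
               1 - mismatches / (qend - qstart) else identity)
}

test_that("chromosome heterozygosity combines unaligned and mismatching bases", {
  # identical haplotypes: one full-length block, no mismatches
  expect_equal(chromosome_heterozygosity(blk(0, 10000, 0),
                                         10000)$pct_variation, 0)
  # 9,500 aligned bases with 100 mismatches on a 10-kb chromosome
  r <- chromosome_heterozygosity(blk(0, 9500, 100), 10000)
  expect_equal(r$unaligned_bases, 500)
  expect_equal(r$dissimilar_bases, 100)
  expect_equal(r$pct_variation, 6.0)
  # nothing aligned at all
  expect_equal(chromosome_heterozygosity(blk(integer(), integer(),
                                             integer()),
                                         10000)$pct_variation, 100)
  expect_error(chromosome_heterozygosity(blk(0, 10500, 0), 10000),
               "past chrom_length")
})

test_that("heterozygosity is invariant to block order and block splitting", {
  set.seed(11)
  starts <- sort(sample(seq(0, 90000, by = 1000), 20))
  blocks <- blk(starts, starts + 800, rbinom(20, 800, 0.01))
  base <- chromosome_heterozygosity(blocks, 100000)$pct_variation
  shuffled <- blocks[sample(nrow(blocks)), ]
  expect_equal(chromosome_heterozygosity(shuffled, 100000)$pct_variation,
               base)
  # split every block in two, partitioning mismatches proportionally
  cut <- 400
  left <- blk(blocks$qstart, blocks$qstart + cut,
              round(blocks$mismatches / 2))
  right <- blk(blocks$qstart + cut, blocks$qend,
               blocks$mismatches - round(blocks$mismatches / 2))
  expect_equal(chromosome_heterozygosity(rbind(left, right),
                                         100000)$pct_variation, base)
})

test_that("overlapping blocks count each base once at the best identity", {
  # [0,1000) at identity .99 (10 mm) overlapped by [500,1500) at .95
  b <- rbind(blk(0, 1000, 10), blk(500, 1500, 50))
  r <- chromosome_heterozygosity(b, 2000)
  # [0,1000) from the .99 block (10/1000 density), [1000,1500) from the
  # .95 block (50/1000 density): 10 + 25 mismatching bases
  expect_equal(r$dissimilar_bases, 10 + 25)
  expect_equal(r$unaligned_bases, 500)
})

test_that("genome heterozygosity is the length-weighted aggregate", {
  one <- chromosome_heterozygosity(blk(0, 9500, 100), 10000)
  expect_equal(genome_heterozygosity(one), one$pct_variation)
  two <- rbind(
    chromosome_heterozygosity(blk(0, 9800, 0), 10000),   # 2 %
    chromosome_heterozygosity(blk(0, 9200, 0), 10000))   # 8 %
  expect_equal(genome_heterozygosity(two), 5)
  expect_error(genome_heterozygosity(NULL), "no chromosome rows")
})

test_that("monomer search keeps >90% identity hits and merges regions", {
  set.seed(5)
  bases <- c("A", "C", "G", "T")
  mono <- paste(sample(bases, 100, TRUE), collapse = "")
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    v[idx] <- vapply(v[idx], function(b) sample(setdiff(bases, b), 1), "")
    paste(v, collapse = "")
  }
  spacer <- function(n) paste(sample(bases, n, TRUE), collapse = "")
  # exact copy, an 8%-diverged copy (kept), and a 15%-diverged copy
  # (rejected at the 0.90 threshold)
  g <- paste0(spacer(500), mono, spacer(300), mutate(mono, 8), spacer(300),
              mutate(mono, 15), spacer(500))
  res <- find_centromere_regions(Biostrings::DNAStringSet(c(chr1 = g)),
                                 mono, merge_gap = 1000)
  expect_equal(nrow(res$hits), 2)
  expect_equal(res$hits$identity, c(1.0, 0.92))
  expect_equal(nrow(res$regions), 1)  # 300-bp gap < merge_gap
  expect_equal(res$regions$n_hits, 2)
})

test_that("a tandem array within the merge gap yields one region", {
  set.seed(6)
  bases <- c("A", "C", "G", "T")
  mono <- paste(sample(bases, 80, TRUE), collapse = "")
  g <- paste0(paste(rep(paste0(mono,
                               paste(sample(bases, 40, TRUE),
                                     collapse = "")), 5), collapse = ""),
              paste(sample(bases, 400, TRUE), collapse = ""))
  res <- find_centromere_regions(Biostrings::DNAStringSet(c(chr1 = g)),
                                 mono, merge_gap = 200)
  expect_equal(res$regions$n_hits, 5)
  expect_equal(nrow(res$regions), 1)
})

test_that("monomer search agrees with a brute-force all-positions oracle", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  w <- 40L
  mono <- paste(sample(bases, w, TRUE), collapse = "")
  mv <- strsplit(mono, "")[[1]]
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[mv])
  gv <- sample(bases, 1500, TRUE)
  # plant some diverged copies on both strands
  for (st in c(101, 401, 901)) {
    copy <- mv
    idx <- sample(w, sample(0:5, 1))
    copy[idx] <- vapply(copy[idx], function(b) sample(setdiff(bases, b), 1), "")
    gv[st:(st + w - 1)] <- copy
  }
  gv[1201:(1200 + w)] <- rc
  g <- paste(gv, collapse = "")
  res <- find_centromere_regions(Biostrings::DNAStringSet(c(chr1 = g)),
                                 mono, min_identity = 0.9)
  oracle <- list()
  for (start in 1:(1500 - w + 1)) {
    window <- gv[start:(start + w - 1)]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") mv else unname(rc)
      ident <- mean(window == pat)
      if (ident > 0.9) {
        oracle[[length(oracle) + 1L]] <- data.frame(
          start = start - 1L, strand = strand, identity = ident)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$start, oracle$strand), ]
  expect_equal(res$hits$start, oracle$start)
  expect_equal(res$hits$strand, oracle$strand)
  expect_equal(res$hits$identity, oracle$identity)
})

test_that("SVs are validated by reciprocal overlap across genome pairs", {
  inv <- function(s, e, type = "inversion") {
    data.frame(chrom = "chr5", start = s, end = e, sv_type = type)
  }
  sets <- list(pn = inv(100, 1100), cab = inv(120, 1120),
               char = inv(90, 1080), vrip = inv(5000, 6000))
  out <- validate_large_svs(sets, min_support = 2)
  # the shared inversion is confirmed by the other 2 carriers from each of
  # the 3 carriers' viewpoints; the isolated SV is dropped
  expect_equal(sort(unique(out$source)), c("cab", "char", "pn"))
  expect_true(all(out$n_support == 2))
  # single-comparison SV is never validated
  expect_equal(nrow(validate_large_svs(list(a = inv(1, 10),
                                            b = inv(5000, 6000)))), 0)
  # same interval but different type gives no mutual support
  sets2 <- list(a = inv(100, 1100, "inversion"), b = inv(100, 1100, "indel"),
                c = inv(100, 1100, "indel"))
  out2 <- validate_large_svs(sets2, min_support = 1)
  expect_false("a" %in% out2$source)
  expect_error(validate_large_svs(sets, reciprocal_overlap = 0), "overlap")
})

test_that("SV support is symmetric", {
  set.seed(3)
  mk <- function() {
    s <- sample(1:5000, 5)
    data.frame(chrom = "chr1", start = s, end = s + sample(200:800, 5),
               sv_type = sample(c("inversion", "indel"), 5, TRUE))
  }
  sets <- list(a = mk(), b = mk(), c = mk())
  out <- validate_large_svs(sets, min_support = 1)
  # whenever set o appears in the support of a validated SV from set s,
  # set s must appear in the support of some validated SV from set o
  for (i in seq_len(nrow(out))) {
    for (o in strsplit(out$support[i], ",")[[1]]) {
      back <- out[out$source == o, ]
      expect_true(any(vapply(strsplit(back$support, ","),
                             function(x) out$source[i] %in% x,
                             logical(1))))
    }
  }
  # minimal reciprocal pair: each record supports the other
  a <- data.frame(chrom = "c", start = 0, end = 100, sv_type = "indel")
  b <- data.frame(chrom = "c", start = 40, end = 140, sv_type = "indel")
  ab <- validate_large_svs(list(x = a, y = b), reciprocal_overlap = 0.5,
                           min_support = 1)
  expect_equal(nrow(ab), 2)
})

test_that("contig reassignment uses the inclusive overlap threshold", {
  union <- data.frame(chrom = "chr3", start = 0, end = 100000)
  inside <- data.frame(chrom = "chr3", start = 20000, end = 30000)
  expect_equal(correct_contig_assignment(inside, union)$decision,
               "reassign_to_associate")
  outside <- data.frame(chrom = "chr3", start = 200000, end = 210000)
  expect_equal(correct_contig_assignment(outside, union)$decision,
               "keep_primary")
  # exactly half inside the union: inclusive boundary reassigns
  half <- data.frame(chrom = "chr3", start = 95000, end = 105000)
  r <- correct_contig_assignment(half, union, min_overlap = 0.5)
  expect_equal(r$overlap_fraction, 0.5)
  expect_equal(r$decision, "reassign_to_associate")
})
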