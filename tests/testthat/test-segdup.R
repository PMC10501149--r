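# Segmental duplication detection, gene retention, and NG86 Ka/Ks.

sd_block <- function(qchrom, qstart, qend, rchrom, rstart, rend, identity) {
  data.frame(qchrom = qchrom, qstart = qstart, qend = qend,
             rchrom = rchrom, rstart = rstart, rend = rend, strand = "+",
             identity = identity,
             mismatches = round((1 - identity) * (qend - qstart)),
             stringsAsFactors = FALSE)
}

test_that("SD detection applies the >1 kb and >90% cutoffs strictly", {
  blocks <- rbind(
    sd_block("chr2", 0, 1500, "chr1", 0, 1500, 0.95),    # kept
    sd_block("chr2", 5000, 5900, "chr1", 5000, 5900, 0.99),  # too short
    sd_block("chr2", 9000, 10500, "chr1", 9000, 10500, 0.85), # too diverged
    sd_block("chr2", 20000, 21000, "chr1", 20000, 21000, 0.95)) # exactly 1 kb
  sds <- detect_segmental_duplications(blocks)
  expect_equal(nrow(sds), 1)
  expect_equal(sds$length, 1500)
})

test_that("reciprocal (A,B)/(B,A) records collapse to one SD", {
  blocks <- rbind(
    sd_block("chr2", 100, 1600, "chr1", 5000, 6500, 0.95),
    sd_block("chr1", 5000, 6500, "chr2", 100, 1600, 0.95))
  sds <- detect_segmental_duplications(blocks)
  expect_equal(nrow(sds), 1)
  expect_warning(
    detect_segmental_duplications(sd_block("chr1", 0, 2000, "chr1", 9000,
                                           11000, 0.95)),
    "intra-chromosomal")
})

test_that("gene retention counts exactly-one-intact-copy source regions", {
  # 10 source genes on chr1, each duplicated twice onto chr2; half the
  # copies disrupted so every source keeps exactly one intact copy of two
  src_start <- (0:9) * 5000L
  genes <- data.frame(gene_id = paste0("s", 1:10), chrom = "chr1",
                      start = src_start + 100L, end = src_start + 1400L)
  blocks <- list(); copy_genes <- list()
  for (i in 1:10) {
    for (k in 1:2) {
      cs <- (i - 1L) * 4000L + (k - 1L) * 2000L
      blocks[[length(blocks) + 1L]] <-
        sd_block("chr2", cs, cs + 1500L, "chr1", src_start[i],
                 src_start[i] + 1500L, 0.95)
      if (k == 1) {  # only the first copy keeps an intact gene
        copy_genes[[length(copy_genes) + 1L]] <- data.frame(
          gene_id = paste0("s", i, "_copy"), chrom = "chr2",
          start = cs + 100L, end = cs + 1400L)
      }
    }
  }
  sds <- detect_segmental_duplications(do.call(rbind, blocks))
  cov <- sd_gene_coverage(sds, rbind(genes, do.call(rbind, copy_genes)))
  ret <- cov$retention
  expect_equal(ret$n_multi_source, 10)
  expect_equal(ret$fraction_single_retained, 1.0)
  # with 5 of the sources keeping both copies intact the fraction is 0.5
  extra <- do.call(rbind, lapply(1:5, function(i) data.frame(
    gene_id = paste0("s", i, "_copy2"), chrom = "chr2",
    start = (i - 1L) * 4000L + 2100L, end = (i - 1L) * 4000L + 3400L)))
  cov2 <- sd_gene_coverage(sds, rbind(genes, do.call(rbind, copy_genes),
                                      extra))
  expect_equal(cov2$retention$fraction_single_retained, 0.5)
})

test_that("a gene straddling an SD boundary is not carried", {
  sds <- detect_segmental_duplications(
    sd_block("chr2", 0, 1500, "chr1", 5000, 6500, 0.95))
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 6000,
                      end = 7000)
  expect_equal(nrow(sd_gene_coverage(sds, genes)$pairs), 0)
})

test_that("NG86 handles the trivial substitution patterns", {
  s <- paste(rep("ATGGCTAAACTT", 5), collapse = "")
  out <- ka_ks(s, s)
  expect_equal(out$Ka, 0)
  expect_equal(out$Ks, 0)
  expect_true(is.na(out$ratio))
  # one synonymous change in a tiny CDS: no nonsynonymous divergence
  out2 <- ka_ks("ATGGCTAAA", "ATGGCCAAA")
  expect_equal(out2$Ka, 0)
  expect_true(out2$Ks > 0)
  expect_equal(out2$ratio, 0)
  # one clear nonsynonymous change (GCT -> GTT, Ala -> Val)
  out3 <- ka_ks("ATGGCTAAACTTGGG", "ATGGTTAAACTTGGG")
  expect_true(out3$Ka > 0)
  expect_equal(out3$Ks, 0)
  expect_error(ka_ks("ATG", "ATGGCT"), "equal length")
  expect_error(ka_ks("ATGG", "ATGC"), "divisible by 3")
})

test_that("ka_ks is symmetric and drops ambiguous codons", {
  set.seed(13)
  codons <- setdiff(vitisdiverge:::.all_codons(), c("TAA", "TAG", "TGA"))
  for (rep in 1:5) {
    a <- paste(sample(codons, 50, TRUE), collapse = "")
    b <- strsplit(a, "")[[1]]
    idx <- sample(150, 8)
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    b <- paste(b, collapse = "")
    f <- ka_ks(a, b); r <- ka_ks(b, a)
    expect_equal(f$Ka, r$Ka)
    expect_equal(f$Ks, r$Ks)
  }
  withN <- ka_ks("ATGNCTAAA", "ATGNCCAAA")
  # the N codon is dropped from both sequences entirely
  expect_equal(withN$S + withN$N, ka_ks("ATGAAA", "ATGAAA")$S +
                 ka_ks("ATGAAA", "ATGAAA")$N)
})

test_that("genome-specific SD genes carry the positive-selection flag", {
  pairs <- data.frame(source_gene_id = c("g1", "g2", "g3"),
                      ratio = c(1.3, 0.2, NA))
  cls <- c(g1 = "genome_specific", g2 = "all_shared",
           g3 = "genome_specific")
  out <- genome_specific_sd_genes(pairs, cls)
  expect_equal(out$source_gene_id, c("g1", "g3"))
  expect_equal(out$positive_selection, c(TRUE, NA))
})
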