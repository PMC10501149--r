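# Variant size classes, gene-relative location, and codon-level effects.

test_that("size classes follow the 30-bp threshold and SV type overrides", {
  cases <- data.frame(
    svtype = c("SNP", "DEL", "DEL", "INS", "DEL", "INS", "INV", "DUP",
               "INVDUP", "BND"),
    length = c(0L, 30L, 31L, 2L, 100L, 1L, 12L, 5L, 7L, 0L),
    expect = c("SNP", "small_indel", "SV", "small_indel", "SV",
               "small_indel", "SV", "SV", "SV", "SV"))
  out <- classify_variant(cases)
  expect_equal(out$size_class, cases$expect)
  # 1-bp indels are below the caller minimum and flagged
  expect_equal(out$flagged, cases$svtype %in% c("DEL", "INS") &
                 cases$length == 1L)
})

test_that("classification partitions every record exactly once", {
  set.seed(42)
  v <- data.frame(
    svtype = sample(c("SNP", "DEL", "INS", "INV", "DUP", "BND"), 200, TRUE),
    length = sample(0:200, 200, TRUE))
  v$length[v$svtype == "SNP"] <- 0L
  v$length[v$svtype %in% c("DEL", "INS")] <-
    pmax(1L, v$length[v$svtype %in% c("DEL", "INS")])
  out <- classify_variant(v)
  expect_true(all(out$size_class %in% c("SNP", "small_indel", "SV")))
  expect_equal(sum(table(out$size_class)), nrow(v))
})

test_that("zero-length non-SNP records are rejected as malformed", {
  expect_error(classify_variant(data.frame(svtype = "DEL", length = 0L)),
               "malformed")
})

test_that("variants are located with exon > intron > intergenic priority", {
  models <- list(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       strand = "+", start = c(100L, 400L),
                       end = c(300L, 600L), stringsAsFactors = FALSE),
    features = data.frame(
      gene_id = c("g1", "g1", "g2"), type = "exon",
      start = c(100L, 250L, 400L), end = c(150L, 300L, 600L),
      phase = NA_integer_, stringsAsFactors = FALSE))
  v <- data.frame(chrom = "chr1", pos = c(120L, 200L, 350L, 140L),
                  svtype = c("SNP", "SNP", "SNP", "DEL"),
                  length = c(0L, 0L, 0L, 80L))
  out <- locate_variant(v, models)
  # SNP in exon; SNP in intron; SNP between genes; deletion spanning the
  # exon-intron boundary takes the exon (most consequential) label
  expect_equal(out$region, c("exon", "intron", "intergenic", "exon"))
  expect_equal(out$gene_ids[1], "g1")
  expect_equal(out$gene_ids[3], "")
  # region counts always sum to the variant count
  expect_equal(sum(table(out$region)), nrow(v))
})

test_that("a long deletion overlapping two genes reports both ids", {
  models <- list(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       strand = "+", start = c(100L, 400L),
                       end = c(300L, 600L), stringsAsFactors = FALSE),
    features = data.frame(gene_id = c("g1", "g2"), type = "exon",
                          start = c(100L, 400L), end = c(300L, 600L),
                          phase = NA_integer_, stringsAsFactors = FALSE))
  v <- data.frame(chrom = "chr1", pos = 150L, svtype = "DEL", length = 400L)
  out <- locate_variant(v, models)
  expect_equal(out$gene_ids, "g1,g2")
})

test_that("codon comparison recovers the standard-genetic-code effects", {
  tg <- tiny_gene_model("+")
  # CDS is ATG GCT TAC TAA at [10,22)
  cases <- list(
    list(pos = 12L, ref = "G", alt = "A", expect = "missense"),   # ATG->ATA
    list(pos = 15L, ref = "T", alt = "C", expect = "synonymous"), # GCT->GCC
    list(pos = 18L, ref = "C", alt = "A", expect = "nonsense"),   # TAC->TAA
    list(pos = 17L, ref = "A", alt = "G", expect = "missense"),   # TAC->TGC
    list(pos = 19L, ref = "T", alt = "C", expect = "stop_loss"),  # TAA->CAA
    list(pos = 2L, ref = "G", alt = "A", expect = "noncoding"))
  for (cs in cases) {
    out <- snp_effect(snp_row(cs$pos, cs$ref, cs$alt), tg$models, tg$genome)
    expect_equal(out$effect, cs$expect, info = paste("pos", cs$pos))
  }
})

test_that("minus-strand effects equal the plus-strand construction", {
  plus <- tiny_gene_model("+")
  minus <- tiny_gene_model("-")
  # same transcript SNP expressed in the two genome orientations:
  # transcript position t (1-based) maps to genome pos 10+t-1 on plus and
  # 10+12-t on minus, with complemented alleles
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (t in c(3L, 6L, 10L)) {
    tx_ref <- substr(plus$cds, t, t)
    tx_alt <- setdiff(c("A", "C", "G", "T"), tx_ref)[1]
    out_p <- snp_effect(snp_row(10L + t - 1L, tx_ref, tx_alt),
                        plus$models, plus$genome)
    out_m <- snp_effect(snp_row(10L + 12L - t, comp[[tx_ref]],
                                comp[[tx_alt]]),
                        minus$models, minus$genome)
    expect_equal(out_m$effect, out_p$effect, info = paste("t =", t))
  }
})

test_that("a CDS whose length is not a codon multiple is skipped", {
  tg <- tiny_gene_model("+")
  tg$models$features$end[tg$models$features$type == "CDS"] <- 21L
  tg$models$features$end[tg$models$features$type == "exon"] <- 21L
  expect_warning(out <- snp_effect(snp_row(15L, "T", "C"), tg$models,
                                   tg$genome),
                 "divisible by 3")
  expect_true(is.na(out$effect))
})
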