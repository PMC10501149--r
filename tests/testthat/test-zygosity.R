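# Hemizygous calling, read evidence, the three-way zygosity partition,
# and cross-genome zygosity comparison.

mk_models <- function(n = 3, pitch = 1000L, len = 300L) {
  starts <- (seq_len(n) - 1L) * pitch + 100L
  list(
    genes = data.frame(gene_id = paste0("g", seq_len(n)), chrom = "chr1",
                       strand = "+", start = starts, end = starts + len,
                       stringsAsFactors = FALSE),
    features = data.frame(gene_id = paste0("g", seq_len(n)), type = "exon",
                          start = starts, end = starts + len,
                          phase = NA_integer_, stringsAsFactors = FALSE))
}

test_that("hemizygosity requires full-span containment in one deletion", {
  genes <- mk_models()$genes
  dels <- data.frame(chrom = "chr1", start = c(50L, 1150L),
                     end = c(1000L, 1250L))
  out <- call_hemizygous_genes(dels, genes)
  expect_equal(out$hemizygous, c(TRUE, FALSE, FALSE))  # g2 only half covered
  expect_error(call_hemizygous_genes(dels, rbind(genes, genes)),
               "duplicate")
})

test_that("an unplaced-contig homolog excludes a hemizygous call", {
  genes <- mk_models()$genes
  dels <- data.frame(chrom = "chr1", start = 50L, end = 1000L)
  unp <- data.frame(gene_id = "g1", identity = 0.99, coverage = 0.95)
  out <- call_hemizygous_genes(dels, genes, unp)
  expect_false(out$hemizygous[1])
  expect_true(out$ambiguous[1])
  weak <- data.frame(gene_id = "g1", identity = 0.5, coverage = 0.95)
  out2 <- call_hemizygous_genes(dels, genes, weak)
  expect_true(out2$hemizygous[1])
})

test_that("read-evidence verdicts follow split-read balance", {
  expect_equal(evaluate_read_evidence(20, 20), "supports_hemizygous")
  expect_equal(evaluate_read_evidence(40, 0), "supports_homozygous")
  expect_equal(evaluate_read_evidence(3, 1, min_depth = 10), "inconclusive")
  expect_equal(evaluate_read_evidence(c(20, 40), c(20, 0)),
               c("supports_hemizygous", "supports_homozygous"))
})

located <- function(pos, svtype, len, region, gene, effect = NA) {
  if (!length(pos)) {
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), svtype = character(),
                      length = integer(), size_class = character(),
                      region = character(), gene_ids = character(),
                      effect = character(), stringsAsFactors = FALSE))
  }
  effect <- rep(effect, length.out = length(pos))
  data.frame(chrom = "chr1", pos = pos,
             id = paste0("v", pos), svtype = svtype, length = len,
             size_class = ifelse(svtype == "SNP", "SNP",
                                 ifelse(len > 30, "SV", "small_indel")),
             region = region, gene_ids = gene, effect = effect,
             stringsAsFactors = FALSE)
}

test_that("zygosity classes follow the precedence and fold rule", {
  models <- mk_models()
  none <- located(integer(), character(), integer(), character(),
                  character())
  out <- classify_gene_zygosity(models, none)
  expect_true(all(out$final_class == "homozygous"))

  v <- rbind(
    located(150, "SNP", 0, "exon", "g1", "missense"),
    located(1150, "SNP", 0, "exon", "g2", "synonymous"),
    located(2150, "SNP", 0, "intron", "g3"))
  out <- classify_gene_zygosity(models, v)
  expect_equal(out$final_class, c("protein_het", "homozygous", "homozygous"))
  expect_equal(out$gene_het, c(TRUE, TRUE, TRUE))

  # a deletion containing g1 outranks its exonic missense SNP
  v2 <- rbind(v, located(50, "DEL", 500, "exon", "g1"))
  out2 <- classify_gene_zygosity(models, v2)
  expect_equal(out2$final_class[1], "hemizygous")

  # exonic small indels are protein-level by definition
  v3 <- located(1150, "INS", 4, "exon", "g2")
  expect_equal(classify_gene_zygosity(models, v3)$final_class[2],
               "protein_het")
})

test_that("the three-way classes always partition the gene set", {
  models <- mk_models(10)
  set.seed(9)
  regions <- sample(c("exon", "intron", "intergenic"), 30, TRUE)
  v <- located(seq(100, 3000, by = 100), sample(c("SNP", "DEL", "INS"), 30,
                                                TRUE),
               sample(c(0L, 5L, 100L), 30, TRUE), regions,
               ifelse(regions == "intergenic", "",
                      sample(paste0("g", 1:10), 30, TRUE)),
               sample(c("missense", "synonymous", NA), 30, TRUE))
  v$length[v$svtype == "SNP"] <- 0L
  out <- classify_gene_zygosity(models, v)
  expect_equal(nrow(out), 10)
  expect_equal(sum(out$final_class %in%
                     c("hemizygous", "protein_het", "homozygous")), 10)
})

test_that("adding a missense SNP never downgrades a gene's class", {
  models <- mk_models(1)
  rank <- c(homozygous = 1, protein_het = 2, hemizygous = 3)
  base_sets <- list(
    located(integer(), character(), integer(), character(), character()),
    located(150, "SNP", 0, "intron", "g1"),
    located(150, "SNP", 0, "exon", "g1", "synonymous"),
    located(50, "DEL", 500, "exon", "g1"))
  extra <- located(200, "SNP", 0, "exon", "g1", "missense")
  for (v in base_sets) {
    before <- classify_gene_zygosity(models, v)$final_class
    after <- classify_gene_zygosity(models, rbind(v, extra))$final_class
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("cross-genome comparison counts same/different/non-collinear", {
  rec <- function(ids, cls) data.frame(gene_id = ids, final_class = cls,
                                       stringsAsFactors = FALSE)
  a <- rec(paste0("a", 1:6), c("hemizygous", "hemizygous", "protein_het",
                               "homozygous", "homozygous", "homozygous"))
  b <- rec(paste0("b", 1:6), c("hemizygous", "homozygous", "protein_het",
                               "homozygous", "protein_het", "homozygous"))
  pairs <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5))
  out <- compare_zygosity(a, b, pairs)
  hemi <- out[out$class == "hemizygous", ]
  expect_equal(hemi$n_same, 1)
  expect_equal(hemi$n_different, 1)
  expect_equal(hemi$n_noncollinear, 0)
  hom <- out[out$class == "homozygous", ]
  expect_equal(hom$n_noncollinear, 1)   # a6 has no partner
  expect_equal(hom$n_different, 1)      # a5 -> protein_het partner
  # identical genomes, full pairing: 100 % same class everywhere
  self <- compare_zygosity(a, a, data.frame(gene_a = a$gene_id,
                                            gene_b = a$gene_id))
  expect_true(all(self$pct_same[self$n_total > 0] == 100))
  # empty pair set: everything non-collinear
  none <- compare_zygosity(a, b, pairs[0, ])
  expect_equal(sum(none$n_noncollinear), nrow(a))
  expect_error(compare_zygosity(a, b, data.frame(gene_a = "zz",
                                                 gene_b = "b1")),
               "unknown gene id")
})
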