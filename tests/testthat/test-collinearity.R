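# Collinear chaining, sharing classes, non-collinear mechanisms, and
# trio origin inference.

mk_positions <- function(ranks_b, chrom_b = "c1") {
  n <- length(ranks_b)
  rbind(data.frame(gene_id = paste0("a", 1:n), genome = "A", chrom = "c1",
                   rank = 1:n, stringsAsFactors = FALSE),
        data.frame(gene_id = paste0("b", 1:n), genome = "B",
                   chrom = chrom_b, rank = ranks_b,
                   stringsAsFactors = FALSE))
}

mk_hits <- function(n) {
  data.frame(geneA = paste0("a", 1:n), geneB = paste0("b", 1:n),
             bitscore = 500, evalue = 1e-50, stringsAsFactors = FALSE)
}

test_that("identical gene order chains into a single full block", {
  ch <- chain_collinear_blocks(mk_hits(10), mk_positions(1:10), "A", "B")
  expect_equal(nrow(ch$blocks), 1)
  expect_equal(ch$blocks$n_pairs, 10)
  expect_equal(ch$blocks$orientation, "+")
  expect_equal(collinear_pairs(ch)$gene_a, paste0("a", 1:10))
})

test_that("runs shorter than min_block_size never become blocks", {
  ch <- chain_collinear_blocks(mk_hits(4), mk_positions(1:4), "A", "B",
                               min_block_size = 5)
  expect_equal(nrow(ch$blocks), 0)
})

test_that("inverted gene order is chained as an antiparallel block", {
  ch <- chain_collinear_blocks(mk_hits(8), mk_positions(8:1), "A", "B")
  expect_equal(nrow(ch$blocks), 1)
  expect_equal(ch$blocks$orientation, "-")
  expect_equal(ch$blocks$n_pairs, 8)
})

test_that("rank gaps beyond max_gap break chains", {
  pos <- mk_positions(c(1:5, 200:204))
  pos$rank[pos$genome == "A"] <- c(1:5, 200:204)
  ch <- chain_collinear_blocks(mk_hits(10), pos, "A", "B",
                               min_block_size = 5, max_gap = 25)
  expect_equal(nrow(ch$blocks), 2)
  expect_equal(sort(ch$blocks$n_pairs), c(5, 5))
})

test_that("hits against unranked genes are an input error", {
  hits <- mk_hits(3)
  hits$geneB[2] <- "missing"
  expect_error(chain_collinear_blocks(hits, mk_positions(1:3), "A", "B"),
               "unranked")
})

test_that("sharing classes implement the closed five-way vocabulary", {
  labels <- c(ref = "cultivated", w1 = "wild", w2 = "wild",
              c1 = "cultivated", c2 = "cultivated")
  others <- c("w1", "w2", "c1", "c2")
  presence <- list(
    w1 = c("gAll", "gWild"), w2 = c("gAll", "gWild"),
    c1 = c("gAll", "gCult", "gOne"), c2 = c("gAll", "gCult"))
  cls <- classify_shared_genes(
    c("gAll", "gWild", "gCult", "gNone", "gOne"), presence, labels)
  expect_equal(unname(cls),
               c("all_shared", "wild_shared", "cultivated_shared",
                 "genome_specific", "other_pattern"))
  expect_error(classify_shared_genes("g", list(zz = "g"), labels),
               "unlabeled")
})

test_that("non-collinear mechanisms split into loss/translocation/duplication", {
  hits <- data.frame(geneA = c("g2", "g3"), geneB = c("x1", "x2"),
                     evalue = c(1e-30, 1e-30))
  self <- data.frame(geneA = "g3", geneB = "g9", evalue = 1e-50)
  cls <- c(g1 = "all_shared", g2 = "all_shared", g3 = "genome_specific")
  out <- classify_noncollinear_mechanism(c("g1", "g2", "g3"), hits, self,
                                         cls)
  expect_equal(unname(out), c("lost_in_other", "translocated_in_other",
                              "duplicate_origin"))
  # homology above the e-value cutoff does not count
  weak <- data.frame(geneA = "g1", geneB = "x9", evalue = 1e-2)
  out2 <- classify_noncollinear_mechanism("g1", weak, NULL, NULL)
  expect_equal(unname(out2), "lost_in_other")
})

test_that("trio origin follows the strict full-coverage rule", {
  in_a <- c(h1 = TRUE, h2 = FALSE, h3 = TRUE, h4 = FALSE)
  cov <- c(h1 = 1 - 1 / 1500, h2 = 1, h3 = 1, h4 = 0.6)
  out <- infer_hemizygote_origin(names(in_a), in_a, cov)
  expect_equal(out$call, c("from_parentA", "from_parentB", "both_present",
                           "unexplained"))
  # one uncovered base defeats presence in parent B
  expect_false(out$present_b[1])
  expect_warning(
    out2 <- infer_hemizygote_origin(c("h1", "h9"), in_a,
                                    c(h1 = 1)),
    "missing parent-B coverage")
  expect_equal(out2$call[2], "unexplained")
})

test_that("gene coverage fractions come from the interval union", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(0L, 2000L), end = c(1000L, 3000L))
  cov <- data.frame(chrom = "chr1", start = c(0L, 600L, 2000L),
                    end = c(500L, 1000L, 2400L))
  fr <- gene_covered_fraction(genes, cov)
  expect_equal(unname(fr["g1"]), 0.9)
  expect_equal(unname(fr["g2"]), 0.4)
})

test_that("chaining is symmetric up to coordinate reflection", {
  swap <- function(hits) data.frame(geneA = hits$geneB, geneB = hits$geneA,
                                    bitscore = hits$bitscore,
                                    evalue = hits$evalue)
  # tie-free structure (one forward, one inverted block): exact symmetry
  pos <- mk_positions(c(1:5, 10:6))
  hits <- mk_hits(10)
  fwd <- chain_collinear_blocks(hits, pos, "A", "B", min_block_size = 3)
  rev <- chain_collinear_blocks(swap(hits), pos, "B", "A",
                                min_block_size = 3)
  f <- collinear_pairs(fwd); r <- collinear_pairs(rev)
  expect_setequal(paste(f$gene_a, f$gene_b), paste(r$gene_b, r$gene_a))
  # random permutations: equally many blocks of the same sizes and scores
  # (equal-score optima may be resolved differently per direction)
  set.seed(21)
  for (rep in 1:5) {
    pos <- mk_positions(sample(10))
    fwd <- chain_collinear_blocks(hits, pos, "A", "B", min_block_size = 3)
    rev <- chain_collinear_blocks(swap(hits), pos, "B", "A",
                                  min_block_size = 3)
    expect_equal(sort(fwd$blocks$n_pairs), sort(rev$blocks$n_pairs))
    expect_equal(sort(fwd$blocks$score), sort(rev$blocks$score))
  }
})
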