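# The synthetic panel generator: determinism, self-consistency of the
# emitted haplotypes against the VCF, capacity errors, and the stated
# limiting behaviours.

test_that("the same config and seed give byte-identical output trees", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_panel(small_config(seed = 5), d1)
  generate_panel(small_config(seed = 5), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  m1 <- tools::md5sum(file.path(d1, f1))
  m2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(m1), unname(m2))
  # a different seed changes the tree
  d3 <- file.path(tempdir(), "det3")
  unlink(d3, recursive = TRUE)
  generate_panel(small_config(seed = 6), d3)
  m3 <- tools::md5sum(file.path(d3, f1))
  expect_false(all(unname(m1) == unname(m3)))
})

test_that("with no variation planted every gene is homozygous", {
  cfg <- sim_config(seed = 3, chrom_length = 120000L, gene_count = 60L,
                    snp_rate = 0, small_indel_rate = 0,
                    sv_deletion_count = 0L, sv_insertion_count = 0L,
                    sv_inversion_count = 0L, protein_het_count = 0L,
                    gene_het_count = 0L, sd_count = 3L)
  d <- file.path(tempdir(), "novar")
  unlink(d, recursive = TRUE)
  res <- generate_panel(cfg, d)
  expect_true(all(res$truth$genes$planted_class == "homozygous"))
  expect_equal(nrow(res$truth$variants), 0)
})

test_that("impossible placements raise explicit capacity errors", {
  expect_error(sim_config(gene_count = -1), "non-negative")
  expect_error(sim_config(snp_rate = 1.5), "rates")
  expect_error(sim_config(te_effect = -2), "negative te_effect")
  cfg <- sim_config(seed = 1, chrom_length = 30000L, gene_count = 40L)
  expect_error(generate_panel(cfg, file.path(tempdir(), "cap")),
               "capacity")
})

test_that("the emitted haplotypes reproduce the VCF by direct comparison", {
  res <- demo_panel()
  g <- res$genomes[1]
  prim <- read_genome_fa(file.path(res$dir, g, "primary.fasta"))
  asc <- read_genome_fa(file.path(res$dir, g, "associate.fasta"))
  tv <- res$truth$variants[res$truth$variants$genome == g, ]
  revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in seq_len(nrow(tv))) {
    v <- tv[i, ]
    p <- as.character(prim[[v$chrom]])
    a <- as.character(asc[[v$chrom]])
    if (v$svtype == "SNP") {
      expect_equal(substr(p, v$pos + 1, v$pos + 1), v$ref)
      expect_equal(substr(a, v$apos + 1, v$apos + 1), v$alt)
    } else if (v$svtype == "DEL") {
      expect_equal(substr(p, v$pos + 1, v$pos + 1 + v$length), v$ref)
      expect_equal(substr(a, v$apos + 1, v$apos + 1), substr(v$ref, 1, 1))
    } else if (v$svtype == "INS") {
      expect_equal(substr(a, v$apos + 1, v$apos + 1 + v$length), v$alt)
      expect_equal(substr(p, v$pos + 1, v$pos + 1), substr(v$alt, 1, 1))
    } else if (v$svtype == "INV") {
      expect_equal(substr(a, v$apos + 1, v$apos + v$length),
                   revcomp(substr(p, v$pos + 1, v$pos + v$length)))
    }
  }
  # and the emitted VCF matches the truth table record for record
  vcf <- read_variant_calls(file.path(res$dir, g, "variants.vcf"))
  expect_equal(vcf$pos, tv$pos)
  expect_equal(vcf$svtype, tv$svtype)
  expect_equal(vcf$length, tv$length)
})

test_that("read alignment evidence follows the binomial split model", {
  expect_equal(simulate_read_alignments("homozygous", 40),
               list(spanning = 40L, split = 0L))
  out <- simulate_read_alignments("hemizygous", 40, seed = 99)
  expect_equal(out$spanning + out$split, 40L)
  set.seed(99)
  expect_equal(out$split, rbinom(1, 40, 0.5))
  expect_error(simulate_read_alignments("homozygous", 0), "depth")
})

test_that("expression counts react to TE proportion as configured", {
  prof <- data.frame(gene_id = paste0("g", 1:4), genome = "A",
                     base = 6, proportion = c(0, 0.2, 0.4, 0.6))
  cfg0 <- sim_config(te_effect = 0, expression_noise_sd = 0)
  e0 <- generate_expression(prof, cfg0)
  expect_equal(length(unique(e0$counts$A[, 1])), 1)  # TE-independent
  cfg1 <- sim_config(te_effect = 5, expression_noise_sd = 0)
  e1 <- generate_expression(prof, cfg1)
  expect_true(all(diff(e1$counts$A[, 1]) < 0))       # monotone suppression
  expect_equal(e1$expected$mu, 6 - 5 * prof$proportion)
})

test_that("planted truth agrees with its own emitted files", {
  res <- demo_panel()
  tg <- res$truth$genes
  # per-genome class counts equal the configured study conditions
  for (g in res$genomes) {
    cls <- table(tg$planted_class[tg$genome == g])
    expect_equal(unname(cls[["hemizygous"]]), 5)
    expect_equal(unname(cls[["protein_het"]]), 20)
    expect_equal(unname(cls[["gene_het_only"]]), 30)
  }
  # gene models on disk match the truth coordinates
  g <- res$genomes[2]
  models <- read_gene_models(file.path(res$dir, g, "genes.gff3"))
  m <- merge(models$genes, tg[tg$genome == g, ], by = "gene_id")
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
  expect_equal(m$strand.x, m$strand.y)
})
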