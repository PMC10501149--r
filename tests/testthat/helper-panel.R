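# Shared fixtures: a memoised demo panel at the default study conditions,
# a reduced configuration for fast end-to-end runs, and the
# classify-from-files path used by the recovery tests.

demo_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "vd-demo-panel")
      cache <<- generate_panel(sim_config(seed = 1), dir)
    }
    cache
  }
})

small_config <- function(seed = 1) {
  sim_config(seed = seed, chrom_length = 120000L, gene_count = 60L,
             sv_deletion_count = 10L, sv_insertion_count = 6L,
             protein_het_count = 5L, gene_het_count = 5L, sd_count = 3L,
             snp_rate = 8e-4, small_indel_rate = 1.5e-4)
}

read_genome_fa <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

# variant -> zygosity path exactly as the pipeline runs it, from files
classify_from_files <- function(dir, g) {
  models <- read_gene_models(file.path(dir, g, "genes.gff3"))
  fa <- read_genome_fa(file.path(dir, g, "primary.fasta"))
  v <- read_variant_calls(file.path(dir, g, "variants.vcf"))
  v <- classify_variant(v)
  v <- locate_variant(v, models)
  v <- snp_effect(v, models, fa)
  v$gene_ids[is.na(v$gene_ids)] <- ""
  dels <- v[v$size_class == "SV" & v$svtype == "DEL", , drop = FALSE]
  dels$start <- dels$pos
  dels$end <- dels$pos + dels$length
  unp <- read.delim(file.path(dir, g, "unplaced_hits.tsv"),
                    comment.char = "#")
  hemi <- call_hemizygous_genes(dels, models$genes, unp)
  classify_gene_zygosity(models, v, hemi)
}

# tiny single-gene model used across the variant/zygosity tests:
# 60-base chromosome, one 12-base single-exon CDS at [10, 22)
tiny_gene_model <- function(strand = "+") {
  cds <- "ATGGCTTACTAA"
  left <- "GGGGGGGGGG"
  right <- paste(rep("C", 38), collapse = "")
  if (strand == "+") {
    seq <- paste0(left, cds, right)
  } else {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    seq <- paste0(left, rc, right)
  }
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  models <- list(
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
                       start = 10L, end = 22L, stringsAsFactors = FALSE),
    features = data.frame(gene_id = "g1", type = c("exon", "CDS"),
                          start = 10L, end = 22L, phase = c(NA, 0L),
                          stringsAsFactors = FALSE))
  list(genome = genome, models = models, cds = cds)
}

snp_row <- function(pos, ref, alt) {
  data.frame(chrom = "chr1", pos = pos, id = "v1", ref = ref, alt = alt,
             svtype = "SNP", length = 0L, stringsAsFactors = FALSE)
}
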