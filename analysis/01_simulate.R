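#!/usr/bin/env Rscript
# Stage 1: generate the synthetic diploid grapevine-like panel with
# planted ground truth.  Five genomes (two wild, three cultivated), two
# haplotypes each, 200 genes per genome over 2 x 500 kb chromosomes.
suppressPackageStartupMessages(library(vitisdiverge))

cfg <- sim_config(seed = 1)
out <- "results/pipeline"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

panel <- generate_panel(cfg, file.path(out, "data"))
truth <- panel$truth

message("genomes: ", paste(cfg$genomes, collapse = ", "))
message("genes per genome (incl. intact SD copies):")
print(table(truth$genes$genome))
message("planted zygosity classes (per genome):")
print(table(truth$genes$genome, truth$genes$planted_class))
message("planted variants: ", nrow(truth$variants),
        " across the panel (",
        paste(names(table(truth$variants$size_class)),
              table(truth$variants$size_class), collapse = ", "), ")")

write.table(truth$genes, "results/tables/truth_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$heterozygosity, "results/tables/truth_heterozygosity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("panel written under ", file.path(out, "data"))
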