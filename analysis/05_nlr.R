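#!/usr/bin/env Rscript
# Stage 5: NLR receptor classification, 200-kb clustering, integrated
# domains, and overlap with downy-mildew resistance (RPV) loci.
suppressPackageStartupMessages(library(vitisdiverge))

cfg <- sim_config(seed = 1)
run <- run_pipeline(cfg, "results/pipeline")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

nlr <- run$results$nlr
write.table(nlr, "results/tables/nlr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(run$results$nlr_clusters, "results/tables/nlr_clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

receptors <- nlr[nlr$subgroup != "not_nlr", ]
message("NLR subgroups per genome:")
print(table(receptors$genome, receptors$subgroup))
for (grp in c("wild", "cultivated")) {
  gs <- cfg$genomes[cfg$labels == grp]
  ratios <- vapply(gs, function(g)
    tnl_ratio(receptors[receptors$genome == g, ]), numeric(1))
  message("TNL:(non-TNL) ratio, ", grp, " genomes: ",
          paste(round(ratios, 2), collapse = ", "))
}
cl <- run$results$nlr_clusters
message("clusters (200-kb linkage) per genome:")
print(table(cl$genome))
ov <- read.delim(file.path("results/pipeline/stages/nlr_rpv.tsv"),
                 comment.char = "#")
message("reference-genome clusters overlapping RPV loci: ", nrow(ov))
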