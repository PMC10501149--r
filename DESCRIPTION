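Package: vitisdiverge
Title: Comparative Genomics of Diploid Grapevine Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested analysis pipeline, a set of
    comparative-genomics procedures for phased diploid grapevine genomes:
    intragenomic heterozygosity from haplotype-pair alignments, variant size
    classification and coding effects, gene zygosity calling (hemizygous /
    protein-level heterozygous / homozygous) from structural variants, gene
    collinearity chaining and sharing classes across a genome panel,
    trio-based inference of hemizygous-gene parental origin, segmental
    duplication detection with Nei-Gojobori Ka/Ks screening, NLR receptor
    classification and clustering, and transposable-element insertion
    polymorphism with expression correlation. A synthetic diploid genome
    panel generator with planted ground truth exercises every stage
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
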