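---
title: "Methods: comparative analysis of diploid grapevine-like genome panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of diploid grapevine-like genome panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

vitisdiverge re-implements, as one tested pipeline, the comparative
procedures used to characterise diversification between wild and
cultivated grapevine genomes: intragenomic (haplotype-pair)
heterozygosity, variant size classes and coding effects, gene zygosity,
gene collinearity and sharing classes, trio-based origin of hemizygous
genes, segmental duplications with a Ka/Ks screen, NLR receptor
classification and clustering, and transposable-element (TE) insertion
polymorphism in gene regulatory regions.  The package ships a synthetic
diploid panel generator whose planted ground truth is the test bed for
every stage; the numbered scripts under `analysis/` walk through the
stages on the default panel.

All internal coordinates are 0-based half-open; conversion to the
1-based closed convention happens only when reading or writing GFF3 and
VCF.

# Intragenomic heterozygosity

The divergence between the two haplotypes of a chromosome is
`100 * (unaligned + dissimilar) / L`, where `L` is the associate
(query) chromosome length, `unaligned` counts associate bases outside
the union of aligned intervals, and `dissimilar` counts mismatching
bases inside alignments.  Where alignment blocks overlap, coverage is
taken on the interval union and the mismatch density of the
best-identity block covering a base is used, so no base is counted
twice.  The genome value is the length-weighted aggregate over
chromosomes.  Indel bases inside alignments are not counted as
dissimilar; insertion bases surface in the unaligned term (an explicit
convention of this package — alignment tools differ here, and the
choice is stated rather than guessed).

# Variants and zygosity

Variant size classes follow the 30-bp convention: single-base
substitutions are SNPs, indels of 2–30 bp are small indels, longer
indels and all inversions/duplications/breakends are structural
variants (SVs).  One-base indels, below the usual caller minimum of 2,
are classed as small indels and flagged.  Coding effects of exonic SNPs
are computed by codon comparison under the standard genetic code, with
minus-strand genes handled by reverse complement.

A gene is *hemizygous* when its full span is contained in a single
deletion between the haplotypes; deletions are not chained, and genes
with a high-homology counterpart (>= 90 % identity over >= 90 % of
their length) among unplaced-contig genes are excluded as ambiguous.  A
gene is *protein-level heterozygous* when any exonic indel/SV overlaps
it (any coding length change alters the protein) or any exonic SNP is
missense, nonsense or stop-loss; *gene-level heterozygous* when any
variant falls in the gene body.  The reported three-way classification
(hemizygous > protein-level > homozygous) folds gene-level-only
heterozygotes into the homozygous class, so the three classes always
partition the gene set — an identity the summary enforces as a hard
error.  Read evidence (spanning vs boundary-split reads, a ~50/50 mix
over a hemizygous locus) is carried as a validation verdict alongside
the call, never as a gate.

# Collinearity, sharing classes and trio origin

Homology hits (one best hit per query) are chained per chromosome pair
by dynamic programming over gene ranks: a chain extends while both rank
gaps are at most 25, with a unit score per pair and a penalty of 0.01
per skipped rank — small enough that an extra pair always beats a
shorter chain, so the optimum is the longest valid chain.  Chains of at
least 5 pairs become blocks (both MCScanX-style defaults are exposed);
antiparallel chains capture inversions.  Chains are extracted greedily
best-first; equal-score optima are resolved toward the lexicographically
smallest hit-index sequence, which makes the output unique and lets an
exhaustive enumeration oracle reproduce it in the tests (symmetry under
swapping genome roles therefore holds up to ties).  Blocks overlapping
on both rank intervals are redundant alternates and the lower e-value
is kept.

Sharing classes are strict: a reference gene collinear in every other
genome is `all_shared`; collinear in exactly the other cultivated
(wild) genomes is `cultivated_shared` (`wild_shared`); collinear
nowhere is `genome_specific`; every other pattern is reported as
`other_pattern` rather than forced into a class.  Non-collinear genes
are explained mechanistically: genome-specific genes with a
within-genome homolog (e-value <= 1e-4) are duplication-derived, genes
with no homolog in the partner genome were lost there, and genes whose
homolog sits outside any block were translocated.

For the trio, a hemizygous offspring gene is present in the sequenced
parent when it has a collinear partner there, and present in the
read-only parent when every base of its body is covered at depth >= 1 —
the strictest reading of "fully covered", exposed as a parameter.
Present in exactly one parent gives the origin call; both-present and
neither-present genes are reported separately, not forced.

# Segmental duplications and Ka/Ks

Inter-chromosomal alignment blocks longer than 1 kb at more than 90 %
identity are segmental duplications (SDs); 0.92 is exposed as the
recently-originated preset.  Reciprocal (A,B)/(B,A) records collapse.
Aligned length (not interval span) is compared against the 1-kb cutoff.
A gene is SD-carried when its full span lies in one SD interval; among
source genes duplicated multiple times, the retention summary is the
fraction whose duplications kept exactly one intact copy.

Ka/Ks uses Nei–Gojobori (1986) counting: synonymous site fractions per
codon averaged over both sequences, substitution counts averaged over
all minimal mutational pathways (pathways through stop codons excluded;
if every pathway is blocked, all are used), and the Jukes–Cantor
correction `d = -(3/4) log(1 - (4/3) p)`.  At `p = 3/4` the limiting
value `Inf` is returned and beyond it `NA`; both set a saturation flag.
The ratio is defined only when Ks > 0.  Codons containing `N` (or
gaps) in either sequence are dropped from both.  NG86 with Jukes–Cantor
was chosen over maximum-likelihood codon models deliberately: it is
deterministic, dependency-free, exactly testable against a per-codon
enumeration oracle (the tests cover all 4,096 ordered codon pairs), and
fully adequate for the binary Ka/Ks > 1 screen this pipeline performs.

# NLR receptors

Receptors require an NB-ARC domain.  The N-terminal signature decides
the subgroup with precedence TIR > CC_R > CC (mixed N-terminal domains
are undefined in the source rule; TIR is the most diagnostic, so TNL
wins): TNL, RNL, CNL, otherwise NL.  Clustering is single-linkage on
start-to-start distances, inclusive at 200 kb.  Non-canonical domains
are integrated domains (IDs); the incidence table flags group-exclusive
IDs and applies the display filter of more than 2 carrier genes while
retaining the full table.  RPV resistance loci are intersected with
cluster spans directly.

# TE insertion polymorphism and expression

Upstream/body/downstream TE proportions are interval-union coverage
fractions of strand-aware 1-kb windows, truncated at chromosome edges
with the truncated length as denominator.  A collinear group is
TE-insertion polymorphic when at least one genome has proportion
exactly 0 and at least one has >= 0.20 (the inclusive reading of the
"≥200 bp (20 %)" rule; the stricter ">20 %" alternative would differ
only at exact equality).  Expression is TPM per replicate, then the
mean of log2(TPM+1) across replicates; Pearson correlation between the
combined LTR+MITE upstream proportion and expression across genomes
(Pearson, not rank-based: with 4–5 panel points a rank statistic is
nearly degenerate) flags candidates at r < -0.9.  Upstream genotyping
applies the 0.20 presence rule per haplotype: none/one/both inserted
give `hom_no_te` / `het_te` / `hom_te`.

# The synthetic panel

The generator emulates a panel of five related genomes (two wild, three
cultivated), two 500-kb chromosomes and 200 genes each — a deliberately
small scale at which every stage runs in seconds while exercising every
code path.  Genes are 1.5-kb two-exon models with valid CDS; an
ancestral "slot" design with per-genome membership quotas produces
conserved gene order, shared / group-shared / genome-specific /
translocated content, and duplication-derived specific genes, so the
realised sharing classes derive from membership rather than being
asserted.  Per genome, the associate haplotype is built from the
primary by applying planted variants — background SNPs at 1.2e-3 per
intergenic base (about the 1-per-828-bases regime of a wild diploid),
small indels at 1.5e-4, background SV deletions/insertions/inversions,
five gene-deleting deletions, twenty exonic missense SNPs and thirty
intronic SNPs — at non-overlapping positions (rejection sampling with
explicit capacity errors), so every truth record is unambiguous.
Haplotype alignment blocks, homology hits and SD blocks are emitted
from construction bookkeeping, keeping the package download-free and
the truth exact.

TE patterns are planted per collinear group (none / constant /
polymorphic); expected log2 expression is a per-group baseline
(uniform on 4–8) minus `te_effect` times the upstream TE proportion,
with Gaussian log-scale noise per replicate.  The suppression strength
has no published value, so it is a free parameter; the default of 4
log2 units per unit proportion makes a planted insertion roughly halve
to quarter expression, a magnitude in line with the reported
promoter-insertion silencing examples.  The planted NLR set gives
cultivated genomes a TNL:(non-TNL) ratio near 1:4 and wild genomes near
1:2 via a wild-specific TNL expansion, with one dense receptor cluster
overlapped by planted RPV loci.  SD sources on chromosome 1 are copied
(with substitutions biased to third codon positions, or to second
positions with a synonymous minority for the planted
positive-selection subset, never creating premature stops in intact
copies) into a reserved zone of chromosome 2; disrupted copies span the
full source gene but carry a premature stop and no gene model, so
retention can be measured.

What the panel does *not* emulate: read-level sequencing error,
assembly artefacts, repeat-driven misalignment, TE families beyond
LTR/MITE labels, and realistic genome-scale feature densities.  Passing
tests therefore demonstrate correctness of the procedures under clean,
exactly-known input — not robustness to the noise sources a real
assembly carries.

# Numerical and degenerate-input conventions

Thresholds from the source procedures are defaults, not constants:
30 bp (SV vs small indel), 1 kb / 0.90 (SD), 200 kb (clusters), 0.20
(TE presence), -0.9 (candidate r), 0.90/0.95 (monomer identity and
coverage).  The monomer search is an ungapped full-length sliding scan
(Hamming identity, both strands): monomer arrays diverge mainly by
substitution, the identity/coverage thresholds are preserved, and the
scan is exactly reproducible by a brute-force all-positions oracle.
Boundary conventions are inclusive where the rule says "within" or
"at": 200-kb linkage, 0.20 TE presence, min_overlap contig
reassignment.  Degenerate inputs return defined values: empty alignment
sets give 100 % unaligned; empty NLR sets give an undefined (NA) TNL
ratio; zero-variance expression gives an undefined correlation with a
recorded reason; all-zero count samples give zero TPM with a warning.

The pipeline manifest records md5 checksums and record counts per
stage; a fixed seed and config reproduce every checksum, and re-runs
over an unchanged directory skip stages whose inputs and outputs are
intact.  Test and demonstration problem sizes (five genomes, 1 Mb per
genome, 200 genes; 100-seed chaining oracle on 12-gene toys; a
500-replicate Monte-Carlo null for the correlation screen) were chosen
so the whole suite exercises every stage in about a minute on one core.

# Known limitations

* The chaining tie-break is deterministic but asymmetric under genome
  swap when distinct optimal chains tie exactly.
* Only inter-chromosomal SDs are detected; tandem duplications are out
  of scope.
* The heterozygosity denominator is the associate assembly, so
  associate-side deletions shrink the denominator rather than entering
  the numerator.
* `other_pattern` aggregates all partial sharing patterns; no attempt
  is made to interpret them phylogenetically.
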