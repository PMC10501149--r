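# End-to-end pipeline over an emitted panel directory: each stage reads
# the standard-format files, runs the corresponding module, writes its
# outputs, and registers them in a checksummed manifest.  Re-runs skip
# stages whose inputs and outputs are unchanged.

.config_hash <- function(cfg) {
  # digest of the canonical JSON serialisation
  unname(tools::md5sum(local({
    f <- tempfile()
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
               f)
    f
  })))
}

.files_md5 <- function(paths, root = NULL) {
  paths <- paths[file.exists(paths)]
  md5 <- unname(tools::md5sum(paths))
  keys <- if (is.null(root)) paths else
    ifelse(startsWith(paths, paste0(root, "/")),
           substring(paths, nchar(root) + 2L), paths)
  setNames(md5, keys)
}

# manifest entries survive a JSON round trip as lists; compare on content
.md5_same <- function(old, now) {
  o <- unlist(old)
  if (is.null(o)) o <- setNames(character(0), character(0))
  length(o) == length(now) && identical(sort(names(o)), sort(names(now))) &&
    all(o[names(now)] == now)
}

#' Extract the spliced CDS of one gene
#'
#' @param models Gene models list.
#' @param genome `DNAStringSet` of the assembly.
#' @param gene_id Gene identifier.
#' @return Character scalar, transcript-oriented CDS.
#' @export
gene_cds_seq <- function(models, genome, gene_id) {
  gi <- match(gene_id, models$genes$gene_id)
  if (is.na(gi)) stop("unknown gene id: ", gene_id)
  chrom <- models$genes$chrom[gi]
  strand <- models$genes$strand[gi]
  cds <- models$features[models$features$type == "CDS" &
                           models$features$gene_id == gene_id, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  seq <- genome[[chrom]]
  parts <- lapply(seq_len(nrow(cds)), function(i)
    as.character(seq[(cds$start[i] + 1L):cds$end[i]]))
  out <- paste0(unlist(parts), collapse = "")
  if (strand == "-") {
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out)))
  }
  out
}

.read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Run the full analysis pipeline on a panel directory
#'
#' Stages: simulate, variants, zygosity, heterozygosity, synteny, origin,
#' segdup, nlr, tepoly, then a consistency-checked summary.  Every stage
#' registers its outputs (with md5 checksums and record counts) in the
#' manifest; re-running over an unchanged directory skips up-to-date
#' stages.
#'
#' @param config A [sim_config()].
#' @param out_dir Working directory; the simulated panel lands in
#'   `out_dir/data`, stage outputs in `out_dir/stages`.
#' @param force Recompute every stage even if up to date.
#' @return List: `manifest`, `summary` (data.frame of headline counts),
#'   and `results` (per-stage in-memory objects).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  data_dir <- file.path(out_dir, "data")
  stage_dir <- file.path(out_dir, "stages")
  dir.create(stage_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (!force && file.exists(manifest_path)) {
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  } else NULL
  cfg_hash <- .config_hash(config)
  if (!is.null(old_manifest) && !identical(old_manifest$config_hash,
                                           cfg_hash)) {
    old_manifest <- NULL
  }
  stages <- list()
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  run_stage <- function(name, input_files, output_files, n_records_fn,
                        compute) {
    in_md5 <- .files_md5(input_files, out_dir)
    old <- NULL
    for (s in old_manifest$stages) if (identical(s$name, name)) old <- s
    up_to_date <- !is.null(old) &&
      .md5_same(old$inputs, in_md5) &&
      all(file.exists(output_files)) &&
      .md5_same(old$outputs, .files_md5(output_files, out_dir))
    if (!up_to_date) compute()
    out_md5 <- .files_md5(output_files, out_dir)
    stages[[length(stages) + 1L]] <<- list(
      name = name, cache_hit = up_to_date,
      inputs = as.list(in_md5), outputs = as.list(out_md5),
      n_records = n_records_fn())
    invisible(NULL)
  }

  genomes <- config$genomes
  gfile <- function(g, f) file.path(data_dir, g, f)
  sfile <- function(f) file.path(stage_dir, f)

  ## 1. simulate ------------------------------------------------------------
  sim_outputs <- unlist(lapply(genomes, function(g)
    gfile(g, c("primary.fasta", "associate.fasta", "genes.gff3",
               "variants.vcf", "haplotype_blocks.tsv", "sd_blocks.tsv",
               "te.bed", "te_haplotype.tsv", "domains.tsv", "counts.tsv",
               "read_evidence.tsv"))))
  sim_outputs <- c(sim_outputs, file.path(data_dir, "rpv.bed"),
                   file.path(data_dir, "trio_coverage.bed"))
  run_stage("simulate", character(), sim_outputs,
            function() length(sim_outputs),
            function() generate_panel(config, data_dir))

  models <- lapply(setNames(genomes, genomes), function(g)
    read_gene_models(gfile(g, "genes.gff3")))
  genomes_fa <- lapply(setNames(genomes, genomes), function(g)
    .read_genome_fasta(gfile(g, "primary.fasta")))

  ## 2. variants ------------------------------------------------------------
  var_out <- vapply(genomes, function(g)
    sfile(paste0("variants_", g, ".tsv")), character(1))
  run_stage("variants",
            unlist(lapply(genomes, function(g)
              gfile(g, c("variants.vcf", "genes.gff3", "primary.fasta")))),
            var_out,
            function() sum(vapply(var_out, function(f)
              nrow(.read_tsv(f)), integer(1))),
            function() {
    for (g in genomes) {
      v <- read_variant_calls(gfile(g, "variants.vcf"))
      v <- classify_variant(v)
      v <- locate_variant(v, models[[g]])
      v <- snp_effect(v, models[[g]], genomes_fa[[g]])
      .write_tsv(v[, c("chrom", "pos", "id", "svtype", "length",
                       "size_class", "region", "gene_ids", "effect")],
                 sfile(paste0("variants_", g, ".tsv")),
                 "classified and located variants; pos 0-based")
    }
  })
  variants <- lapply(setNames(genomes, genomes), function(g)
    .read_tsv(sfile(paste0("variants_", g, ".tsv"))))

  ## 3. zygosity ------------------------------------------------------------
  zyg_out <- vapply(genomes, function(g)
    sfile(paste0("zygosity_", g, ".tsv")), character(1))
  run_stage("zygosity", var_out, zyg_out,
            function() sum(vapply(zyg_out, function(f)
              nrow(.read_tsv(f)), integer(1))),
            function() {
    for (g in genomes) {
      v <- variants[[g]]
      v$gene_ids <- ifelse(is.na(v$gene_ids), "", v$gene_ids)
      dels <- v[v$size_class == "SV" & v$svtype == "DEL", , drop = FALSE]
      dels$start <- dels$pos
      dels$end <- dels$pos + dels$length
      unp <- .read_tsv(gfile(g, "unplaced_hits.tsv"))
      hemi <- call_hemizygous_genes(dels, models[[g]]$genes, unp)
      rec <- classify_gene_zygosity(models[[g]], v, hemi)
      ev <- .read_tsv(gfile(g, "read_evidence.tsv"))
      rec$read_verdict <- evaluate_read_evidence(
        ev$spanning[match(rec$gene_id, ev$gene_id)],
        ev$split[match(rec$gene_id, ev$gene_id)])
      .write_tsv(rec, sfile(paste0("zygosity_", g, ".tsv")),
                 "per-gene zygosity records")
    }
  })
  zygosity <- lapply(setNames(genomes, genomes), function(g)
    .read_tsv(sfile(paste0("zygosity_", g, ".tsv"))))

  ## 4. heterozygosity ------------------------------------------------------
  het_out <- sfile("heterozygosity.tsv")
  run_stage("heterozygosity",
            unlist(lapply(genomes, function(g)
              gfile(g, c("haplotype_blocks.tsv", "associate.fasta")))),
            het_out,
            function() nrow(.read_tsv(het_out)),
            function() {
    rows <- list()
    for (g in genomes) {
      blocks <- read_alignment_blocks(gfile(g, "haplotype_blocks.tsv"))
      assoc <- .read_genome_fasta(gfile(g, "associate.fasta"))
      per_chrom <- lapply(names(assoc), function(ch) {
        chromosome_heterozygosity(
          blocks[blocks$qchrom == ch, , drop = FALSE],
          length(assoc[[ch]]), chrom = ch)
      })
      per_chrom <- do.call(rbind, per_chrom)
      per_chrom$genome <- g
      per_chrom$genome_pct <- genome_heterozygosity(per_chrom)
      rows[[g]] <- per_chrom
    }
    .write_tsv(do.call(rbind, rows), het_out,
               "intragenomic variation per chromosome and genome")
  })
  het <- .read_tsv(het_out)

  ## 5. synteny -------------------------------------------------------------
  positions <- do.call(rbind, lapply(genomes, function(g) {
    gdf <- models[[g]]$genes
    gdf <- gdf[order(gdf$chrom, gdf$start), ]
    rank <- stats::ave(gdf$start, gdf$chrom, FUN = seq_along)
    data.frame(gene_id = gdf$gene_id, genome = g, chrom = gdf$chrom,
               rank = as.integer(rank), stringsAsFactors = FALSE)
  }))
  pair_names <- t(utils::combn(genomes, 2))
  syn_out <- c(sfile("collinear_pairs.tsv"), sfile("shared_classes.tsv"))
  run_stage("synteny",
            c(unlist(lapply(genomes, function(g) gfile(g, "genes.gff3"))),
              file.path(data_dir, "hits",
                        paste0(pair_names[, 1], "__", pair_names[, 2],
                               ".tsv"))),
            syn_out,
            function() nrow(.read_tsv(syn_out[1])),
            function() {
    all_pairs <- list()
    for (k in seq_len(nrow(pair_names))) {
      a <- pair_names[k, 1]; b <- pair_names[k, 2]
      hits <- read_homology_hits(
        file.path(data_dir, "hits", paste0(a, "__", b, ".tsv")))
      ch <- chain_collinear_blocks(hits, positions, a, b)
      cp <- collinear_pairs(ch)
      if (nrow(cp)) {
        all_pairs[[k]] <- data.frame(genome_a = a, genome_b = b, cp,
                                     stringsAsFactors = FALSE)
      }
    }
    all_pairs <- do.call(rbind, all_pairs)
    .write_tsv(all_pairs, syn_out[1], "collinear gene pairs per genome pair")
    shared <- do.call(rbind, lapply(genomes, function(g) {
      others <- setdiff(genomes, g)
      presence <- lapply(setNames(others, others), function(o) {
        fw <- all_pairs[all_pairs$genome_a == g & all_pairs$genome_b == o, ]
        bw <- all_pairs[all_pairs$genome_a == o & all_pairs$genome_b == g, ]
        unique(c(fw$gene_a, bw$gene_b))
      })
      cls <- classify_shared_genes(
        positions$gene_id[positions$genome == g], presence, config$labels)
      data.frame(genome = g, gene_id = names(cls), shared_class = unname(cls),
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(shared, syn_out[2], "sharing class per gene")
  })
  coll_pairs <- .read_tsv(syn_out[1])
  shared <- .read_tsv(syn_out[2])

  ## 6. origin (trio) -------------------------------------------------------
  origin_out <- sfile("origin.tsv")
  offspring <- config$trio_offspring
  parent_a <- config$trio_parent_a
  run_stage("origin",
            c(zyg_out[match(offspring, genomes)], syn_out[1],
              file.path(data_dir, "trio_coverage.bed")),
            origin_out,
            function() nrow(.read_tsv(origin_out)),
            function() {
    zo <- zygosity[[offspring]]
    hemi_ids <- zo$gene_id[zo$final_class == "hemizygous"]
    fw <- coll_pairs[coll_pairs$genome_a == offspring &
                       coll_pairs$genome_b == parent_a, ]
    bw <- coll_pairs[coll_pairs$genome_a == parent_a &
                       coll_pairs$genome_b == offspring, ]
    in_a <- setNames(rep(TRUE, length(unique(c(fw$gene_a, bw$gene_b)))),
                     unique(c(fw$gene_a, bw$gene_b)))
    cov <- read_bed(file.path(data_dir, "trio_coverage.bed"))
    gdf <- models[[offspring]]$genes
    frac <- gene_covered_fraction(gdf[gdf$gene_id %in% hemi_ids, ,
                                      drop = FALSE], cov)
    res <- infer_hemizygote_origin(hemi_ids, in_a, frac)
    .write_tsv(res, origin_out, "parental origin of hemizygous genes")
  })
  origin <- .read_tsv(origin_out)

  ## 7. segdup --------------------------------------------------------------
  sd_out <- c(sfile("segdup.tsv"), sfile("segdup_genes.tsv"))
  run_stage("segdup",
            c(unlist(lapply(genomes, function(g)
              gfile(g, c("sd_blocks.tsv", "genes.gff3", "primary.fasta")))),
              syn_out[2]),
            sd_out,
            function() nrow(.read_tsv(sd_out[1])),
            function() {
    sds_all <- list(); pairs_all <- list()
    for (g in genomes) {
      blocks <- read_alignment_blocks(gfile(g, "sd_blocks.tsv"))
      sds <- detect_segmental_duplications(blocks)
      cov <- sd_gene_coverage(sds, models[[g]]$genes)
      sds$genome <- g
      sds$retention_fraction <- cov$retention$fraction_single_retained
      sds_all[[g]] <- sds
      p <- cov$pairs
      if (nrow(p)) {
        p$genome <- g
        kk <- lapply(seq_len(nrow(p)), function(i) {
          if (!p$copy_has_intact_gene[i]) {
            return(list(Ka = NA_real_, Ks = NA_real_, ratio = NA_real_))
          }
          ka_ks(gene_cds_seq(models[[g]], genomes_fa[[g]],
                             p$source_gene_id[i]),
                gene_cds_seq(models[[g]], genomes_fa[[g]],
                             p$copy_gene_id[i]))
        })
        p$Ka <- vapply(kk, function(x) x$Ka, numeric(1))
        p$Ks <- vapply(kk, function(x) x$Ks, numeric(1))
        p$ratio <- vapply(kk, function(x) x$ratio, numeric(1))
        sc <- setNames(shared$shared_class[shared$genome == g],
                       shared$gene_id[shared$genome == g])
        p$source_shared_class <- unname(sc[p$source_gene_id])
        p$genome_specific_copy <- !is.na(sc[p$copy_gene_id]) &
          sc[p$copy_gene_id] == "genome_specific"
        p$positive_selection <- ifelse(is.na(p$ratio), NA, p$ratio > 1)
        pairs_all[[g]] <- p
      }
    }
    .write_tsv(do.call(rbind, sds_all), sd_out[1],
               "segmental duplications per genome")
    .write_tsv(do.call(rbind, pairs_all), sd_out[2],
               "gene-carrying SDs with NG86 Ka/Ks")
  })
  sds <- .read_tsv(sd_out[1])
  sd_genes <- .read_tsv(sd_out[2])

  ## 8. nlr -----------------------------------------------------------------
  nlr_out <- c(sfile("nlr.tsv"), sfile("nlr_clusters.tsv"),
               sfile("nlr_ids.tsv"), sfile("nlr_rpv.tsv"))
  run_stage("nlr",
            c(unlist(lapply(genomes, function(g) gfile(g, "domains.tsv"))),
              file.path(data_dir, "rpv.bed")),
            nlr_out,
            function() nrow(.read_tsv(nlr_out[1])),
            function() {
    nlr_sets <- list(); clusters_all <- list()
    for (g in genomes) {
      doms <- .read_tsv(gfile(g, "domains.tsv"))
      cls <- classify_nlr(doms)
      cls$genome <- g
      nlr_sets[[g]] <- cls
      pos <- models[[g]]$genes
      pos <- pos[pos$gene_id %in% cls$gene_id[cls$subgroup != "not_nlr"], ]
      cl <- cluster_nlr_genes(data.frame(gene_id = pos$gene_id,
                                         chrom = pos$chrom,
                                         start = pos$start))
      cl$clusters$genome <- g
      clusters_all[[g]] <- cl$clusters
    }
    .write_tsv(do.call(rbind, nlr_sets), nlr_out[1],
               "NLR subgroup per gene")
    .write_tsv(do.call(rbind, clusters_all), nlr_out[2],
               "NLR clusters (200-kb linkage)")
    ids <- compare_integrated_domains(nlr_sets, config$labels)
    .write_tsv(ids, nlr_out[3], "integrated-domain incidence")
    ref_g <- config$wild_labels[1]
    rpv <- read_bed(file.path(data_dir, "rpv.bed"))
    names(rpv)[names(rpv) == "name"] <- "name"
    ov <- overlap_rpv(clusters_all[[ref_g]], rpv)
    .write_tsv(ov, nlr_out[4], "NLR cluster / RPV locus overlaps")
  })
  nlr_tab <- .read_tsv(nlr_out[1])
  nlr_clusters <- .read_tsv(nlr_out[2])

  ## 9. tepoly --------------------------------------------------------------
  te_out <- c(sfile("te_profiles.tsv"), sfile("te_polymorphism.tsv"),
              sfile("te_genotypes.tsv"))
  run_stage("tepoly",
            c(unlist(lapply(genomes, function(g)
              gfile(g, c("te.bed", "genes.gff3", "counts.tsv",
                         "te_haplotype.tsv")))),
              syn_out[1]),
            te_out,
            function() nrow(.read_tsv(te_out[2])),
            function() {
    profiles <- list(); logexpr <- list()
    for (g in genomes) {
      tes <- read_bed(gfile(g, "te.bed"))
      gdf <- models[[g]]$genes
      prof <- te_proportion(gdf, tes, flank = config$flank)
      prof$genome <- g
      profiles[[g]] <- prof
      cm <- .read_tsv(gfile(g, "counts.tsv"))
      counts <- as.matrix(cm[, -1, drop = FALSE])
      rownames(counts) <- cm$gene_id
      logexpr[[g]] <- mean_log_expression(counts,
                                          rep(1500, nrow(counts)))
    }
    .write_tsv(do.call(rbind, profiles), te_out[1],
               "TE coverage proportions per gene")
    # collinear groups: reference-genome genes with partners everywhere
    ref_g <- genomes[1]
    others <- setdiff(genomes, ref_g)
    partner <- lapply(setNames(others, others), function(o) {
      fw <- coll_pairs[coll_pairs$genome_a == ref_g &
                         coll_pairs$genome_b == o, ]
      bw <- coll_pairs[coll_pairs$genome_a == o &
                         coll_pairs$genome_b == ref_g, ]
      m <- c(setNames(fw$gene_b, fw$gene_a), setNames(bw$gene_a, bw$gene_b))
      m[!duplicated(names(m))]
    })
    ref_ids <- positions$gene_id[positions$genome == ref_g]
    in_all <- ref_ids[vapply(ref_ids, function(r)
      all(vapply(partner, function(p) r %in% names(p), logical(1))),
      logical(1))]
    prop_mat <- matrix(NA_real_, length(in_all), length(genomes),
                       dimnames = list(in_all, genomes))
    expr_mat <- prop_mat
    prof_by <- do.call(rbind, profiles)
    up <- setNames(prof_by$proportion_up1kb, prof_by$gene_id)
    for (r in in_all) {
      grp <- c(setNames(r, ref_g),
               vapply(others, function(o) unname(partner[[o]][r]),
                      character(1)))
      for (g in genomes) {
        prop_mat[r, g] <- up[[grp[[g]]]]
        expr_mat[r, g] <- logexpr[[g]][[grp[[g]]]]
      }
    }
    poly <- te_expression_correlation(prop_mat, expr_mat)
    .write_tsv(poly, te_out[2],
               "TE insertion polymorphism and expression correlation")
    gts <- do.call(rbind, lapply(genomes, function(g) {
      th <- .read_tsv(gfile(g, "te_haplotype.tsv"))
      gt <- genotype_upstream(th$prop_up_primary, th$prop_up_associate)
      data.frame(genome = g, gene_id = th$gene_id, gt,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(gts, te_out[3], "upstream TE genotype per gene")
  })
  te_poly <- .read_tsv(te_out[2])
  te_genotypes <- .read_tsv(te_out[3])

  ## summary ----------------------------------------------------------------
  summary <- summarize_run(list(
    genomes = genomes, zygosity = zygosity, het = het, shared = shared,
    sds = sds, sd_genes = sd_genes, nlr = nlr_tab, te_poly = te_poly,
    origin = origin, models = models))
  .write_tsv(summary, sfile("summary.tsv"), "headline counts per genome")

  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   started = t0,
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = stages)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), manifest_path)
  list(manifest = manifest, summary = summary,
       results = list(zygosity = zygosity, het = het, shared = shared,
                      sds = sds, sd_genes = sd_genes, nlr = nlr_tab,
                      nlr_clusters = nlr_clusters, te_poly = te_poly,
                      te_genotypes = te_genotypes, origin = origin,
                      coll_pairs = coll_pairs))
}

#' Checksum table of a manifest
#'
#' Stage/file/md5 triples, the deterministic part of a manifest; two runs
#' of the same config and seed must agree on it exactly.
#'
#' @param manifest Manifest list from [run_pipeline()].
#' @return Data.frame: stage, file, md5.
#' @export
manifest_checksums <- function(manifest) {
  do.call(rbind, lapply(manifest$stages, function(s) {
    if (!length(s$outputs)) return(NULL)
    data.frame(stage = s$name, file = names(unlist(s$outputs)),
               md5 = unname(unlist(s$outputs)), stringsAsFactors = FALSE)
  }))
}

#' Summarise a pipeline run with partition checks
#'
#' Asserts the zygosity partition identity (class counts sum to the gene
#' total) and the sharing-class partition before emitting the headline
#' table; an inconsistent partition is an error, not a warning.
#'
#' @param x List of stage outputs (as assembled by [run_pipeline()]).
#' @return Data.frame of per-genome headline counts.
#' @export
summarize_run <- function(x) {
  rows <- lapply(x$genomes, function(g) {
    z <- x$zygosity[[g]]
    n_genes <- nrow(x$models[[g]]$genes)
    counts <- table(factor(z$final_class,
                           levels = c("hemizygous", "protein_het",
                                      "homozygous")))
    if (sum(counts) != n_genes || nrow(z) != n_genes) {
      stop("zygosity classes do not partition the gene set in ", g)
    }
    sh <- x$shared[x$shared$genome == g, ]
    if (nrow(sh) != n_genes) {
      stop("sharing classes do not partition the gene set in ", g)
    }
    nl <- x$nlr[x$nlr$genome == g & x$nlr$subgroup != "not_nlr", ]
    sdg <- x$sd_genes[x$sd_genes$genome == g, ]
    data.frame(
      genome = g,
      n_genes = n_genes,
      n_hemizygous = as.integer(counts[["hemizygous"]]),
      n_protein_het = as.integer(counts[["protein_het"]]),
      n_homozygous = as.integer(counts[["homozygous"]]),
      pct_het_or_hemi = 100 * (counts[["hemizygous"]] +
                                 counts[["protein_het"]]) / n_genes,
      het_pct = x$het$genome_pct[match(g, x$het$genome)],
      n_all_shared = sum(sh$shared_class == "all_shared"),
      n_genome_specific = sum(sh$shared_class == "genome_specific"),
      n_sds = sum(x$sds$genome == g),
      n_sd_genes = length(unique(sdg$source_gene_id)),
      n_nlr = nrow(nl),
      tnl_ratio = tnl_ratio(nl),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_poly <- sum(x$te_poly$is_polymorphic)
  out$n_te_polymorphic_groups <- n_poly
  out$n_te_candidates <- sum(x$te_poly$candidate, na.rm = TRUE)
  out
}
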