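# Readers and writers for the tabular and standard genomic formats used
# across the pipeline.  Internal coordinates are 0-based half-open; GFF3 and
# VCF are converted at this boundary.  All writers use fixed formatting so
# that a fixed seed yields byte-identical output trees.

.write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wb")  # binary: identical line endings everywhere
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}

#' Read / write pairwise alignment blocks
#'
#' Coords-style tab-separated records: `qchrom qstart qend rchrom rstart
#' rend strand identity mismatches`, 0-based half-open on both sides.
#'
#' @param path File path.
#' @return A data.frame of alignment blocks.
#' @export
read_alignment_blocks <- function(path) {
  df <- .read_tsv(path)
  needed <- c("qchrom", "qstart", "qend", "rchrom", "rstart", "rend",
              "strand", "identity", "mismatches")
  if (!all(needed %in% names(df))) {
    stop("alignment block file lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df
}

#' @rdname read_alignment_blocks
#' @param blocks Data.frame of alignment blocks.
#' @export
write_alignment_blocks <- function(blocks, path) {
  .write_tsv(blocks, path,
             "alignment blocks; coordinates 0-based half-open")
}

#' Read / write homology hit tables
#'
#' One best hit per query (`geneA`), with bitscore and e-value.
#'
#' @param path File path.
#' @return A data.frame with columns geneA, geneB, bitscore, evalue.
#' @export
read_homology_hits <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("geneA", "geneB", "bitscore", "evalue") %in% names(df)))
  df
}

#' @rdname read_homology_hits
#' @param hits Data.frame of homology hits.
#' @export
write_homology_hits <- function(hits, path) {
  .write_tsv(hits, path, "homology hits; one best hit per query gene")
}

#' Read gene models from GFF3
#'
#' Returns gene spans plus exon and CDS features keyed by gene id, with
#' coordinates converted to the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return List with data.frames `genes` (gene_id, chrom, strand, start,
#'   end) and `features` (gene_id, type, start, end, phase).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  gid <- function(x) {
    id <- x$ID
    if (!is.null(x$Parent)) {
      par <- vapply(x$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
      id <- ifelse(is.na(par) | par == "", id, par)
    }
    id
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  feats <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  list(
    genes = data.frame(
      gene_id = genes$ID,
      chrom = as.character(genes$seqnames),
      strand = as.character(genes$strand),
      start = genes$start - 1L,
      end = genes$end,
      stringsAsFactors = FALSE
    ),
    features = data.frame(
      gene_id = gid(feats),
      type = as.character(feats$type),
      start = feats$start - 1L,
      end = feats$end,
      phase = if ("phase" %in% names(feats)) as.integer(feats$phase) else NA_integer_,
      stringsAsFactors = FALSE
    )
  )
}

#' Write gene models to GFF3
#'
#' @param models List as returned by [read_gene_models()].
#' @param path Output file.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  f <- models$features
  lines <- c("##gff-version 3",
             "# coordinates 1-based closed (converted from internal 0-based half-open)")
  gene_lines <- sprintf("%s\tvitisdiverge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  # interleave features after their gene, in gene order
  f <- f[order(match(f$gene_id, g$gene_id), f$start), , drop = FALSE]
  chrom_of <- setNames(g$chrom, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)
  feat_lines <- sprintf("%s\tvitisdiverge\t%s\t%d\t%d\t.\t%s\t%s\tID=%s:%s%d;Parent=%s",
                        chrom_of[f$gene_id], f$type, f$start + 1L, f$end,
                        strand_of[f$gene_id],
                        ifelse(is.na(f$phase), ".", as.character(f$phase)),
                        f$gene_id, tolower(f$type),
                        stats::ave(seq_len(nrow(f)), f$gene_id, f$type,
                                   FUN = seq_along),
                        f$gene_id)
  ord <- order(match(c(g$gene_id, f$gene_id), g$gene_id),
               c(rep(0L, nrow(g)), rep(1L, nrow(f))),
               c(g$start, f$start))
  body <- c(gene_lines, feat_lines)[ord]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, body), con)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' @param path BED file.
#' @return Data.frame with chrom, start, end, name (and score if present).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  df
}

#' @rdname read_bed
#' @param df Data.frame with at least chrom, start, end.
#' @export
write_bed <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open", con)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read variant calls from VCF
#'
#' Parsed with vcfR; honours SVTYPE/SVLEN INFO keys and symbolic ALTs
#' such as `<DEL>`.  Positions are converted to 0-based.
#'
#' @param path VCF file.
#' @return Data.frame with chrom, pos (0-based), id, ref, alt, svtype, length.
#' @export
read_variant_calls <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(),
                      svtype = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  svtype <- unname(vcfR::extract.info(v, "SVTYPE"))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  len <- ifelse(!is.na(svlen), abs(svlen), abs(nchar(alt) - nchar(ref)))
  svtype[is.na(svtype)] <- ifelse(
    nchar(ref[is.na(svtype)]) == 1L & nchar(alt[is.na(svtype)]) == 1L, "SNP",
    ifelse(nchar(ref[is.na(svtype)]) > nchar(alt[is.na(svtype)]), "DEL",
           "INS"))
  data.frame(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]) - 1L,
    id = unname(fix[, "ID"]),
    ref = unname(ref),
    alt = unname(alt),
    svtype = unname(svtype),
    length = as.integer(len),
    stringsAsFactors = FALSE
  )
}

#' Write variant calls to VCF 4.2
#'
#' @param variants Data.frame as returned by [read_variant_calls()].
#' @param path Output path.
#' @param reference Label written into the header.
#' @export
write_variant_calls <- function(variants, path, reference = "primary") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", reference),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length difference between REF and ALT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(variants)) {
    info <- sprintf("SVTYPE=%s;SVLEN=%d", variants$svtype, variants$length)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                       variants$chrom, variants$pos + 1L, variants$id,
                       variants$ref, variants$alt, info), con)
  }
  invisible(path)
}

#' Write a DNAStringSet as FASTA with fixed line width
#' @noRd
.write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}
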