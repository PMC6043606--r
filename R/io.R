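#' Read a per-position pileup count table
#'
#' Plain TSV with header: `chrom`, `pos` (1-based), `ref_base` and read
#' counts `A`, `C`, `G`, `T`.
#'
#' @param path file path.
#' @return a `pileup_counts` data frame.
#' @export
read_pileup_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref_base", BASES)
  if (!all(need %in% names(x)))
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "))
  class(x) <- c("pileup_counts", "data.frame")
  x
}

#' Write a pileup count table as TSV
#' @param pileup a `pileup_counts` data frame.
#' @param path output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data frame with `chrom`, `start`, `end` (1-based
#'   inclusive, as used throughout the package).
#' @param path output path.
#' @param name optional name column values.
#' @export
write_bed <- function(intervals, path, name = NULL) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end)
  if (!is.null(name)) bed$name <- name
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genotype table as a minimal VCF
#'
#' One sample, GT-only FORMAT; genotype classes map to `0/0`, `0/1`, `1/1`.
#' Uses vcfR when available to assemble and write the object.
#'
#' @param genotype a genotype data frame (`chrom`, `pos`, `ref_base`,
#'   `alt_base`, `gt`).
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @param sample sample name.
#' @export
write_genotype_vcf <- function(genotype, path, sample = "sample1") {
  gt_str <- c("0/0", "0/1", "1/1")[genotype$gt + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    paste(genotype$chrom, genotype$pos, ".", genotype$ref_base,
          genotype$alt_base, ".", "PASS", ".", "GT", gt_str, sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read per-isolate SNP calls from a VCF
#'
#' Parses a single-sample VCF into the raw-call table consumed by
#' [refine_snps()]. Requires the vcfR package.
#'
#' @param path VCF path.
#' @return data frame `chrom`, `pos`, `ref`, `alt`, `gt` (1 = het, 2 =
#'   hom-nonref; hom-ref rows are dropped).
#' @export
read_snp_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)[, 1]
  cls <- ifelse(gt %in% c("0/1", "0|1", "1/0", "1|0"), 1L,
         ifelse(gt %in% c("1/1", "1|1"), 2L, 0L))
  out <- data.frame(chrom = vcfR::getCHROM(v),
                    pos = as.integer(vcfR::getPOS(v)),
                    ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                    gt = cls, stringsAsFactors = FALSE)
  out[out$gt > 0, , drop = FALSE]
}

#' Write a cladogram in Newick format
#' @param clade result of [build_cladogram()].
#' @param path output path.
#' @export
write_newick <- function(clade, path) {
  writeLines(clade$newick, path)
  invisible(path)
}
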