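#' Cross-isolate SNP-call refinement
#'
#' Variant callers applied per isolate miss genuine heterozygous positions in
#' one isolate that were confidently called in another, even when supporting
#' reads are present. Refinement takes the union of raw calls across isolates
#' and, at each called position, rescues a heterozygous call in every other
#' isolate with sufficient coverage and sufficient reads supporting the same
#' alternate allele; covered positions without support become homozygous
#' reference, under-covered ones missing.
#'
#' @param calls named list (one element per isolate) of raw-call data frames
#'   with columns `chrom`, `pos`, `ref`, `alt`, `gt` (1 = het, 2 =
#'   hom-nonref).
#' @param pileups named list of `pileup_counts` data frames on the same
#'   coordinates (names matching `calls`).
#' @param min_depth minimum total depth for a rescued or hom-ref call.
#' @param min_alt_frac minimum fraction of reads carrying the same alternate
#'   allele for a rescue.
#' @return a `snp_matrix`: data frame with key columns `chrom`, `pos`, `ref`,
#'   `alt` (multi-allelic positions stay as separate rows), one genotype
#'   column `gt_<isolate>` (0/1/2, NA = missing) and one provenance column
#'   `src_<isolate>` ("raw", "rescued", "homref", "missing").
#' @export
refine_snps <- function(calls, pileups, min_depth = 10, min_alt_frac = 0.2) {
  isolates <- names(calls)
  if (is.null(isolates) || any(isolates == ""))
    stop("calls must be a named list")
  if (!setequal(isolates, names(pileups)))
    stop("calls and pileups must cover the same isolates")
  all_calls <- do.call(rbind, lapply(isolates, function(id)
    calls[[id]][, c("chrom", "pos", "ref", "alt", "gt")]))
  key <- with(all_calls, paste(chrom, pos, alt, sep = ":"))
  sites <- all_calls[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), , drop = FALSE]
  rownames(sites) <- NULL
  skey <- with(sites, paste(chrom, pos, alt, sep = ":"))
  for (id in isolates) {
    gt <- rep(NA_integer_, nrow(sites))
    src <- rep("missing", nrow(sites))
    ck <- with(calls[[id]], paste(chrom, pos, alt, sep = ":"))
    hit <- match(skey, ck)
    gt[!is.na(hit)] <- calls[[id]]$gt[hit[!is.na(hit)]]
    src[!is.na(hit)] <- "raw"
    p <- pileups[[id]]
    pk <- paste(p$chrom, p$pos, sep = ":")
    ph <- match(paste(sites$chrom, sites$pos, sep = ":"), pk)
    covered <- which(is.na(hit) & !is.na(ph))
    if (length(covered)) {
      cnt <- as.matrix(p[ph[covered], BASES, drop = FALSE])
      depth <- rowSums(cnt)
      altc <- cnt[cbind(seq_along(covered), match(sites$alt[covered], BASES))]
      deep <- depth >= min_depth
      rescue <- deep & (altc / pmax(depth, 1)) >= min_alt_frac & altc > 0
      gt[covered[rescue]] <- 1L
      src[covered[rescue]] <- "rescued"
      homref <- deep & !rescue
      gt[covered[homref]] <- 0L
      src[covered[homref]] <- "homref"
    }
    sites[[paste0("gt_", id)]] <- gt
    sites[[paste0("src_", id)]] <- src
  }
  structure(sites, class = c("snp_matrix", "data.frame"),
            isolates = isolates)
}

#' Build a SNP matrix directly from genotype data frames
#'
#' Convenience constructor for simulated data: takes per-isolate genotype
#' tables (as produced by [simulate_sexual_isolate()] or
#' [simulate_clonal_isolates()]) and assembles the cross-isolate matrix
#' without a rescue step. Positions absent from an isolate's table are
#' recorded as homozygous reference (the simulation observes every site).
#'
#' @param genotypes named list of genotype data frames.
#' @return a `snp_matrix` (see [refine_snps()]); provenance columns all "raw".
#' @export
snp_matrix_from_genotypes <- function(genotypes) {
  isolates <- names(genotypes)
  if (is.null(isolates) || any(isolates == ""))
    stop("genotypes must be a named list")
  allg <- do.call(rbind, lapply(genotypes, function(g)
    g[g$gt > 0, c("chrom", "pos", "ref_base", "alt_base")]))
  names(allg) <- c("chrom", "pos", "ref", "alt")
  key <- with(allg, paste(chrom, pos, alt, sep = ":"))
  sites <- allg[!duplicated(key), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), , drop = FALSE]
  rownames(sites) <- NULL
  skey <- with(sites, paste(chrom, pos, alt, sep = ":"))
  for (id in isolates) {
    g <- genotypes[[id]]
    gk <- paste(g$chrom, g$pos, g$alt_base, sep = ":")
    hit <- match(skey, gk)
    gt <- ifelse(is.na(hit), 0L, g$gt[hit])
    sites[[paste0("gt_", id)]] <- gt
    sites[[paste0("src_", id)]] <- "raw"
  }
  structure(sites, class = c("snp_matrix", "data.frame"), isolates = isolates)
}

matrix_isolates <- function(matrix) {
  iso <- attr(matrix, "isolates")
  if (is.null(iso)) iso <- sub("^gt_", "", grep("^gt_", names(matrix), value = TRUE))
  iso
}

# logical matrix: site x isolate, TRUE where the isolate carries a SNP
snp_presence <- function(matrix, snp_classes = 1L) {
  iso <- matrix_isolates(matrix)
  m <- sapply(iso, function(id) matrix[[paste0("gt_", id)]] %in% snp_classes)
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(matrix))
  colnames(m) <- iso
  m
}

#' Per-isolate SNP totals, sharing with a reference isolate, and private SNPs
#'
#' SNPs are heterozygous positions by default (`snp_classes = 1`). Shared
#' percentage for isolate i is `|SNPs(i) intersect SNPs(ref)| / |SNPs(i)|`;
#' a private SNP is carried by exactly one isolate. Missing genotypes do not
#' count as carrying or lacking a SNP.
#'
#' @param matrix a `snp_matrix`.
#' @param reference_isolate isolate id used as the sharing reference.
#' @param snp_classes genotype classes counted as a SNP (default het only).
#' @return data frame: `isolate`, `n_snps`, `shared_with_ref_pct`,
#'   `n_private`.
#' @export
sharing_stats <- function(matrix, reference_isolate, snp_classes = 1L) {
  if (nrow(matrix) == 0) stop("empty SNP matrix")
  iso <- matrix_isolates(matrix)
  if (!reference_isolate %in% iso)
    stop("unknown reference isolate: ", reference_isolate)
  pres <- snp_presence(matrix, snp_classes)
  carriers <- rowSums(pres)
  ref <- pres[, reference_isolate]
  data.frame(
    isolate = iso,
    n_snps = colSums(pres),
    shared_with_ref_pct = 100 * colSums(pres & ref) / pmax(colSums(pres), 1),
    n_private = colSums(pres & carriers == 1),
    row.names = NULL, stringsAsFactors = FALSE)
}
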