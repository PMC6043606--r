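#' Compute the per-position non-reference read fraction R
#'
#' For each position, `rc` counts reads carrying the reference base and `nc`
#' counts reads carrying the most common non-reference base; the statistic is
#' `R = nc / (nc + rc)`. Using only the most common non-reference nucleotide
#' discards part of the technical error: positions where a second
#' non-reference base also has appreciable support most likely reflect
#' sequencing artefacts and are flagged as ambiguous.
#'
#' @param pileup a `pileup_counts` data frame (`chrom`, `pos`, `ref_base`,
#'   counts `A`, `C`, `G`, `T`).
#' @param ambiguous_frac flag a position when the second-best non-reference
#'   count exceeds `max(1, ambiguous_frac * nc)`.
#' @return an `r_track` data frame: `chrom`, `pos`, `rc`, `nc`, `depth`
#'   (`rc + nc`), `R` (NA at depth 0), `ambiguous`.
#' @export
compute_R <- function(pileup, ambiguous_frac = 0.2) {
  cnt <- as.matrix(pileup[, BASES])
  if (any(cnt < 0)) stop("negative read counts")
  ref_idx <- match(pileup$ref_base, BASES)
  n <- nrow(cnt)
  rc <- cnt[cbind(seq_len(n), ref_idx)]
  nonref <- cnt
  nonref[cbind(seq_len(n), ref_idx)] <- -1L
  best <- max.col(nonref, ties.method = "first")
  nc <- pmax(nonref[cbind(seq_len(n), best)], 0L)
  nonref[cbind(seq_len(n), best)] <- -1L
  second <- pmax(nonref[cbind(seq_len(n), max.col(nonref, ties.method = "first"))], 0L)
  depth <- rc + nc
  R <- ifelse(depth > 0, nc / depth, NA_real_)
  out <- data.frame(chrom = pileup$chrom, pos = pileup$pos,
                    rc = rc, nc = nc, depth = depth, R = R,
                    ambiguous = second > pmax(1, ambiguous_frac * nc),
                    stringsAsFactors = FALSE)
  class(out) <- c("r_track", "data.frame")
  out
}

#' Classify positions into genotype classes from R
#'
#' Positions with depth outside `[cov_lo, cov_hi]` (extreme read coverage) are
#' excluded; ambiguous positions keep their flag; the remainder are called
#' hom-ref (`R` below the band), het (`R` inside the band) or hom-nonref
#' (`R` above the band).
#'
#' @param track an `r_track` from [compute_R()].
#' @param cov_lo,cov_hi inclusive depth bounds. Defaults are 0.25x and 2x the
#'   genome-wide median depth.
#' @param het_band numeric length-2: the inclusive R band called heterozygous.
#' @return the track with a `class` column (factor: hom-ref, het, hom-nonref,
#'   ambiguous, excluded) and the class counts as `attr(, "counts")`.
#' @export
classify_positions <- function(track, cov_lo = NULL, cov_hi = NULL,
                               het_band = c(0.2, 0.8)) {
  lv <- c("hom-ref", "het", "hom-nonref", "ambiguous", "excluded")
  if (nrow(track) == 0) {
    track$class <- factor(character(), levels = lv)
    attr(track, "counts") <- table(track$class)
    return(track)
  }
  med <- stats::median(track$depth)
  if (is.null(cov_lo)) cov_lo <- 0.25 * med
  if (is.null(cov_hi)) cov_hi <- 2 * med
  if (cov_lo >= cov_hi) stop("cov_lo must be below cov_hi")
  cls <- ifelse(track$depth < cov_lo | track$depth > cov_hi | is.na(track$R),
                "excluded",
         ifelse(track$ambiguous, "ambiguous",
         ifelse(track$R < het_band[1], "hom-ref",
         ifelse(track$R > het_band[2], "hom-nonref", "het"))))
  track$class <- factor(cls, levels = lv)
  attr(track, "counts") <- table(track$class)
  track
}

#' Test the Hardy-Weinberg 2:1 heterozygous : homozygous-non-reference ratio
#'
#' Under HWE with the reference sequence being one random haplotype from the
#' population, a polymorphic site is heterozygous with probability 2pq and
#' homozygous non-reference with probability pq, so among such sites the
#' heterozygous fraction is 2/3. The exact binomial test of that fraction
#' detects the clonal signature (a gross deficit of homozygous non-reference
#' positions).
#'
#' @param n_het,n_homnonref observed class counts.
#' @return list with `ratio` (`n_het / n_homnonref`, Inf when the denominator
#'   is 0), `p_value` (two-sided exact binomial test of het fraction = 2/3)
#'   and the inputs.
#' @export
hwe_ratio_test <- function(n_het, n_homnonref) {
  n <- n_het + n_homnonref
  if (n <= 0) stop("need at least one het or hom-nonref position")
  ratio <- if (n_homnonref == 0) Inf else n_het / n_homnonref
  p <- stats::binom.test(n_het, n, p = 2 / 3)$p.value
  list(ratio = ratio, p_value = p, n_het = n_het, n_homnonref = n_homnonref)
}

#' Estimate reference-mapping bias from the heterozygous R mode
#'
#' Aligners retain reads matching the reference more readily than reads
#' carrying the alternate allele, shifting the heterozygous mode of R below
#' 0.5. If the mode sits at `m = b / (1 + b)`, the implied bias is
#' `b = m / (1 - m)`.
#'
#' @param het_R vector of R values at heterozygous positions.
#' @return the estimated bias multiplier in (0, 1].
#' @export
estimate_mapping_bias <- function(het_R) {
  het_R <- het_R[!is.na(het_R)]
  if (length(het_R) < 50) stop("too few heterozygous positions to estimate bias")
  d <- stats::density(het_R, bw = 0.02, from = 0.05, to = 0.95)
  m <- d$x[which.max(d$y)]
  min(m / (1 - m), 1)
}

#' Rescale R for mapping bias
#'
#' Multiplicatively rescales the non-reference count by `1 / bias` so that
#' heterozygous positions re-centre at R = 0.5:
#' `R' = (nc / bias) / (nc / bias + rc)`.
#'
#' @param track an `r_track`.
#' @param bias multiplier in (0, 1], e.g. from [estimate_mapping_bias()].
#' @return the track with `R` replaced by the corrected value.
#' @export
correct_bias <- function(track, bias) {
  if (bias <= 0 || bias > 1) stop("bias must be in (0, 1]")
  sc <- track$nc / bias
  track$R <- ifelse(track$depth > 0, sc / (sc + track$rc), NA_real_)
  track
}

# local maxima of a density curve with height at least min_height * max
density_modes <- function(x, min_height = 0.2, bw = 0.02) {
  d <- stats::density(x, bw = bw, from = min(x), to = max(x))
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= min_height * max(y)]
  d$x[pk]
}

#' Check that an isolate comprises a single genotype
#'
#' At heterozygous positions of a single diploid genotype R concentrates in
#' one mode at 0.5 (after bias correction). A mixture of two genotypes splits
#' heterozygous sites of each component into modes near 0.25 and 0.75 (the
#' component's hets are homozygous in the other), which the mode scan detects.
#'
#' @param het_R R values at called heterozygous positions.
#' @param bias optional mapping-bias multiplier used to centre the expectation
#'   at `b/(1+b)` instead of 0.5.
#' @param tol allowed deviation of the mean from the (corrected) expectation.
#' @param mode_separation minimum distance between detected modes for them to
#'   count as distinct.
#' @return list with `verdict` ("single", "mixed" or "indeterminate"),
#'   `mean_R`, `sd_R` and detected `modes`.
#' @export
single_genotype_check <- function(het_R, bias = 1, tol = 0.05,
                                  mode_separation = 0.1) {
  het_R <- het_R[!is.na(het_R)]
  if (length(het_R) < 100) {
    return(list(verdict = "indeterminate", mean_R = NA_real_, sd_R = NA_real_,
                modes = numeric()))
  }
  expect <- bias / (1 + bias)
  m <- mean(het_R)
  modes <- density_modes(het_R)
  distinct <- length(modes) > 1 &&
    (max(modes) - min(modes)) > mode_separation
  verdict <- if (abs(m - expect) <= tol && !distinct) "single" else "mixed"
  list(verdict = verdict, mean_R = m, sd_R = stats::sd(het_R), modes = modes)
}

#' Relative copy number of a region from read depth
#'
#' Copies per haploid genome, e.g. for the 18S rDNA repeat: the median read
#' depth inside the region divided by the genome-wide median depth.
#'
#' @param region_depth per-position depths inside the region.
#' @param genome_depth per-position depths genome-wide.
#' @return the depth ratio.
#' @export
relative_copy_number <- function(region_depth, genome_depth) {
  if (length(region_depth) == 0) stop("empty region")
  if (length(genome_depth) == 0) stop("empty genome track")
  g <- stats::median(genome_depth)
  if (g == 0) stop("genome median depth is zero; copy number undefined")
  stats::median(region_depth) / g
}

#' Detect hemizygous regions from depth and heterozygosity
#'
#' A hemizygous interval (one homologous copy deleted) shows roughly half the
#' genome-median read depth and no heterozygous calls. Chromosomes are tiled
#' into windows; windows whose median depth falls within `band` times the
#' genome median and which contain no het call are merged into intervals.
#'
#' @param track a classified `r_track` (see [classify_positions()]) covering
#'   the positions of interest.
#' @param chrom_lengths data frame `chrom`, `length`.
#' @param window window size in bp.
#' @param band numeric length-2 multiplier band around half-depth.
#' @param min_windows minimum number of consecutive qualifying windows.
#' @return data frame `chrom`, `start`, `end` (1-based inclusive intervals).
#' @export
detect_hemizygous_regions <- function(track, chrom_lengths, window = 1000,
                                      band = c(0.35, 0.65), min_windows = 3) {
  med <- stats::median(track$depth)
  out <- list()
  for (i in seq_len(nrow(chrom_lengths))) {
    ch <- chrom_lengths$chrom[i]
    t <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(t) == 0) next
    n_win <- ceiling(chrom_lengths$length[i] / window)
    wi <- pmin((t$pos - 1) %/% window + 1, n_win)
    wmed <- tapply(t$depth, factor(wi, levels = seq_len(n_win)), stats::median)
    has_het <- tapply(t$class == "het", factor(wi, levels = seq_len(n_win)),
                      any)
    ok <- !is.na(wmed) & wmed >= band[1] * med & wmed <= band[2] * med &
      !is.na(has_het) & !has_het
    if (!any(ok)) next
    r <- IRanges::reduce(IRanges::IRanges(start = which(ok), width = 1))
    r <- r[IRanges::width(r) >= min_windows]
    if (length(r) == 0) next
    out[[length(out) + 1]] <- data.frame(
      chrom = ch,
      start = (IRanges::start(r) - 1) * window + 1,
      end = pmin(IRanges::end(r) * window, chrom_lengths$length[i]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
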