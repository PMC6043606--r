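#' Desert model: the negative-binomial null for SNP spacing
#'
#' Under the null, SNPs occur independently at per-bp probability `p`
#' (1/p = mean inter-SNP distance), so the distance from a position to the
#' k-th following SNP is negative-binomial with parameters `p` and `k`.
#' A desert is an interval long enough that containing fewer than `k` SNPs
#' has null probability at most `alpha`.
#'
#' @param p per-bp SNP probability (typically total SNPs / callable length).
#' @param k SNP count parameter (intervals with fewer than `k` SNPs are
#'   candidates).
#' @param alpha tail probability threshold.
#' @param merge_gap deserts overlapping or separated by at most this many bp
#'   are merged.
#' @export
desert_model <- function(p, k = 5, alpha = 1e-4, merge_gap = 100) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (k < 1) stop("k must be >= 1")
  structure(list(p = p, k = k, alpha = alpha, merge_gap = merge_gap),
            class = "desert_model")
}

#' Minimum desert length for a given SNP-count parameter
#'
#' The smallest integer L such that `P[Binomial(L, p) <= k - 1] <= alpha` --
#' equivalently, the distance to the k-th SNP exceeds L with probability at
#' most alpha. Expressed through the binomial tail (exact summation) to avoid
#' negative-binomial success/failure convention ambiguity.
#'
#' @param model a [desert_model()].
#' @param k override of the model's k (used for the chromosome-end rule).
#' @return integer length L in bp.
#' @export
desert_threshold <- function(model, k = model$k) {
  p <- model$p
  alpha <- model$alpha
  if (stats::pbinom(k - 1, k, p) <= alpha) return(as.integer(k))
  lo <- k
  hi <- k
  while (stats::pbinom(k - 1, hi, p) > alpha) hi <- hi * 2
  while (hi - lo > 1) {                     # pbinom(k-1, L, p) decreases in L
    mid <- (lo + hi) %/% 2
    if (stats::pbinom(k - 1, mid, p) <= alpha) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' SNP density of a region with a 2-sigma band
#'
#' `p = n / L` and `sigma = sqrt(p (1 - p) / L)`.
#'
#' @param n SNP count in the region.
#' @param L region length in bp.
#' @return list `p`, `sigma`, `lo` (`p - 2 sigma`), `hi` (`p + 2 sigma`).
#' @export
desert_density <- function(n, L) {
  if (L <= 0) stop("region length must be positive")
  if (n > L) stop("more SNPs than base pairs")
  p <- n / L
  sigma <- sqrt(p * (1 - p) / L)
  list(p = p, sigma = sigma, lo = p - 2 * sigma, hi = p + 2 * sigma)
}

# desert candidates on one chromosome; positions sorted ascending
desert_candidates_chrom <- function(pos, chrom_len, model) {
  k <- model$k
  n <- length(pos)
  L_k <- desert_threshold(model)
  starts <- integer()
  ends <- integer()
  # interior + 5' start: maximal intervals with k-1 SNPs strictly inside,
  # bounded by SNPs (or the 5' chromosome start as a sentinel)
  if (n >= k) {
    a <- c(0L, pos[seq_len(n - k)]) + 1L   # just after bounding SNP (pos 1 at 5')
    b <- pos[seq.int(k, n)] - 1L           # just before the (i+k)-th SNP
    keep <- (b - a + 1L) > L_k
    starts <- a[keep]
    ends <- b[keep]
  }
  # 3' end: with j < k SNPs remaining, use the negative binomial with
  # parameters p and j; j = 0 can never declare a desert
  for (j in seq_len(min(k - 1, n))) {
    a <- if (j == n) 1L else pos[n - j] + 1L
    b <- chrom_len
    if (b - a + 1L > desert_threshold(model, k = j)) {
      starts <- c(starts, a)
      ends <- c(ends, b)
    }
  }
  list(starts = starts, ends = ends)
}

#' Find SNP deserts
#'
#' Identifies all maximal intervals longer than the model threshold that
#' contain fewer than `k` SNPs, applies the chromosome-end rule (with j < k
#' SNPs remaining the threshold uses parameter j), and merges intervals that
#' overlap or are separated by at most `merge_gap` bp, iterating to a fixed
#' point. Merged regions are annotated with their SNP count and density
#' +/- 2 sigma.
#'
#' @param snps data frame `chrom`, `pos` of SNP positions (1-based).
#' @param chrom_lengths data frame `chrom`, `length`.
#' @param model a [desert_model()].
#' @return data frame `chrom`, `start`, `end` (1-based inclusive), `length`,
#'   `n_snps`, `density`, `density_lo`, `density_hi`, sorted by chromosome
#'   and start.
#' @export
find_deserts <- function(snps, chrom_lengths, model) {
  out <- list()
  for (i in seq_len(nrow(chrom_lengths))) {
    ch <- chrom_lengths$chrom[i]
    len <- chrom_lengths$length[i]
    pos <- snps$pos[snps$chrom == ch]
    if (is.unsorted(pos)) {
      warning("unsorted SNP positions on ", ch, "; sorting")
      pos <- sort(pos)
    }
    cand <- desert_candidates_chrom(pos, len, model)
    if (length(cand$starts) == 0) next
    r <- IRanges::reduce(IRanges::IRanges(start = cand$starts, end = cand$ends),
                         min.gapwidth = model$merge_gap + 1)
    n_in <- IRanges::countOverlaps(
      r, IRanges::IRanges(start = pos, width = 1))
    dens <- lapply(seq_along(r), function(j)
      desert_density(n_in[j], IRanges::width(r)[j]))
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, start = IRanges::start(r), end = IRanges::end(r),
      length = IRanges::width(r), n_snps = n_in,
      density = vapply(dens, `[[`, 0, "p"),
      density_lo = vapply(dens, `[[`, 0, "lo"),
      density_hi = vapply(dens, `[[`, 0, "hi"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), n_snps = integer(),
                      density = numeric(), density_lo = numeric(),
                      density_hi = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Cluster desert boundaries shared across isolates
#'
#' Long deserts caused by a loss-of-heterozygosity event in a common ancestor
#' share their boundaries across clonal isolates. Deserts from different
#' isolates whose left and right boundaries both agree within `tol_bp` are
#' grouped (single linkage); for each cluster the number of isolates sharing
#' the exact modal boundary is reported.
#'
#' @param desert_lists named list (per isolate) of desert data frames from
#'   [find_deserts()].
#' @param tol_bp boundary tolerance in bp (default 0 = exact).
#' @return data frame with one row per (cluster, isolate desert):
#'   `cluster`, `isolate`, `chrom`, `start`, `end`, plus per-cluster counts
#'   `n_isolates`, `n_exact_left`, `n_exact_right` (isolates sharing the
#'   modal left/right boundary exactly).
#' @export
shared_boundaries <- function(desert_lists, tol_bp = 0) {
  if (length(desert_lists) < 2) stop("need deserts from at least two isolates")
  all <- do.call(rbind, lapply(names(desert_lists), function(id) {
    d <- desert_lists[[id]]
    if (nrow(d) == 0) return(NULL)
    data.frame(isolate = id, chrom = d$chrom, start = d$start, end = d$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(cluster = integer(), isolate = character(),
                      chrom = character(), start = integer(), end = integer(),
                      n_isolates = integer(), n_exact_left = integer(),
                      n_exact_right = integer(), stringsAsFactors = FALSE))
  }
  n <- nrow(all)
  # single-linkage clustering: union-find over pairs matching within tol
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all$chrom[i] == all$chrom[j] &&
        abs(all$start[i] - all$start[j]) <= tol_bp &&
        abs(all$end[i] - all$end[j]) <= tol_bp) {
      parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  all$cluster <- as.integer(factor(root))
  stats_per <- lapply(split(seq_len(n), all$cluster), function(ix) {
    ml <- as.integer(names(which.max(table(all$start[ix]))))
    mr <- as.integer(names(which.max(table(all$end[ix]))))
    c(n_isolates = length(unique(all$isolate[ix])),
      n_exact_left = sum(all$start[ix] == ml),
      n_exact_right = sum(all$end[ix] == mr))
  })
  st <- do.call(rbind, stats_per)[all$cluster, , drop = FALSE]
  out <- cbind(all[, c("cluster", "isolate", "chrom", "start", "end")],
               as.data.frame(st))
  rownames(out) <- NULL
  out[order(out$cluster, out$isolate), , drop = FALSE]
}

#' Relative-age profile of long deserts
#'
#' Under uniform mutation rates and a SNP-free origin, older deserts carry
#' higher SNP densities. Computes per-desert densities with 2-sigma bands,
#' the density of the intervening (non-desert) sequence, the fold depletion
#' (flank density / desert density), and a chi-square homogeneity test of
#' SNP counts across deserts with expectations proportional to length.
#'
#' @param deserts desert data frame (as from [find_deserts()]).
#' @param snps data frame `chrom`, `pos` of the isolate's SNPs.
#' @param chrom_lengths data frame `chrom`, `length`.
#' @param min_length only deserts at least this long are profiled (default
#'   50 kb).
#' @return list: `deserts` (profiled subset with density bands),
#'   `flank_density`, `fold_depletion` (flank / pooled desert density),
#'   `homogeneity_p` (chi-square p across deserts; NA if < 2 deserts).
#' @export
desert_age_profile <- function(deserts, snps, chrom_lengths,
                               min_length = 50000) {
  d <- deserts[deserts$length >= min_length, , drop = FALSE]
  if (nrow(d) == 0) stop("no deserts of at least min_length")
  dens <- lapply(seq_len(nrow(d)), function(i) desert_density(d$n_snps[i], d$length[i]))
  d$density <- vapply(dens, `[[`, 0, "p")
  d$density_lo <- vapply(dens, `[[`, 0, "lo")
  d$density_hi <- vapply(dens, `[[`, 0, "hi")
  desert_len <- sum(deserts$length)
  desert_snps <- sum(deserts$n_snps)
  flank_len <- sum(chrom_lengths$length) - desert_len
  flank_snps <- nrow(snps) - desert_snps
  flank_density <- if (flank_len > 0) flank_snps / flank_len else NA_real_
  pooled <- sum(d$n_snps) / sum(d$length)
  fold <- if (pooled > 0) flank_density / pooled else Inf
  hom_p <- NA_real_
  if (nrow(d) >= 2 && sum(d$n_snps) > 0) {
    hom_p <- suppressWarnings(
      stats::chisq.test(d$n_snps, p = d$length / sum(d$length))$p.value)
  }
  list(deserts = d, flank_density = flank_density, fold_depletion = fold,
       homogeneity_p = hom_p)
}
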