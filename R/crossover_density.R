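#' Genotype-concordance track for an isolate pair
#'
#' At each informative site (heterozygous in at least one of the pair, both
#' genotypes observed) the pair is concordant when the genotype classes
#' match and discordant otherwise. Along a chromosome, crossovers between the
#' two lineages manifest as switches between long concordant and discordant
#' runs.
#'
#' @param matrix a `snp_matrix`.
#' @param a,b isolate ids.
#' @return a `concordance_track` data frame: `chrom`, `pos`, `concordant`
#'   (logical), sorted by chromosome and position.
#' @export
build_concordance <- function(matrix, a, b) {
  iso <- matrix_isolates(matrix)
  if (!all(c(a, b) %in% iso)) stop("unknown isolate id")
  ga <- matrix[[paste0("gt_", a)]]
  gb <- matrix[[paste0("gt_", b)]]
  keep <- !is.na(ga) & !is.na(gb) & (ga == 1L | gb == 1L)
  out <- data.frame(chrom = matrix$chrom[keep], pos = matrix$pos[keep],
                    concordant = ga[keep] == gb[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("concordance_track", "data.frame")
  out
}

# smooth a run-length encoding by repeatedly absorbing the weakest run below
# min_run into its neighbours (interior neighbours share a state, so the
# three runs coalesce), then count the remaining state transitions. A run's
# strength is its support: the number of sites genuinely in its state --
# absorbed opposite-state sites do not count, so a long run cannot be
# manufactured by swallowing noise.
count_transitions <- function(state, min_run) {
  r <- rle(state)
  len <- r$lengths
  val <- r$values
  sup <- r$lengths
  while (length(sup) > 1 && min(sup) < min_run) {
    i <- which.min(sup)
    if (i == 1) {
      len <- c(len[1] + len[2], len[-(1:2)])
      sup <- sup[-1]
      val <- val[-1]
    } else if (i == length(sup)) {
      n <- length(sup)
      len <- c(len[seq_len(n - 2)], len[n - 1] + len[n])
      sup <- sup[-n]
      val <- val[-n]
    } else {
      len <- c(len[seq_len(i - 2)], len[i - 1] + len[i] + len[i + 1],
               len[-seq_len(i + 1)])
      sup <- c(sup[seq_len(i - 2)], sup[i - 1] + sup[i + 1],
               sup[-seq_len(i + 1)])
      val <- c(val[seq_len(i - 1)], val[-seq_len(i + 1)])
    }
  }
  sum(val[-1] != val[-length(val)])
}

#' Estimate crossover count and density from a concordance track
#'
#' Runs of fewer than `min_run_sites` informative sites are treated as noise
#' (isolated discordances from private mutations or call errors) and
#' absorbed; transitions between the remaining long runs are counted as
#' crossovers, per chromosome. Density is the crossover count divided by the
#' assayed span (first to last informative site per chromosome, summed) in
#' kb.
#'
#' @param track a `concordance_track` from [build_concordance()].
#' @param min_run_sites minimum run length in informative sites (default 10).
#' @return list `n_crossovers`, `span_kb`, `density_per_kb`.
#' @export
estimate_crossovers <- function(track, min_run_sites = 10) {
  if (min_run_sites < 1) stop("min_run_sites must be >= 1")
  if (nrow(track) == 0) {
    warning("empty concordance track; density 0")
    return(list(n_crossovers = 0L, span_kb = 0, density_per_kb = 0))
  }
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  n_xo <- 0L
  span <- 0
  for (ix in by_chrom) {
    n_xo <- n_xo + count_transitions(track$concordant[ix], min_run_sites)
    span <- span + (max(track$pos[ix]) - min(track$pos[ix])) / 1000
  }
  list(n_crossovers = n_xo, span_kb = span,
       density_per_kb = if (span > 0) n_xo / span else 0)
}

#' Pairwise crossover densities against a reference isolate
#'
#' @param matrix a `snp_matrix`.
#' @param reference_isolate isolate all others are compared against.
#' @param min_run_sites passed to [estimate_crossovers()].
#' @return named numeric vector of densities per kb (one per non-reference
#'   isolate).
#' @export
crossover_density_vs_reference <- function(matrix, reference_isolate,
                                           min_run_sites = 10) {
  iso <- setdiff(matrix_isolates(matrix), reference_isolate)
  out <- vapply(iso, function(id) {
    estimate_crossovers(build_concordance(matrix, reference_isolate, id),
                        min_run_sites)$density_per_kb
  }, 0)
  names(out) <- iso
  out
}
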