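#' Predicted homozygous non-reference count under HWE
#'
#' With the reference being one random haplotype, a polymorphic site is
#' heterozygous with probability 2pq and homozygous non-reference with
#' probability pq, so the expected homozygous non-reference count is half the
#' heterozygous count.
#'
#' @param n_het observed heterozygous position count.
#' @return expected homozygous non-reference count (real number).
#' @export
predicted_homnonref <- function(n_het) {
  if (any(n_het < 0)) stop("n_het must be non-negative")
  n_het / 2
}

#' Upper bound on the probability that a het site is shared under HWE
#'
#' Under HWE an independent isolate is heterozygous at a site with allele
#' frequency p with probability 2p(1-p) <= 1/2, so the probability that a
#' heterozygous site is simultaneously heterozygous in n other independent
#' isolates is at most (1/2)^n; the bound is tight at p = 1/2.
#'
#' @param n_other_isolates number of other isolates.
#' @return the per-site bound (1/2)^n.
#' @export
sharing_bound <- function(n_other_isolates) {
  if (n_other_isolates < 1) stop("need at least one other isolate")
  0.5^n_other_isolates
}

#' Exact binomial test of SNP sharing at unlinked sites
#'
#' Takes sites chosen to be unlinked (one per chromosome) and the number at
#' which sharing across all other isolates was observed; returns the exact
#' upper-tail probability `P[X >= n_shared]` with
#' `X ~ Binomial(n_sites, per_site_bound)`.
#'
#' @param n_sites number of unlinked sites tested.
#' @param n_shared number of those shared by all other isolates.
#' @param per_site_bound per-site sharing probability bound, e.g.
#'   [sharing_bound()].
#' @param alpha significance level for the verdict.
#' @return list `tail_probability`, `verdict` ("clonal-signature" when the
#'   tail falls below `alpha`, else "consistent-with-HWE"), and the inputs.
#' @export
unlinked_sharing_test <- function(n_sites, n_shared, per_site_bound,
                                  alpha = 1e-6) {
  if (per_site_bound <= 0 || per_site_bound > 1)
    stop("per_site_bound must be in (0, 1]")
  if (n_shared > n_sites) stop("n_shared cannot exceed n_sites")
  tail <- stats::pbinom(n_shared - 1, n_sites, per_site_bound,
                        lower.tail = FALSE)
  list(tail_probability = tail,
       verdict = if (tail < alpha) "clonal-signature" else "consistent-with-HWE",
       n_sites = n_sites, n_shared = n_shared,
       per_site_bound = per_site_bound)
}

#' Sample one shared-candidate site per chromosome and run the sharing test
#'
#' Implements "one per chromosome to avoid linkage": among the focal
#' isolate's SNP sites, one is sampled uniformly per chromosome and scored as
#' shared when all other isolates are heterozygous there too.
#'
#' @param matrix a `snp_matrix`.
#' @param focal_isolate isolate whose SNPs are sampled.
#' @param seed integer seed for the per-chromosome draw.
#' @param alpha significance level passed to [unlinked_sharing_test()].
#' @return the [unlinked_sharing_test()] result (n_sites = number of
#'   chromosomes with at least one focal SNP).
#' @export
sample_unlinked_sharing <- function(matrix, focal_isolate, seed = 1,
                                    alpha = 1e-6) {
  iso <- matrix_isolates(matrix)
  others <- setdiff(iso, focal_isolate)
  if (length(others) < 1) stop("need at least one other isolate")
  pres <- snp_presence(matrix)
  focal_rows <- which(pres[, focal_isolate])
  if (length(focal_rows) == 0) stop("focal isolate has no SNPs")
  set.seed(seed)
  picked <- vapply(split(focal_rows, matrix$chrom[focal_rows]),
                   function(rows) rows[sample.int(length(rows), 1)], 0L)
  shared <- rowSums(pres[picked, others, drop = FALSE]) == length(others)
  unlinked_sharing_test(length(picked), sum(shared),
                        sharing_bound(length(others)), alpha = alpha)
}

# split numeric vector into low/high clusters at the largest log-scale gap
high_cluster <- function(x) {
  if (length(x) < 2) return(rep(TRUE, length(x)))
  lx <- log10(pmax(x, 1e-6))
  o <- order(lx)
  gaps <- diff(lx[o])
  cut <- which.max(gaps)
  hi <- rep(FALSE, length(x))
  hi[o[(cut + 1):length(x)]] <- TRUE
  hi
}

#' Combined clonal / sexual verdict per isolate
#'
#' Labels an isolate H-like (sexually recombining) when its homozygous
#' non-reference : heterozygous ratio is within tolerance of the HWE 1/2 and
#' its crossover density falls in the higher cluster; L-like (clonal) when
#' the homozygous non-reference deficit is at least `deficit_fold`-fold and
#' the unlinked sharing test rejects HWE; indeterminate on conflicting
#' evidence.
#'
#' @param class_counts data frame: `isolate`, `n_het`, `n_homnonref`.
#' @param sharing_tests named list (per isolate) of
#'   [unlinked_sharing_test()] results (or NULL entries when undefined).
#' @param crossover_density named numeric vector of per-isolate crossover
#'   densities per kb (against a common reference isolate); optional.
#' @param ratio_tol relative tolerance around the HWE hom-nonref/het ratio of
#'   1/2 (default 0.25).
#' @param deficit_fold minimum fold-deficit of observed vs predicted
#'   homozygous non-reference counts for a clonal label (default 10).
#' @return data frame `isolate`, `label` in {"H-like", "L-like",
#'   "indeterminate"}, with the supporting quantities.
#' @export
clonality_verdict <- function(class_counts, sharing_tests = NULL,
                              crossover_density = NULL,
                              ratio_tol = 0.25, deficit_fold = 10) {
  if (nrow(class_counts) < 2) stop("need at least two isolates")
  iso <- class_counts$isolate
  pred <- predicted_homnonref(class_counts$n_het)
  obs_ratio <- class_counts$n_homnonref / pmax(class_counts$n_het, 1)
  deficit <- pred / pmax(class_counts$n_homnonref, 1)
  hi_xo <- if (!is.null(crossover_density)) {
    h <- high_cluster(crossover_density[iso])
    names(h) <- iso
    h
  } else NULL
  label <- vapply(seq_along(iso), function(i) {
    hwe_ratio_ok <- abs(obs_ratio[i] - 0.5) <= ratio_tol * 0.5
    rejects <- !is.null(sharing_tests) && !is.null(sharing_tests[[iso[i]]]) &&
      sharing_tests[[iso[i]]]$verdict == "clonal-signature"
    h_like <- hwe_ratio_ok && (is.null(hi_xo) || hi_xo[iso[i]])
    l_like <- deficit[i] >= deficit_fold && rejects
    if (h_like && !l_like) "H-like"
    else if (l_like && !h_like) "L-like"
    else "indeterminate"
  }, "")
  data.frame(isolate = iso, label = label, n_het = class_counts$n_het,
             n_homnonref = class_counts$n_homnonref,
             predicted_homnonref = pred, deficit_fold = deficit,
             stringsAsFactors = FALSE)
}
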