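# Shared desk-scale fixtures, built in code at test time.

desk_ref <- function(n_chrom = 4, len = 2e5) ref_genome(n_chrom, len)

desk_sites <- function(ref = desk_ref(), seed = 42,
                       pop = population_model()) {
  sim_population(ref, pop, seed = seed)
}

# a small clonal family plus sexual outgroup, as named genotype list; the
# reference is anchored to the clonal founder's consensus, as in a study
# whose reference assembly comes from a member of the clone
desk_community <- function(n_clones = 3, n_sexual = 2, years = 100,
                           seed = 7, ref = desk_ref(),
                           sites = desk_sites(ref)) {
  af <- anchor_founder(sites, founder_seed = seed)
  cm <- clonal_model(years = rep(years, n_clones), founder_seed = seed)
  clones <- simulate_clonal_isolates(af$sites, ref, cm, seed = seed + 1,
                                     founder = af$founder)
  names(clones) <- paste0("L", seq_len(n_clones))
  sex <- lapply(seq_len(n_sexual), function(i)
    simulate_sexual_isolate(af$sites, seed = seed + 100 + i))
  if (n_sexual > 0) names(sex) <- paste0("H", seq_len(n_sexual))
  list(clones = clones, sexual = sex, all = c(clones, sex),
       founder = attr(clones, "founder"), ref = ref, sites = af$sites)
}

# exhaustive scan oracle for SNP deserts on one small chromosome: enumerate
# every SNP/end-bounded interval pair with < k SNPs strictly inside (subsets
# of maximal intervals are harmless -- merging collapses them), keep those
# longer than the relevant threshold (interior: parameter k; intervals
# running to the 3' end: parameter = SNPs inside, none for 0), then greedy
# merging of sorted overlapping/near intervals
brute_force_deserts <- function(pos, chrom_len, model) {
  pos <- sort(pos)
  k <- model$k
  bounds <- c(0L, pos, chrom_len + 1L)
  nb <- length(bounds)
  cand <- NULL
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      n_inside <- j - i - 1              # SNPs strictly between bounds
      if (n_inside >= k) break
      a <- bounds[i] + 1L
      b <- bounds[j] - 1L
      if (b < a) next
      thr <- if (j == nb) {
        if (n_inside == 0) next          # 3' rule: j = 0 never a desert
        desert_threshold(model, k = n_inside)
      } else desert_threshold(model)
      if (b - a + 1L > thr) cand <- rbind(cand, c(a, b))
    }
  }
  if (is.null(cand)) return(data.frame(start = integer(), end = integer()))
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  merged <- cand[1, , drop = FALSE]
  for (r in seq_len(nrow(cand))[-1]) {
    last <- nrow(merged)
    if (cand[r, 1] <= merged[last, 2] + model$merge_gap + 1L) {
      merged[last, 2] <- max(merged[last, 2], cand[r, 2])
    } else merged <- rbind(merged, cand[r, , drop = FALSE])
  }
  data.frame(start = merged[, 1], end = merged[, 2])
}

# exact upper-tail of Binomial(n, p) by full outcome enumeration (oracle)
enumerate_binomial_tail <- function(n, n_shared, p) {
  total <- 0
  for (outcome in 0:(2^n - 1)) {
    bits <- sum(bitwAnd(outcome, 2^(0:(n - 1))) > 0)
    if (bits >= n_shared) total <- total + p^bits * (1 - p)^(n - bits)
  }
  total
}
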