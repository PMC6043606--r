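#' Construct a reference genome description
#'
#' A minimal description of a haploid reference assembly: chromosome names and
#' lengths. Defaults give a small desk-scale genome (4 chromosomes x 1 Mb)
#' whose analyses run in seconds; real diatom genomes are ~32 Mb over 24
#' chromosomes and are handled identically.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp (recycled).
#' @param names chromosome names; default `chr1..chrN`.
#' @return a `ref_genome` data frame with columns `chrom`, `length`.
#' @export
ref_genome <- function(n_chrom = 4, chrom_length = 1e6, names = NULL) {
  if (n_chrom < 1) stop("need at least one chromosome")
  len <- rep_len(as.numeric(chrom_length), n_chrom)
  if (any(len <= 0)) stop("chromosome lengths must be positive")
  nm <- if (is.null(names)) paste0("chr", seq_len(n_chrom)) else names
  if (anyDuplicated(nm)) stop("chromosome names must be unique")
  structure(data.frame(chrom = nm, length = len, stringsAsFactors = FALSE),
            class = c("ref_genome", "data.frame"))
}

genome_length <- function(ref) sum(ref$length)

#' Population model for polymorphic sites
#'
#' Describes the standing variation of the sexual source population: the
#' expected density of biallelic polymorphic sites and the allele-frequency
#' spectrum from which per-site minor allele frequencies are drawn.
#'
#' @param snp_density expected polymorphic sites per bp. The default matches
#'   ~180,000 heterozygous sites over a 32 Mb genome.
#' @param sfs_mode `"uniform"` draws the minor allele frequency uniformly on
#'   (0, 0.5]; `"neutral"` draws with density proportional to 1/q on
#'   `[1/(2 * sfs_n), 0.5]`.
#' @param sfs_n effective population size controlling the lower frequency
#'   cutoff of the neutral spectrum.
#' @return a `population_model` list.
#' @export
population_model <- function(snp_density = 180000 / 32e6,
                             sfs_mode = c("uniform", "neutral"),
                             sfs_n = 1000) {
  sfs_mode <- match.arg(sfs_mode)
  if (snp_density <= 0 || snp_density >= 1) stop("snp_density must be in (0, 1)")
  structure(list(snp_density = snp_density, sfs_mode = sfs_mode, sfs_n = sfs_n),
            class = "population_model")
}

draw_minor_freq <- function(n, pop) {
  if (pop$sfs_mode == "uniform") {
    runif(n, 0, 0.5)
  } else {
    # density 1/q on [q0, 0.5]: inverse-CDF sampling
    q0 <- 1 / (2 * pop$sfs_n)
    q0 * (0.5 / q0)^runif(n)
  }
}

BASES <- c("A", "C", "G", "T")

#' Simulate the polymorphic sites of a population
#'
#' Places polymorphic sites along the reference, draws a minor allele
#' frequency per site and picks the reference base as one random haplotype
#' from the population (the reference therefore carries the major allele with
#' probability equal to its frequency). `alt_freq` is the population frequency
#' of the non-reference allele.
#'
#' @param ref a [ref_genome()].
#' @param pop a [population_model()].
#' @param seed integer seed.
#' @return a `population_sites` data frame: `chrom`, `pos` (1-based, sorted),
#'   `ref_base`, `alt_base`, `alt_freq`.
#' @export
sim_population <- function(ref, pop, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(ref)), function(i) {
    L <- ref$length[i]
    n <- rbinom(1, L, pop$snp_density)
    if (n == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        ref_base = character(), alt_base = character(),
                        alt_freq = numeric(), stringsAsFactors = FALSE))
    }
    pos <- sort(sample.int(L, n))
    f <- draw_minor_freq(n, pop)             # minor allele frequency q
    ref_is_major <- runif(n) < (1 - f)       # reference = random haplotype
    alt_freq <- ifelse(ref_is_major, f, 1 - f)
    ri <- sample.int(4, n, replace = TRUE)
    ab <- BASES[(ri + sample.int(3, n, replace = TRUE) - 1) %% 4 + 1]
    data.frame(chrom = ref$chrom[i], pos = pos, ref_base = BASES[ri],
               alt_base = ab, alt_freq = alt_freq, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  if (nrow(sites) < 1) {
    warning("expected site count below 1; empty site table generated")
  }
  structure(sites, class = c("population_sites", "data.frame"))
}

#' Simulate one sexual (Hardy-Weinberg) isolate
#'
#' Draws an independent diploid genotype at every polymorphic site with
#' class probabilities `(1-a)^2 : 2a(1-a) : a^2` where `a` is the
#' non-reference allele frequency. With the reference chosen as a random
#' haplotype, the expected per-site probabilities of heterozygous and
#' homozygous non-reference classes are `2pq` and `pq`, giving the 2:1 law
#' regardless of the allele-frequency spectrum.
#'
#' @param sites a `population_sites` table from [sim_population()].
#' @param seed integer seed.
#' @return a genotype data frame: `chrom`, `pos`, `ref_base`, `alt_base`,
#'   `gt` (0 = hom-ref, 1 = het, 2 = hom-nonref).
#' @export
simulate_sexual_isolate <- function(sites, seed = 1) {
  set.seed(seed)
  a <- sites$alt_freq
  u <- runif(length(a))
  gt <- ifelse(u < a^2, 2L, ifelse(u < a^2 + 2 * a * (1 - a), 1L, 0L))
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref_base = sites$ref_base, alt_base = sites$alt_base,
                    gt = gt, stringsAsFactors = FALSE)
  class(out) <- c("genotype_matrix", "data.frame")
  out
}

#' Clonal lineage model
#'
#' One inbred founder (a sexual draw with loss-of-heterozygosity blocks forced
#' homozygous reference) gives rise to descendants purely by mitosis; each
#' descendant accumulates private heterozygous point mutations at rate `mu`
#' per bp per division over its years since divergence.
#'
#' @param years numeric vector, one entry per descendant isolate.
#' @param mu mutation rate per bp per division.
#' @param division_interval_days days between mitotic divisions.
#' @param loh_blocks data frame `chrom`, `start`, `end` (1-based inclusive) of
#'   regions made homozygous-reference in the founder; must not overlap.
#' @param founder_seed seed for the founder's sexual draw.
#' @export
clonal_model <- function(years, mu = 1e-9, division_interval_days = 2,
                         loh_blocks = NULL, founder_seed = 1) {
  if (mu < 0) stop("mu must be non-negative")
  if (!is.null(loh_blocks) && nrow(loh_blocks)) {
    for (ch in unique(loh_blocks$chrom)) {
      b <- loh_blocks[loh_blocks$chrom == ch, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
        stop("loh_blocks overlap within chromosome ", ch)
    }
  }
  structure(list(years = years, mu = mu,
                 division_interval_days = division_interval_days,
                 loh_blocks = loh_blocks, founder_seed = founder_seed),
            class = "clonal_model")
}

in_blocks <- function(chrom, pos, blocks) {
  if (is.null(blocks) || nrow(blocks) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(blocks))) {
    hit <- hit | (chrom == blocks$chrom[i] &
                    pos >= blocks$start[i] & pos <= blocks$end[i])
  }
  hit
}

#' Anchor the reference sequence to a founder's majority-rules consensus
#'
#' A haploid majority-rules reference assembled from one diploid individual
#' carries that individual's allele at every homozygous site and one of its
#' two alleles (a coin flip) at heterozygous sites. Consequently the
#' reference donor -- and any clone descended from it -- can be heterozygous
#' but essentially never homozygous non-reference, which is the clonal
#' lineage's signature when the reference isolate belongs to it. This
#' function draws the founder's genotype under HWE and re-labels each site's
#' reference/alternate alleles to the founder consensus. Marginally the
#' reference base remains a single random haplotype from the population, so
#' sexual isolates drawn against the anchored sites keep the 2:1
#' heterozygous : homozygous non-reference law.
#'
#' @param sites a `population_sites` table.
#' @param founder_seed seed for the founder draw.
#' @return list with `sites` (re-anchored table, same positions) and
#'   `founder` (the founder's genotype data frame; `gt` is 0 or 1 only).
#' @export
anchor_founder <- function(sites, founder_seed = 1) {
  set.seed(founder_seed)
  a <- sites$alt_freq
  u <- runif(length(a))
  gt <- ifelse(u < a^2, 2L, ifelse(u < a^2 + 2 * a * (1 - a), 1L, 0L))
  flip_het <- runif(length(a)) < 0.5
  swap <- gt == 2L | (gt == 1L & flip_het)   # consensus takes the alt allele
  new_sites <- sites
  new_sites$ref_base[swap] <- sites$alt_base[swap]
  new_sites$alt_base[swap] <- sites$ref_base[swap]
  new_sites$alt_freq[swap] <- 1 - a[swap]
  founder <- data.frame(chrom = new_sites$chrom, pos = new_sites$pos,
                        ref_base = new_sites$ref_base,
                        alt_base = new_sites$alt_base,
                        gt = ifelse(gt == 1L, 1L, 0L),
                        stringsAsFactors = FALSE)
  class(founder) <- c("genotype_matrix", "data.frame")
  class(new_sites) <- class(sites)
  list(sites = new_sites, founder = founder)
}

#' Simulate a clonal family of isolates
#'
#' @param sites population sites ([sim_population()]).
#' @param ref the [ref_genome()] the sites were placed on (supplies the
#'   mutational target size).
#' @param clonal a [clonal_model()].
#' @param seed seed for the descendants' private mutations.
#' @param ploidy copies of the genome mutations can hit (private SNPs arise as
#'   heterozygous hits on a diploid target).
#' @param founder optional founder genotype, typically from
#'   [anchor_founder()] so that the reference is the founder's own consensus
#'   (no homozygous non-reference sites). When NULL, the founder is drawn
#'   internally with `clonal$founder_seed` and the re-anchored site table is
#'   attached as `attr(, "sites")` -- isolates simulated against the original
#'   sites are not comparable to these clones.
#' @return list of genotype data frames, one per descendant; the founder is
#'   attached as `attr(, "founder")` and each element carries its private
#'   mutation positions as `attr(, "private")`.
#' @export
simulate_clonal_isolates <- function(sites, ref, clonal, seed = 1, ploidy = 2,
                                     founder = NULL) {
  anchored_sites <- NULL
  if (is.null(founder)) {
    af <- anchor_founder(sites, clonal$founder_seed)
    founder <- af$founder
    anchored_sites <- af$sites
  }
  founder$gt[in_blocks(founder$chrom, founder$pos, clonal$loh_blocks)] <- 0L
  set.seed(seed)
  G <- genome_length(ref)
  divs_per_year <- 365.25 / clonal$division_interval_days
  cum <- c(0, cumsum(ref$length))
  out <- lapply(clonal$years, function(yr) {
    lambda <- ploidy * G * clonal$mu * divs_per_year * yr
    n_mut <- rpois(1, lambda)
    iso <- founder
    if (n_mut > 0) {
      taken <- paste(founder$chrom, founder$pos)
      muts <- data.frame(chrom = character(), pos = integer())
      while (nrow(muts) < n_mut) {
        g <- sample(G, n_mut - nrow(muts), replace = TRUE)
        ci <- findInterval(g - 1, cum, rightmost.closed = FALSE)
        cand <- data.frame(chrom = ref$chrom[ci], pos = as.integer(g - cum[ci]),
                           stringsAsFactors = FALSE)
        key <- paste(cand$chrom, cand$pos)
        keep <- !(key %in% taken) & !duplicated(key)
        cand <- cand[keep, , drop = FALSE]
        taken <- c(taken, key[keep])
        muts <- rbind(muts, cand)
      }
      ri <- sample.int(4, n_mut, replace = TRUE)
      ab <- BASES[(ri + sample.int(3, n_mut, replace = TRUE) - 1) %% 4 + 1]
      new_rows <- data.frame(chrom = muts$chrom, pos = muts$pos,
                             ref_base = BASES[ri], alt_base = ab, gt = 1L,
                             stringsAsFactors = FALSE)
      iso <- rbind(iso, new_rows)
      iso <- iso[order(iso$chrom, iso$pos), , drop = FALSE]
      rownames(iso) <- NULL
      attr(iso, "private") <- muts
    } else {
      attr(iso, "private") <- data.frame(chrom = character(), pos = integer())
    }
    class(iso) <- c("genotype_matrix", "data.frame")
    iso
  })
  attr(out, "founder") <- founder
  if (!is.null(anchored_sites)) attr(out, "sites") <- anchored_sites
  out
}

#' Sequencing model for pileup simulation
#'
#' @param mean_coverage mean per-position read depth (Poisson).
#' @param error_rate probability a read's base is replaced by a uniformly
#'   random other base.
#' @param mapping_bias multiplier (<= 1) down-weighting the probability that a
#'   read sampled at a heterozygous site comes from the non-reference
#'   haplotype; 1 means unbiased.
#' @export
sequencing_model <- function(mean_coverage = 60, error_rate = 0.01,
                             mapping_bias = 1) {
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (mapping_bias <= 0 || mapping_bias > 1) stop("mapping_bias must be in (0, 1]")
  structure(list(mean_coverage = mean_coverage, error_rate = error_rate,
                 mapping_bias = mapping_bias), class = "sequencing_model")
}

# distribute per-position error reads uniformly over the other three bases;
# vectorised: split the error count into three binomial shares, then map the
# relative slots onto the absolute base columns
scatter_errors <- function(counts, base_idx, err_rate, mat) {
  n <- length(counts)
  n_err <- rbinom(n, counts, err_rate)
  kept <- counts - n_err
  idx <- cbind(seq_len(n), base_idx)
  mat[idx] <- mat[idx] + kept
  e1 <- rbinom(n, n_err, 1 / 3)
  e2 <- rbinom(n, n_err - e1, 1 / 2)
  e3 <- n_err - e1 - e2
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  for (slot in 1:3) {
    dest <- others[cbind(base_idx, slot)]
    add <- list(e1, e2, e3)[[slot]]
    di <- cbind(seq_len(n), dest)
    mat[di] <- mat[di] + add
  }
  mat
}

#' Simulate a per-position read-count pileup
#'
#' Per position, depth is Poisson(`mean_coverage`); each read is drawn from
#' one of the two haplotypes (at heterozygous sites the non-reference
#' haplotype is down-weighted by `mapping_bias` before renormalisation, so a
#' read is non-reference with probability `bias / (1 + bias)`); sequencing
#' error then flips each read's base to a uniformly random other base with
#' probability `error_rate`.
#'
#' @param genotype a genotype data frame (`chrom`, `pos`, `ref_base`,
#'   `alt_base`, `gt`).
#' @param seqmodel a [sequencing_model()].
#' @param seed integer seed.
#' @return a `pileup_counts` data frame: `chrom`, `pos`, `ref_base`, and read
#'   counts `A`, `C`, `G`, `T`.
#' @export
simulate_pileup <- function(genotype, seqmodel, seed = 1) {
  set.seed(seed)
  n <- nrow(genotype)
  depth <- rpois(n, seqmodel$mean_coverage)
  b <- seqmodel$mapping_bias
  p_alt <- c(0, b / (1 + b), 1)[genotype$gt + 1L]
  alt_reads <- rbinom(n, depth, p_alt)
  ref_reads <- depth - alt_reads
  mat <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  ref_idx <- match(genotype$ref_base, BASES)
  alt_idx <- match(genotype$alt_base, BASES)
  mat <- scatter_errors(ref_reads, ref_idx, seqmodel$error_rate, mat)
  mat <- scatter_errors(alt_reads, alt_idx, seqmodel$error_rate, mat)
  out <- data.frame(chrom = genotype$chrom, pos = genotype$pos,
                    ref_base = genotype$ref_base, mat,
                    stringsAsFactors = FALSE)
  class(out) <- c("pileup_counts", "data.frame")
  out
}

#' Simulate a meiotic recombinant relative of an isolate
#'
#' Derives a second isolate related to `genotype` through meiosis with
#' planted crossover breakpoints: along each chromosome the pair alternates
#' between segments where the recombinant shares both haplotypes with the
#' source (genotypes identical) and segments where it shares neither (an
#' independent Hardy-Weinberg draw from the population). Breakpoint
#' positions are the planted truth for crossover-estimator calibration.
#'
#' @param genotype the source isolate's genotype data frame.
#' @param sites the `population_sites` the genotype was drawn on.
#' @param n_breakpoints total number of breakpoints, spread over chromosomes
#'   proportionally to their site counts.
#' @param seed integer seed.
#' @param min_gap_sites minimum number of polymorphic sites between
#'   consecutive breakpoints (and from chromosome ends), so every planted
#'   segment carries enough informative sites to be detectable.
#' @return a genotype data frame with the planted breakpoint positions as
#'   `attr(, "breakpoints")` (data frame `chrom`, `pos`).
#' @export
simulate_recombinant <- function(genotype, sites, n_breakpoints, seed = 1,
                                 min_gap_sites = 30) {
  other <- simulate_sexual_isolate(sites, seed = seed + 10^6)
  set.seed(seed)
  chroms <- unique(sites$chrom)
  n_per <- as.vector(stats::rmultinom(1, n_breakpoints,
                                      table(factor(sites$chrom, chroms))))
  out <- genotype
  bps <- list()
  for (i in seq_along(chroms)) {
    if (n_per[i] == 0) next
    ix <- which(sites$chrom == chroms[i])
    n_sites <- length(ix)
    n_bp <- n_per[i]
    slack <- n_sites - (n_bp + 1) * min_gap_sites
    if (slack < n_bp)
      stop("too few sites on ", chroms[i], " for the requested breakpoints")
    # breakpoints at site indices spaced >= min_gap_sites apart, drawn
    # constructively (sorted sample plus fixed gap offsets)
    bi <- sort(sample.int(slack, n_bp)) +
      min_gap_sites * seq_len(n_bp)
    bp <- sites$pos[ix][bi]
    # alternate segments: IBD2 (identical), IBD0 (independent draw)
    seg <- findInterval(sites$pos[ix], bp)
    swap <- ix[seg %% 2 == 1]
    out$gt[swap] <- other$gt[swap]
    bps[[length(bps) + 1]] <- data.frame(chrom = chroms[i], pos = bp,
                                         stringsAsFactors = FALSE)
  }
  attr(out, "breakpoints") <- if (length(bps)) do.call(rbind, bps) else
    data.frame(chrom = character(), pos = integer())
  class(out) <- c("genotype_matrix", "data.frame")
  out
}
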