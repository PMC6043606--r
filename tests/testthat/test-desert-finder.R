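test_that("the desert length threshold matches the exact binomial tail", {
  # p = 1: every bp is a SNP; five bp always hold five SNPs
  expect_equal(desert_threshold(desert_model(1 - 1e-12, k = 5)), 5)
  # alpha = 1: the smallest window that can hold k SNPs
  expect_equal(desert_threshold(desert_model(0.01, k = 5, alpha = 1)), 5)
  # genome-scale density: brute-force CDF summation oracle
  dm <- desert_model(p = 180000 / 32e6, k = 5)
  L <- desert_threshold(dm)
  cdf <- function(L) sum(vapply(0:4, function(i)
    choose(L, i) * dm$p^i * (1 - dm$p)^(L - i), 0))
  expect_lte(cdf(L), 1e-4)
  expect_gt(cdf(L - 1), 1e-4)
  # Poisson cross-check: lambda = p L puts the tail in the same regime
  expect_equal(stats::ppois(4, dm$p * L), cdf(L), tolerance = 0.05)
})

test_that("density bands follow p +/- 2 sqrt(p(1-p)/L)", {
  d <- desert_density(75, 320000)
  expect_equal(d$p, 75 / 320000)
  expect_equal(d$sigma, sqrt(d$p * (1 - d$p) / 320000))
  expect_equal(d$sigma, 2.71e-5, tolerance = 0.01)
  expect_equal(desert_density(0, 100), list(p = 0, sigma = 0, lo = 0, hi = 0))
  d1 <- desert_density(100, 100)
  expect_equal(d1$p, 1)
  expect_equal(d1$sigma, 0)
  expect_error(desert_density(10, 5), "more SNPs")
})

test_that("a single large gap in a dense SNP track yields exactly one desert", {
  # SNP every 100 bp on 10 kb except a 5 kb hole; threshold ~2 kb
  pos <- setdiff(seq(100, 10000, by = 100), seq(3100, 8000, by = 100))
  dm <- desert_model(p = 0.01, k = 5, alpha = 1e-4)
  expect_lt(desert_threshold(dm), 2500)
  d <- find_deserts(data.frame(chrom = "c", pos = pos),
                    data.frame(chrom = "c", length = 10000), dm)
  expect_equal(nrow(d), 1)
  expect_lte(d$start, 3100)
  expect_gte(d$end, 8000)
  expect_lt(d$n_snps, 10)
})

test_that("sub-threshold gaps merge across small separations", {
  # two gaps, each below threshold, separated by 50 bp -> one merged desert
  dm <- desert_model(p = 0.02, k = 2, alpha = 1e-4)
  L <- desert_threshold(dm)
  gap <- ceiling(0.8 * L)
  s1 <- 1000
  pos <- c(seq(100, s1, by = 50),
           s1 + gap + 25,                       # lone SNP between two gaps
           seq(s1 + 2 * gap + 50, s1 + 2 * gap + 1000, by = 50))
  d <- find_deserts(data.frame(chrom = "c", pos = pos),
                    data.frame(chrom = "c", length = s1 + 2 * gap + 1200), dm)
  expect_equal(nrow(d), 1)
  expect_gte(d$length, 2 * gap)
})

test_that("SNP-free chromosomes shorter than the threshold carry no desert", {
  dm <- desert_model(p = 0.001, k = 5)
  d <- find_deserts(data.frame(chrom = character(), pos = integer()),
                    data.frame(chrom = "c", length = 2000), dm)
  expect_equal(nrow(d), 0)
})

test_that("find_deserts equals the exhaustive scan on small chromosomes", {
  dm <- desert_model(p = 0.005, k = 5, alpha = 1e-3)
  for (seed in 1:12) {
    set.seed(seed)
    len <- sample(20000:50000, 1)
    n <- rbinom(1, len, dm$p)
    pos <- sort(sample.int(len, n))
    got <- find_deserts(data.frame(chrom = "c", pos = pos),
                        data.frame(chrom = "c", length = len), dm)
    want <- brute_force_deserts(pos, len, dm)
    expect_equal(got$start, want$start, info = paste("seed", seed))
    expect_equal(got$end, want$end, info = paste("seed", seed))
  }
})

test_that("deserts never overlap and are invariant to input order", {
  dm <- desert_model(p = 0.002, k = 5)
  set.seed(77)
  pos <- sort(sample.int(2e5, 300))
  chrom <- data.frame(chrom = "c", length = 2e5)
  d <- find_deserts(data.frame(chrom = "c", pos = pos), chrom, dm)
  if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  shuffled <- sample(pos)
  expect_warning(d2 <- find_deserts(data.frame(chrom = "c", pos = shuffled),
                                    chrom, dm), "unsorted")
  expect_equal(d2, d)
})

test_that("false-desert discovery shrinks as alpha decreases", {
  set.seed(5)
  chrom <- data.frame(chrom = "c", length = 5e5)
  pos <- sort(sample.int(5e5, rbinom(1, 5e5, 0.002)))
  counts <- vapply(c(1e-2, 1e-4, 1e-8), function(a)
    nrow(find_deserts(data.frame(chrom = "c", pos = pos), chrom,
                      desert_model(p = 0.002, k = 5, alpha = a))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("shared LoH blocks give matching desert boundaries across clones", {
  ref <- desk_ref(2, 2e5)
  sites <- desk_sites(ref)
  blocks <- data.frame(chrom = c("chr1", "chr2"),
                       start = c(50001, 100001), end = c(120000, 160000))
  cm <- clonal_model(years = rep(20, 3), loh_blocks = blocks, founder_seed = 3)
  clones <- simulate_clonal_isolates(sites, ref, cm, seed = 4)
  names(clones) <- paste0("L", 1:3)
  deserts <- lapply(clones, function(g) {
    snps <- data.frame(chrom = g$chrom[g$gt == 1], pos = g$pos[g$gt == 1])
    find_deserts(snps, ref, desert_model(p = nrow(snps) / sum(ref$length)))
  })
  cl <- shared_boundaries(deserts, tol_bp = 2000)
  big <- cl[cl$end - cl$start > 50000, ]
  expect_true(all(big$n_isolates == 3))
  # each planted block recovered as one cluster covering it
  for (b in seq_len(nrow(blocks))) {
    hit <- big$chrom == blocks$chrom[b] & big$start <= blocks$start[b] + 2000 &
      big$end >= blocks$end[b] - 2000
    expect_true(any(hit))
  }
  # identical lists cluster completely; tol 0 with offset boundaries does not
  one <- deserts[[1]]
  cl2 <- shared_boundaries(list(a = one, b = one), tol_bp = 0)
  expect_true(all(cl2$n_isolates == 2))
  off <- one; off$start <- off$start + 1
  cl3 <- shared_boundaries(list(a = one, b = off), tol_bp = 0)
  expect_true(all(cl3$n_isolates == 1))
})

test_that("age profile: homogeneous deserts pass, depletion matches arithmetic", {
  # deserts all drawn from one Poisson rate: homogeneity not rejected
  set.seed(8)
  lens <- rep(80000, 6)
  rate <- 1e-4
  d <- data.frame(chrom = "c", start = seq(1, by = 2e5, length.out = 6),
                  end = seq(1, by = 2e5, length.out = 6) + lens - 1,
                  length = lens, n_snps = rpois(6, rate * lens))
  chrom <- data.frame(chrom = "c", length = 1.4e6)
  genome_snps <- data.frame(chrom = "c",
                            pos = sort(sample.int(1.4e6, 3000)))
  prof <- desert_age_profile(d, genome_snps, chrom, min_length = 50000)
  expect_gt(prof$homogeneity_p, 0.01)
  # fold depletion from printed-scale numbers: genome 180000/32 Mb,
  # desert 75 SNPs in 320 kb -> 24-fold
  d2 <- data.frame(chrom = "c", start = 1, end = 320000, length = 320000,
                   n_snps = 75)
  chrom2 <- data.frame(chrom = "c", length = 32e6)
  snps2 <- data.frame(chrom = "c", pos = seq_len(180000 + 75))
  prof2 <- desert_age_profile(d2, snps2, chrom2)
  flank_density <- 180000 / (32e6 - 320000)
  expect_equal(prof2$fold_depletion, flank_density / (75 / 320000),
               tolerance = 1e-6)
  expect_gt(prof2$fold_depletion, 20)
  # equal densities: fold depletion 1
  d3 <- data.frame(chrom = "c", start = 1, end = 100000, length = 100000,
                   n_snps = 1000)
  snps3 <- data.frame(chrom = "c", pos = seq_len(2000))
  chrom3 <- data.frame(chrom = "c", length = 200000)
  expect_equal(desert_age_profile(d3, snps3, chrom3)$fold_depletion, 1)
})
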