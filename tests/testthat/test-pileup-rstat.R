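pileup_row <- function(counts, ref = "A") {
  data.frame(chrom = "chr1", pos = seq_len(nrow(counts)), ref_base = ref,
             A = counts[, 1], C = counts[, 2], G = counts[, 3],
             T = counts[, 4], stringsAsFactors = FALSE)
}

test_that("R equals nc / (nc + rc) with the most common non-reference base", {
  pu <- pileup_row(rbind(c(5, 5, 0, 0),    # rc 5, nc 5 -> 0.5
                         c(10, 0, 0, 0),   # nc 0 -> 0
                         c(3, 7, 0, 0),    # 0.7
                         c(0, 0, 0, 0),    # depth 0 -> NA
                         c(4, 6, 2, 0)))   # second non-ref 2 > 0.2*6 -> flag
  r <- compute_R(pu)
  expect_equal(r$R[1:3], c(0.5, 0, 0.7))
  expect_true(is.na(r$R[4]))
  expect_true(r$ambiguous[5])
  expect_false(any(r$ambiguous[1:3]))
  bad <- pileup_row(rbind(c(-1, 2, 0, 0)))
  expect_error(compute_R(bad), "negative")
})

test_that("classification recovers simulated truth and excludes extreme coverage", {
  ref <- desk_ref(2, 1e5)
  sites <- desk_sites(ref)
  g <- simulate_sexual_isolate(sites, seed = 3)
  pu <- simulate_pileup(g, sequencing_model(60, 0.01, 1), seed = 4)
  tr <- classify_positions(compute_R(pu))
  usable <- tr$class %in% c("hom-ref", "het", "hom-nonref")
  called <- as.integer(tr$class[usable]) - 1L
  expect_gt(mean(called == g$gt[usable]), 0.99)
  # depth below cov_lo is excluded
  one <- pileup_row(rbind(c(2, 1, 0, 0)))
  t1 <- classify_positions(compute_R(one), cov_lo = 5, cov_hi = 100)
  expect_equal(as.character(t1$class), "excluded")
  # all R = 0 -> all hom-ref
  z <- classify_positions(compute_R(pileup_row(matrix(c(10, 0, 0, 0), 20, 4, byrow = TRUE))),
                          cov_lo = 1, cov_hi = 100)
  expect_true(all(z$class == "hom-ref"))
})

test_that("classification is monotone in R", {
  ord <- c("hom-ref" = 1, "het" = 2, "hom-nonref" = 3)
  depths <- rbind(c(10, 0), c(9, 1), c(8, 2), c(7, 3), c(5, 5),
                  c(3, 7), c(2, 8), c(1, 9), c(0, 10))
  pu <- pileup_row(cbind(depths[, 1], depths[, 2], 0, 0))
  tr <- classify_positions(compute_R(pu), cov_lo = 1, cov_hi = 100)
  ranks <- ord[as.character(tr$class)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("the 2:1 HWE ratio test separates sexual from clonal count patterns", {
  sexual <- hwe_ratio_test(180000, 90000)
  expect_equal(sexual$ratio, 2)
  expect_gt(sexual$p_value, 0.05)
  clonal <- hwe_ratio_test(40000, 2000)
  expect_equal(clonal$ratio, 20)
  expect_lt(clonal$p_value, 1e-10)
  tiny <- hwe_ratio_test(2, 1)
  expect_equal(tiny$ratio, 2)
  expect_equal(tiny$p_value, 1)
  expect_equal(hwe_ratio_test(10, 0)$ratio, Inf)
  expect_error(hwe_ratio_test(0, 0), "at least one")
})

test_that("single-genotype check flags 50:50 mixtures and honours bias correction", {
  set.seed(9)
  # single clone: het R ~ Binomial(60, 1/2)/60
  single <- rbinom(5000, 60, 0.5) / 60
  expect_equal(single_genotype_check(single)$verdict, "single")
  # 50:50 mixture of two genotypes: sites het in one, hom in the other,
  # pile up at allele fractions 1/4 and 3/4 (mixture arithmetic)
  mixed <- c(rbinom(2500, 60, 0.25), rbinom(2500, 60, 0.75)) / 60
  expect_equal(single_genotype_check(mixed)$verdict, "mixed")
  # mapping bias 0.8 shifts the het mode to 0.8/1.8; with the bias supplied
  # the isolate still reads as single
  biased <- rbinom(5000, 60, 0.8 / 1.8) / 60
  expect_equal(single_genotype_check(biased, bias = 0.8)$verdict, "single")
  expect_equal(single_genotype_check(biased)$verdict, "mixed")
  expect_equal(single_genotype_check(rbinom(10, 60, .5) / 60)$verdict,
               "indeterminate")
})

test_that("mapping bias is estimated from the het mode and corrected", {
  set.seed(10)
  nc <- rbinom(5000, 60, 0.8 / 1.8)
  tr <- data.frame(chrom = "chr1", pos = seq_len(5000), rc = 60 - nc, nc = nc,
                   depth = 60, R = nc / 60, ambiguous = FALSE)
  b <- estimate_mapping_bias(tr$R)
  expect_equal(b, 0.8, tolerance = 0.1)
  corrected <- correct_bias(tr, b)
  expect_equal(mean(corrected$R), 0.5, tolerance = 0.02)
})

test_that("relative copy number reflects depth ratios", {
  set.seed(11)
  genome <- rpois(20000, 60)
  region <- rpois(300, 8 * 60)
  expect_equal(relative_copy_number(region, genome), 8, tolerance = 0.15)
  expect_equal(relative_copy_number(genome, genome), 1)
  expect_error(relative_copy_number(numeric(), genome), "empty")
  expect_error(relative_copy_number(region, rep(0, 100)), "zero")
})

test_that("hemizygous regions are detected from half-depth het-free intervals", {
  ref <- data.frame(chrom = "chr1", length = 2e5)
  set.seed(12)
  pos <- seq(1, 2e5, by = 50)
  depth <- rpois(length(pos), 60)
  gt <- rbinom(length(pos), 1, 0.3)           # scattered het calls
  del <- pos >= 50001 & pos <= 100000          # one haplotype deleted: 50 kb
  depth[del] <- rpois(sum(del), 30)
  gt[del] <- 0
  tr <- data.frame(chrom = "chr1", pos = pos, depth = depth,
                   R = ifelse(gt == 1, 0.5, 0),
                   class = factor(ifelse(gt == 1, "het", "hom-ref"),
                                  levels = c("hom-ref", "het", "hom-nonref",
                                             "ambiguous", "excluded")))
  hemi <- detect_hemizygous_regions(tr, ref, window = 2000)
  expect_equal(nrow(hemi), 1)
  expect_lt(abs(hemi$start - 50001), 2 * 2000 + 1)
  expect_lt(abs(hemi$end - 100000), 2 * 2000 + 1)
  # uniform diploid coverage: nothing
  tr2 <- tr; tr2$depth <- rpois(length(pos), 60)
  expect_equal(nrow(detect_hemizygous_regions(tr2, ref, window = 2000)), 0)
  # a wholly hemizygous chromosome alongside diploid ones: one interval
  # spanning that chromosome (the genome median supplies the baseline)
  ref2 <- data.frame(chrom = c("chr1", "chr2"), length = c(2e5, 5e4))
  pos2 <- seq(1, 5e4, by = 50)
  tr2ch <- data.frame(chrom = "chr2", pos = pos2,
                      depth = rpois(length(pos2), 30), R = 0,
                      class = factor("hom-ref", levels = levels(tr$class)))
  hemi3 <- detect_hemizygous_regions(rbind(tr2, tr2ch), ref2, window = 2000)
  on_chr2 <- hemi3[hemi3$chrom == "chr2", ]
  expect_equal(nrow(on_chr2), 1)
  expect_equal(on_chr2$start, 1)
  expect_equal(on_chr2$end, 5e4)
})
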