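mk_pileup <- function(pos, A = 0, C = 0, G = 0, T = 0) {
  data.frame(chrom = "chr1", pos = pos, ref_base = "A",
             A = A, C = C, G = G, T = T, stringsAsFactors = FALSE)
}

test_that("refinement rescues supported positions and records the rest", {
  calls <- list(
    iso1 = data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      gt = 1L, stringsAsFactors = FALSE),
    iso2 = data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gt = integer(),
                      stringsAsFactors = FALSE))
  pileups <- list(
    iso1 = mk_pileup(100L, A = 15, G = 14),
    iso2 = mk_pileup(100L, A = 16, G = 14))   # 30 reads, 14 alt -> rescue
  m <- refine_snps(calls, pileups, min_depth = 10, min_alt_frac = 0.2)
  expect_equal(m$gt_iso2, 1L)
  expect_equal(m$src_iso2, "rescued")
  expect_equal(m$src_iso1, "raw")

  # zero alt reads: hom-ref, not rescued
  pileups$iso2 <- mk_pileup(100L, A = 30)
  m2 <- refine_snps(calls, pileups)
  expect_equal(m2$gt_iso2, 0L)
  expect_equal(m2$src_iso2, "homref")

  # under-covered: missing
  pileups$iso2 <- mk_pileup(100L, A = 4, G = 3)
  m3 <- refine_snps(calls, pileups)
  expect_true(is.na(m3$gt_iso2))

  # different alt alleles never merge
  calls$iso2 <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                           gt = 1L, stringsAsFactors = FALSE)
  pileups$iso1 <- mk_pileup(100L, A = 15, G = 14, T = 1)
  pileups$iso2 <- mk_pileup(100L, A = 15, T = 14)
  m4 <- refine_snps(calls, pileups)
  expect_equal(nrow(m4), 2)
  expect_setequal(m4$alt, c("G", "T"))
})

test_that("refinement is monotone and idempotent", {
  ref <- desk_ref(2, 1e5)
  sites <- desk_sites(ref)
  gts <- list(a = simulate_sexual_isolate(sites, seed = 1),
              b = simulate_sexual_isolate(sites, seed = 2))
  pus <- lapply(gts, simulate_pileup, seqmodel = sequencing_model(30, 0.01, 1),
                seed = 5)
  calls <- lapply(gts, function(g)
    data.frame(chrom = g$chrom, pos = g$pos, ref = g$ref_base,
               alt = g$alt_base, gt = g$gt,
               stringsAsFactors = FALSE)[g$gt > 0, ])
  m <- refine_snps(calls, pus)
  # never loses a raw call
  for (id in c("a", "b"))
    expect_gte(sum(m[[paste0("gt_", id)]] > 0, na.rm = TRUE),
               nrow(calls[[id]]))
  # idempotence: feeding the refined genotypes back changes nothing
  calls2 <- lapply(c(a = "a", b = "b"), function(id) {
    g <- m[[paste0("gt_", id)]]
    keep <- !is.na(g) & g > 0
    data.frame(chrom = m$chrom[keep], pos = m$pos[keep], ref = m$ref[keep],
               alt = m$alt[keep], gt = g[keep], stringsAsFactors = FALSE)
  })
  m2 <- refine_snps(calls2, pus)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$gt_a, m$gt_a)
  expect_equal(m2$gt_b, m$gt_b)
})

test_that("rescue recall and false-rescue rate meet targets on synthetic truth", {
  ref <- desk_ref(2, 1e5)
  sites <- desk_sites(ref)
  gts <- list(a = simulate_sexual_isolate(sites, seed = 21),
              b = simulate_sexual_isolate(sites, seed = 22))
  pus <- lapply(seq_along(gts), function(i)
    simulate_pileup(gts[[i]], sequencing_model(30, 0.01, 1), seed = 30 + i))
  names(pus) <- names(gts)
  # drop 30% of b's true het calls; refinement should rescue them
  calls_a <- with(gts$a, data.frame(chrom = chrom, pos = pos, ref = ref_base,
                                    alt = alt_base, gt = gt))[gts$a$gt > 0, ]
  b_het <- which(gts$b$gt == 1)
  set.seed(40)
  dropped <- sample(b_het, round(0.3 * length(b_het)))
  calls_b <- with(gts$b, data.frame(chrom = chrom, pos = pos, ref = ref_base,
                                    alt = alt_base, gt = gt))
  calls_b <- calls_b[setdiff(which(gts$b$gt > 0), dropped), ]
  m <- refine_snps(list(a = calls_a, b = calls_b), pus)
  key <- paste(m$chrom, m$pos)
  gkey <- paste(gts$b$chrom, gts$b$pos)
  truth <- gts$b$gt[match(key, gkey)]
  rescued <- m$src_b == "rescued"
  # recall: dropped true hets also called in a, recovered
  dropped_key <- gkey[dropped]
  recoverable <- key %in% dropped_key
  expect_gt(mean(m$gt_b[recoverable] == 1, na.rm = TRUE), 0.95)
  # false rescues: rescued positions whose truth is hom-ref
  expect_lt(sum(rescued & truth == 0) / max(sum(rescued), 1), 0.01)
})

test_that("sharing statistics match set arithmetic", {
  g <- data.frame(chrom = "chr1", pos = 1:10, ref_base = "A", alt_base = "G",
                  gt = 1L)
  m <- snp_matrix_from_genotypes(list(x = g, y = g))
  s <- sharing_stats(m, "x")
  expect_equal(s$shared_with_ref_pct, c(100, 100))
  expect_equal(s$n_private, c(0, 0))
  # disjoint SNP sets
  g2 <- g; g2$pos <- 11:20
  m2 <- snp_matrix_from_genotypes(list(x = g, y = g2))
  s2 <- sharing_stats(m2, "x")
  expect_equal(s2$shared_with_ref_pct[s2$isolate == "y"], 0)
  expect_equal(s2$n_private, c(10, 10))
  expect_error(sharing_stats(m2, "nope"), "unknown")
})

test_that("clonal families show high pairwise sharing, sexual isolates do not", {
  com <- desk_community()
  m <- snp_matrix_from_genotypes(com$all)
  s <- sharing_stats(m, "L1")
  expect_true(all(s$shared_with_ref_pct[startsWith(s$isolate, "L")] > 75))
  expect_true(all(s$shared_with_ref_pct[startsWith(s$isolate, "H")] < 60))
})
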