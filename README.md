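# clonescan

Tools for distinguishing a clonal, obligately asexual lineage from sexually
recombining isolates in multi-isolate whole-genome resequencing of diploid
microbial eukaryotes (the motivating system is a marine diatom) mapped to a
haploid majority-rules reference.

A sexually reproducing isolate in Hardy–Weinberg equilibrium (HWE), sequenced
against a reference that is one random haplotype from its population, shows:

- heterozygous and homozygous non-reference positions in a **2:1 ratio**
  (per-site probabilities 2*pq* and *pq*, for any allele-frequency spectrum);
- a per-site probability of at most **(1/2)^n = 1/16** (for n = 4) that one
  of its SNPs is simultaneously heterozygous in four other isolates;
- appreciable **crossover density** against any other isolate.

A clonal family descended mitotically from a single inbred founder — with the
reference assembled from a member of the clone — instead shows almost no
homozygous non-reference positions, near-complete SNP sharing, vanishing
crossover densities, and large SNP-free blocks ("SNP deserts") with identical
boundaries across isolates, the footprint of a single ancestral
loss-of-heterozygosity event.

The package implements, for each isolate or isolate set:

- the per-position non-reference read fraction **R = nc / (nc + rc)** and
  genotype-class calling, with mapping-bias correction, single-genotype
  checks, relative copy number and hemizygous-region detection
  (`compute_R`, `classify_positions`, `single_genotype_check`,
  `relative_copy_number`, `detect_hemizygous_regions`);
- HWE diagnostics: the 2:1 test, the predicted homozygous non-reference
  count, the exact binomial sharing test on unlinked sites (one per
  chromosome) and a combined per-isolate verdict (`hwe_ratio_test`,
  `predicted_homnonref`, `sharing_bound`, `unlinked_sharing_test`,
  `clonality_verdict`);
- **SNP-desert detection** under a negative-binomial spacing null
  (P[Bin(L, p) <= k-1] <= 1e-4 with k = 5; 100 bp merging; a parameter-j
  rule at chromosome ends), density ± 2σ bands, cross-isolate boundary
  clustering and a desert-age homogeneity test (`desert_threshold`,
  `find_deserts`, `shared_boundaries`, `desert_age_profile`);
- cross-isolate **SNP-call refinement** (rescuing positions called in one
  isolate and supported but uncalled in another) and sharing statistics
  (`refine_snps`, `sharing_stats`);
- **crossover-density estimation** from genotype-concordance run
  segmentation with noise absorption (`build_concordance`,
  `estimate_crossovers`);
- the maximum-SNP-sharing **cladogram** with shared/private-SNP branch
  lengths and a divergence clock from private SNP counts
  (`build_cladogram`, `divergence_years`);
- discrete-generation **competition simulations** of an obligate asexual
  clone against facultative sexuals, including the advantageous-recessive
  reassembly scenario (`run_competition`, `recessive_reassembly`);
- a **synthetic-data generator** for all of the above: HWE populations,
  founder-anchored references, clonal families with LoH blocks and private
  mutations, planted recombinants, and error-bearing pileup count tables
  (`sim_population`, `anchor_founder`, `simulate_clonal_isolates`,
  `simulate_recombinant`, `simulate_pileup`).

See the vignette `vignettes/clonality-methods.Rmd` for the models, their
assumptions and the numerical conventions.

## Worked example

Simulate a community of three clones (sharing a 70 kb LoH block) and two
sexual isolates on a small 4 x 200 kb genome, then run the core analyses:

```r
library(clonescan)

ref   <- ref_genome(n_chrom = 4, chrom_length = 2e5)
sites <- sim_population(ref, population_model(), seed = 42)
af    <- anchor_founder(sites, founder_seed = 7)   # reference = founder consensus

cm <- clonal_model(years = c(100, 100, 100),
                   loh_blocks = data.frame(chrom = "chr1",
                                           start = 50001, end = 120000),
                   founder_seed = 7)
clones <- simulate_clonal_isolates(af$sites, ref, cm, seed = 8,
                                   founder = af$founder)
names(clones) <- c("L1", "L2", "L3")
sexuals <- list(H1 = simulate_sexual_isolate(af$sites, seed = 9),
                H2 = simulate_sexual_isolate(af$sites, seed = 10))

m <- snp_matrix_from_genotypes(c(clones, sexuals))
sharing_stats(m, "L1")
#>   isolate n_snps shared_with_ref_pct n_private
#> 1      L1   1427           100.00000        28
#> 2      L2   1430            97.83217        31
#> 3      L3   1417            98.72971        18
#> 4      H1   1540            36.29870       591
#> 5      H2   1556            35.98972       606
```

The clones share ~98% of their SNPs and carry a few dozen private mutations
each; the sexual isolates share only ~36% and carry hundreds. The HWE ratio
separates the regimes just as sharply — the clone has *no* homozygous
non-reference positions (the reference is its own founder's consensus),
while the sexual isolate sits on the 2:1 expectation:

```r
#> L1: het = 1427, hom-nonref = 0,   het/hom ratio = Inf,  HWE p = 6.15e-252
#> H1: het = 1540, hom-nonref = 781, het/hom ratio = 1.97, HWE p = 0.758
```

The planted LoH block on chr1 (50,001–120,000) is recovered as a SNP desert
(boundaries resolve to the nearest flanking SNPs):

```r
g    <- clones$L1
snps <- data.frame(chrom = g$chrom[g$gt == 1], pos = g$pos[g$gt == 1])
dm   <- desert_model(p = nrow(snps) / sum(ref$length))
find_deserts(snps, ref, dm)
#>   chrom start    end length n_snps      density   density_lo  density_hi
#> 1  chr1 45484 123368  77885     10 0.0001283944 4.719587e-05 0.000209593
```

The sharing cladogram resolves the three clones as one subtree (internal
branch lengths = SNPs shared by all isolates below; terminal = private):

```r
build_cladogram(m)$newick
#> ((H1:591,((L1:28,L3:18):1399,L2:31):1399):559,H2:606):253;
```

And the divergence clock converts a private-SNP count into a lineage age:

```r
divergence_years(2070, clock_model(mu = 1e-9, division_interval_days = 2,
                                   genome_size = 32e6, ploidy = 2))
#> 177.1047   # years — about 2,000 private SNPs accumulate within two centuries
```

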