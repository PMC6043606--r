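---
title: "Detecting clonal asexual lineages from resequencing data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clonal asexual lineages from resequencing data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescan)
```

## The problem

Diploid microbial eukaryotes such as centric diatoms are facultatively
sexual: long stretches of mitotic (clonal) growth are punctuated by episodic
meiosis and fertilisation. When several isolates of one species are
resequenced against a single haploid, majority-rules reference assembly,
their reproductive history leaves quantitative fingerprints in the read
data:

* a **sexually recombining** population in Hardy–Weinberg equilibrium (HWE)
  shows heterozygous positions and homozygous non-reference positions in a
  2:1 ratio, measurable crossover densities between any two isolates, and
  modest SNP sharing;
* a **clonal lineage** descended mitotically from a single founder — when
  the reference assembly itself derives from a member of that lineage —
  shows almost no homozygous non-reference positions, near-complete SNP
  sharing, vanishing crossover densities, and large SNP-free blocks with
  identical boundaries across isolates, the footprint of a single ancestral
  loss-of-heterozygosity (LoH) event.

clonescan implements the statistics that separate these regimes, a
synthetic-data generator with the matching statistical structure for
calibration and testing, and competition simulations that probe *why* an
obligate asexual clone can dominate.

## The R statistic and genotype classes

For every genome position, `rc` counts reads carrying the reference base and
`nc` reads carrying the most common non-reference base. The per-position
statistic is

$$R = \frac{nc}{nc + rc}.$$

Restricting to the single most common non-reference nucleotide removes part
of the sequencing error: positions where a *second* non-reference base also
has support are overwhelmingly technical artefacts, and `compute_R()` flags
them as ambiguous when that second count exceeds `max(1, 0.2 * nc)`.

`classify_positions()` calls hom-ref / het / hom-nonref from R with a
heterozygous band of `(0.2, 0.8)` by default. At depths of 20x or more with
error rates around 1% the three modes (near 0, 0.5 and 1) are separated by
much more than the band edges, so the exact band matters little; it is
configurable for noisier data. Positions with extreme read coverage are
excluded before classification; "extreme" defaults to outside 0.25x–2x the
genome-wide median depth, a conventional choice we adopt because no sharper
definition is forced by the statistics.

Aligners map reads carrying non-reference alleles slightly less efficiently
than reference reads, which drags the heterozygous mode of R below 0.5. The
classical remedy is re-filtering on high base qualities; since this package
consumes count tables rather than raw reads, it instead offers an optional
multiplicative rescaling: the bias `b` is estimated from the mode `m` of the
heterozygous R distribution as `b = m / (1 - m)` and `nc` is rescaled by
`1/b`, which recentres heterozygous sites at 0.5 while leaving homozygous
classes essentially untouched.

## Hardy–Weinberg diagnostics

Three independent diagnostics each compare an isolate against the HWE
expectation.

**The 2:1 law.** At a biallelic site with allele frequencies $p$ and $q$,
a diploid HWE genotype is heterozygous with probability $2pq$. If the
reference base is one random haplotype from the population, the site is
homozygous *non-reference* with probability $pq$ (the genotype is homozygous
for one allele, the reference carries the other). The ratio of expectations
is exactly 2 at every site, so it is 2 for any allele-frequency spectrum —
this is why the generator can expose the spectrum as a knob without
endangering the invariant. `hwe_ratio_test()` turns the observed counts into
an exact binomial test of het fraction 2/3; `predicted_homnonref()` gives
the expected homozygous non-reference count (half the het count), whose
gross deficit is the first clonal signature.

**The sharing bound.** An independent HWE isolate is heterozygous at a site
with probability $2pq \le 1/2$, so the chance that a SNP is simultaneously
heterozygous in $n$ other isolates is at most $(1/2)^n$ — $1/16$ for four.
`unlinked_sharing_test()` evaluates the exact upper tail of
$\mathrm{Binomial}(n_{\rm sites}, (1/2)^n)$ at the observed sharing level.
To avoid linkage inflating the count, `sample_unlinked_sharing()` draws one
candidate site per chromosome, mirroring a 24-chromosome genome with 24
sites. We deliberately use the conservative bound rather than a
frequency-weighted sharing probability: the bound is assumption-free and
already rejects HWE by many orders of magnitude in the clonal regime.

**Crossover density.** `build_concordance()` marks each informative site
(heterozygous in at least one isolate of a pair) concordant or discordant;
crossovers appear as switches between long runs. Because the supplementary
description of the original estimator is not available, the estimator here
is a declared reconstruction: run-length segmentation in which runs
supported by fewer than `min_run_sites` (default 10) same-state sites are
iteratively absorbed into their neighbours, starting with the weakest. A
run's strength is its *support* — absorbed opposite-state sites never count
towards it — so long runs cannot be manufactured out of noise. Transitions
between the surviving runs are counted per chromosome and divided by the
assayed span in kb. On planted recombinants this recovers breakpoint counts
to within one, and it reproduces the order-of-magnitude separation between
clonal pairs (density about 0) and sexual pairs; the absolute densities of
real data depend on informative-site spacing and are not comparable across
studies.

`clonality_verdict()` combines the three: an isolate is labelled clonal
("L-like") only when the homozygous non-reference deficit is at least
10-fold *and* the sharing test rejects HWE; sexual ("H-like") only when the
observed hom-nonref:het ratio is within 25% of 1/2 (and, when crossover
densities are supplied, the isolate falls in the higher density cluster);
conflicting evidence yields "indeterminate" rather than a silent choice. The
10-fold and 25% defaults reflect the order-of-magnitude gaps between the two
regimes; they are configuration, not fitted constants.

## SNP deserts

Let $1/p$ be an isolate's mean distance between heterozygous positions,
estimated as total SNPs over callable genome length (assembly gaps can be
masked with a BED of excluded intervals). Under a null of independent
per-bp SNPs, the distance to the $k$-th next SNP is negative binomial with
parameters $p$ and $k$. `desert_threshold()` finds the smallest $L$ with
$P[\mathrm{Bin}(L, p) \le k - 1] \le \alpha$ — the binomial-tail form avoids
the success/failure convention ambiguity of negative-binomial
parameterisations and is summed exactly. With the conventional $k = 5$ and
$\alpha = 10^{-4}$, `find_deserts()` reports all maximal intervals longer
than $L$ containing fewer than $k$ SNPs, merging intervals that overlap or
sit within 100 bp of each other, iterated to a fixed point.

Chromosome ends need care. At the 3' end, where only $j < k$ SNPs remain,
the threshold is recomputed with parameter $j$; with $j = 0$ no desert can
be declared, because the spacing model has no event left to wait for — a
short SNP-free chromosome is not evidence of anything. The candidate
interval runs from just after the last SNP preceding the final $j$ to the
chromosome end. Intervals are tested strictly against $>L$. These choices
are verified against an exhaustive interval-enumeration oracle on small
chromosomes in the test suite.

Each desert is annotated with its density $p = n/L$ and the band
$p \pm 2\sigma$, $\sigma = \sqrt{p(1-p)/L}$. `shared_boundaries()` clusters
deserts across isolates whose left and right boundaries agree within a
tolerance (default 0 bp — exact), the signature of LoH inherited from a
common ancestor rather than of independent sweeps. `desert_age_profile()`
asks whether long deserts (at least 50 kb) are contemporaneous: under
uniform mutation accumulation from a SNP-free origin, older deserts are
denser, so a chi-square homogeneity test across desert SNP counts (expected
proportional to length) that fails to reject is consistent with a single
simultaneous LoH event, and the flank/desert density ratio gives the fold
depletion.

## SNP refinement and the sharing cladogram

Per-isolate variant calling misses positions in one isolate that were
confidently called in another. `refine_snps()` takes the union of raw calls
and, at each position, rescues a heterozygous call in any other isolate with
depth at least 10 and at least 20% of reads supporting the *same* alternate
allele; covered positions without support become homozygous reference,
under-covered ones missing. The thresholds separate a 1% error process from
a true heterozygote at 10x and are exposed as configuration; multi-allelic
positions are kept as separate records and never merged. Refinement never
removes a raw call and is idempotent.

`build_cladogram()` groups isolates by recursive bipartitioning. The
objective "maximise SNPs shared within each subtree, minimise sharing across
subtrees" is formalised as the split score $S(A) + S(B) - X(A,B)$, where
$S(\cdot)$ counts SNPs present in *all* members of a side and $X$ counts
SNPs present on both sides but in all members of neither. All bipartitions
are scored exhaustively ($2^{n-1}-1$ at the root; trivial for the single
digit isolate counts this analysis targets), ties broken deterministically
by the lexicographically smallest partition. Internal branch lengths are the
number of SNPs shared by every isolate below the branch; terminal branch
lengths are private SNP counts. The score is this package's explicit
formalisation — alternatives can be plugged in — and its defining property,
that a clonal family always resolves as one subtree against sexual
outgroups, is exercised over 100 seeded simulations in the tests.

`divergence_years()` converts a private SNP count into a lineage age:
`years = private / (ploidy * genome_size * mu * divisions_per_year)`. The
diploid target (`ploidy = 2`) is the default because private SNPs are
heterozygous — each of the two homologous copies is a mutational target.
With a mutation rate of $10^{-9}$ per bp per division, one division per two
days and a 32 Mb genome, roughly 2,000 private SNPs accumulate within two
centuries.

## The synthetic-data generator

`sim_population()` places polymorphic sites at a default density of
180,000 sites over 32 Mb (about 1 per 178 bp) and draws minor allele
frequencies from a uniform spectrum on (0, 0.5] or a neutral 1/q spectrum;
the wild spectrum is unknown, and the analyses above are insensitive to it,
so it is a knob rather than an assertion. The reference base at each site is
one random haplotype from the population.

`anchor_founder()` models the decisive feature of a reference assembled from
a member of the clonal lineage: a haploid majority-rules consensus of one
diploid individual carries that individual's allele at homozygous sites and
a coin-flip allele at heterozygous sites. The founder — and every clone
descended from it — is therefore heterozygous or homozygous-reference but
essentially never homozygous non-reference, while the marginal distribution
of the reference base remains a single random haplotype, preserving the 2:1
law for independent sexual isolates drawn against the same anchored sites.
Without this anchoring a simulated "clone" would inherit the founder's
$pq$-fraction of homozygous non-reference sites and the clonal signature
would vanish; this is a property of real reference-based studies, not an
artefact of the generator.

`simulate_clonal_isolates()` forces the founder homozygous-reference inside
configured LoH blocks and gives each descendant private heterozygous
mutations, Poisson with mean `ploidy * genome * mu * divisions`, at
uniformly random positions (collisions with existing sites are redrawn; at
desk scale the collision rate is negligible). `simulate_pileup()` adds
Poisson depth, a mapping-bias-weighted haplotype choice per read and a
uniform base-error process, so a heterozygous site at bias $b$ has expected
$R = b/(1+b)$. `simulate_recombinant()` plants crossover breakpoints by
alternating identical-by-descent and independently redrawn segments, with a
minimum informative-site spacing (default 30 sites) so every planted segment
is in principle detectable — the calibration truth for the crossover
estimator.

What the generator does *not* emulate: linkage disequilibrium within
segments of sexual isolates (sites are drawn independently), indels and
structural variation beyond homozygous-reference LoH blocks, read-level
artefacts (chimeras, duplicates, mapping to repeats) beyond a single bias
multiplier, and culture-acquired hemizygous deletions' correlation with
time. Passing tests therefore demonstrate that the estimators recover the
statistical structure they target, not that they are robust to every
artefact of a particular sequencing platform.

Default problem sizes are chosen for interactive use: a 4 x 1 Mb desk
genome for community simulations (tests mostly use 4 x 100–200 kb), a
single 6 Mb chromosome at elevated density when at least $10^6$ polymorphic
sites are required for ratio checks, and 24 x 50 kb when the one-site-per-
chromosome sharing test needs the full chromosome count. All generators are
bit-reproducible under a fixed seed.

## Life-history competition simulations

`run_competition()` implements a minimal discrete-generation model: one
generation is one mitotic division (about two days); an obligate asexual
clone doubles every generation; a facultative lineage doubles except during
sexual episodes occupying the last `d` generations (default 2) of every
interval of `T` generations (default 365, about two years); the population
is then resampled multinomially to a cap `N` (default $10^4$). With `d = 0`
the model reduces exactly to neutral Wright–Fisher drift, the calibration
limit used in the tests. With `d > 0` the asexual clone compounds a growth
advantage of $2^{d/T}$ per interval and fixes in a majority of replicates,
faster for larger `d` or shorter `T` — dominance on the order of $10^4$–
$10^6$ generations under plausible parameters, i.e. decades to centuries at
two days per division.

`recessive_reassembly()` adds a single tracked locus with an advantageous
Mendelian recessive, modelled as an `f`-fold increase in the time between
meiotic events for homozygous carriers, and follows the *lineage identity*
of the original homozygous focal clone separately from the allele itself.
During an episode the participating genotypes pool gametes and return
Hardy–Weinberg offspring; focal members that undergo meiosis lose their
lineage identity. A facultative focal genotype therefore eventually
contributes its haplotypes to the population and is displaced by reassembled
homozygous backgrounds even as the allele sweeps to fixation, whereas the
obligate variant of the same configuration retains its genotype identity at
fixation — the qualitative contrast that distinguishes "asexual because
obligate" from "asexual because currently advantaged". The original study's
exact population sizes and intervals are not published; all parameters here
are explicit configuration, and the package's claims about them are
qualitative (direction and ordering), never numeric fits.

Episodes are scheduled at the *end* of each interval so that a lineage's
first sexual pause occurs after `T - d` generations of growth; whole
genotype classes enter meiosis together, a deliberate simplification that
makes episode cost and reassembly explicit at the expense of within-class
asynchrony.

## Numerical conventions and degenerate inputs

Positions are 1-based inclusive throughout; BED exports are 0-based
half-open. Zero-depth positions have undefined R and are excluded.
`hwe_ratio_test()` reports an infinite ratio (test still defined) when no
homozygous non-reference positions exist. Desert density with $n > L$ is
rejected; empty chromosomes return empty desert tables. The sharing test
rejects bounds outside (0, 1]. Unsorted SNP input is sorted with a warning.
All stochastic functions take explicit seeds and are reproducible
bit-for-bit.
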