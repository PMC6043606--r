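#' Count SNP positions shared by all members of an isolate subset
#'
#' @param matrix a `snp_matrix`.
#' @param subset character vector of isolate ids.
#' @param snp_classes genotype classes counted as carrying a SNP (default
#'   heterozygous only).
#' @return integer count of positions at which every member carries a SNP.
#' @export
sharing_counts <- function(matrix, subset, snp_classes = 1L) {
  if (length(subset) == 0) stop("empty isolate subset")
  iso <- matrix_isolates(matrix)
  if (!all(subset %in% iso)) stop("unknown isolate id in subset")
  pres <- snp_presence(matrix, snp_classes)
  sum(rowSums(pres[, subset, drop = FALSE]) == length(subset))
}

# all bipartitions of ids into two non-empty sides, canonical: side A holds
# the lexicographically smallest id
bipartitions <- function(ids) {
  ids <- sort(ids)
  rest <- ids[-1]
  n <- length(rest)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    a <- c(ids[1], rest[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    b <- setdiff(ids, a)
    if (length(b) == 0) next
    out[[length(out) + 1]] <- list(a = a, b = b)
  }
  out
}

split_score <- function(pres, a, b) {
  in_all <- function(s) rowSums(pres[, s, drop = FALSE]) == length(s)
  any_in <- function(s) rowSums(pres[, s, drop = FALSE]) > 0
  S_a <- sum(in_all(a))
  S_b <- sum(in_all(b))
  cross <- sum(any_in(a) & any_in(b) & !(in_all(a) | in_all(b)))
  S_a + S_b - cross
}

#' Build the maximum-SNP-sharing cladogram
#'
#' Recursive top-down bipartitioning of the isolates: at each node every
#' bipartition (A, B) is scored as `S(A) + S(B) - X(A, B)`, where `S(.)` is
#' the count of SNPs shared by all members of a side and `X` the count of
#' SNPs present in at least one member of each side but not in all of either
#' side; the maximum-scoring split is taken (ties broken by the
#' lexicographically smallest partition, which the enumeration order
#' guarantees). Internal branch lengths are the numbers of SNPs shared by all
#' isolates in the subtree below; terminal branch lengths are private SNP
#' counts.
#'
#' @param matrix a `snp_matrix`.
#' @param snp_classes genotype classes counted as a SNP.
#' @return a `clade_tree` list: `tree` (nested list with `members`,
#'   `shared`, children `left`/`right`, leaf `private`), `newick` (branch
#'   lengths in SNP counts) and `phylo` (an [ape::read.tree()] object).
#' @export
build_cladogram <- function(matrix, snp_classes = 1L) {
  iso <- matrix_isolates(matrix)
  if (length(iso) < 2) stop("need at least two isolates")
  pres <- snp_presence(matrix, snp_classes)
  carriers <- rowSums(pres)
  private <- vapply(iso, function(id) sum(pres[, id] & carriers == 1), 0L)
  names(private) <- iso
  recurse <- function(ids) {
    shared <- sum(rowSums(pres[, ids, drop = FALSE]) == length(ids))
    if (length(ids) == 1) {
      return(list(members = ids, shared = shared, private = private[[ids]]))
    }
    parts <- bipartitions(ids)
    scores <- vapply(parts, function(p) split_score(pres, p$a, p$b), 0)
    best <- parts[[which.max(scores)]]   # first max = lexicographic tie-break
    list(members = ids, shared = shared,
         left = recurse(best$a), right = recurse(best$b))
  }
  tree <- recurse(sort(iso))
  nwk <- paste0(to_newick(tree), ";")
  list(tree = tree, newick = nwk, phylo = ape::read.tree(text = nwk))
}

# newick with internal branch length = shared count of the subtree,
# terminal branch length = private count
to_newick <- function(node) {
  if (length(node$members) == 1) {
    return(paste0(node$members, ":", node$private))
  }
  paste0("(", to_newick(node$left), ",", to_newick(node$right), "):",
         node$shared)
}

#' Clock model for divergence-time estimates
#'
#' @param mu mutations per bp per division.
#' @param division_interval_days days per mitotic division.
#' @param genome_size haploid genome size in bp.
#' @param ploidy copies of the genome accumulating (heterozygous) private
#'   mutations.
#' @export
clock_model <- function(mu = 1e-9, division_interval_days = 2,
                        genome_size = 32e6, ploidy = 2) {
  if (mu <= 0 || division_interval_days <= 0 || genome_size <= 0 || ploidy <= 0)
    stop("all clock parameters must be positive")
  structure(list(mu = mu, division_interval_days = division_interval_days,
                 genome_size = genome_size, ploidy = ploidy),
            class = "clock_model")
}

#' Years required to accumulate a private SNP count
#'
#' `years = private_snps / (ploidy * genome_size * mu * divisions_per_year)`
#' with `divisions_per_year = 365.25 / division_interval_days`.
#'
#' @param private_snps observed private SNP count.
#' @param clock a [clock_model()].
#' @return estimated years since divergence.
#' @export
divergence_years <- function(private_snps, clock) {
  rate <- clock$ploidy * clock$genome_size * clock$mu *
    (365.25 / clock$division_interval_days)
  private_snps / rate
}
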