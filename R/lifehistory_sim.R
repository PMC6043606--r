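#' Configuration for the clone-competition simulator
#'
#' A minimal discrete-generation model of an obligate asexual clone competing
#' with facultatively sexual lineages. One generation is one mitotic
#' division (about two days for a diatom). Facultative lineages undergo a
#' sexual episode every `meiotic_interval` generations; an episode pauses
#' their division for `meiotic_cost` generations while the asexual clone
#' keeps dividing. Each generation the population is resampled multinomially
#' back to the cap `N`.
#'
#' @param N population cap.
#' @param generations maximum generations to simulate.
#' @param meiotic_interval T, generations between sexual episodes (default
#'   365, i.e. about two years at two days per division).
#' @param meiotic_cost d, generations of paused division during an episode.
#' @param recessive_advantage f >= 1; multiplies T for genotypes homozygous
#'   for the advantageous recessive allele (the advantage is modelled as an
#'   increased time between meiotic events).
#' @param init_freq initial frequency of the focal (asexual or focal-aa)
#'   lineage.
#' @param division_interval_days used to convert generations to years.
#' @export
sim_config <- function(N = 10000, generations = 20000,
                       meiotic_interval = 365, meiotic_cost = 2,
                       recessive_advantage = 1, init_freq = 0.01,
                       division_interval_days = 2) {
  if (N < 1) stop("N must be positive")
  if (meiotic_interval < 1) stop("meiotic_interval must be >= 1")
  if (meiotic_cost < 0) stop("meiotic_cost must be >= 0")
  if (recessive_advantage < 1) stop("recessive_advantage must be >= 1")
  structure(list(N = N, generations = generations,
                 meiotic_interval = meiotic_interval,
                 meiotic_cost = meiotic_cost,
                 recessive_advantage = recessive_advantage,
                 init_freq = init_freq,
                 division_interval_days = division_interval_days),
            class = "sim_config")
}

# multinomial resample of counts back to N (drift)
resample <- function(counts, N) {
  tot <- sum(counts)
  if (tot == 0) return(counts)
  as.numeric(stats::rmultinom(1, N, counts / tot))
}

#' Competition between an obligate asexual clone and facultative sexuals
#'
#' Each generation the asexual clone doubles; the facultative lineage doubles
#' except during its sexual episodes (every T generations, lasting d
#' generations, during which its members pair and recombine at the tracked
#' neutral locus -- which leaves class frequencies unchanged); the population
#' is then resampled to the cap. With d = 0 the model reduces to neutral
#' Wright-Fisher drift between the two classes.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a `trajectory` list: `freq` (asexual frequency per generation),
#'   `fixed` ("asexual", "facultative" or NA if censored),
#'   `fixation_generation` (NA if censored), `fixation_years`.
#' @export
run_competition <- function(config, seed = 1) {
  set.seed(seed)
  N <- config$N
  counts <- c(asex = round(config$init_freq * N),
              fac = N - round(config$init_freq * N))
  T_int <- config$meiotic_interval
  d <- config$meiotic_cost
  freq <- numeric(config$generations)
  fixed <- NA_character_
  fix_gen <- NA_integer_
  for (g in seq_len(config$generations)) {
    # sexual episodes occupy the last d generations of each interval of T
    in_episode <- d > 0 && (g - 1) %% T_int >= T_int - d
    growth <- c(2, if (in_episode) 1 else 2)
    counts <- resample(counts * growth, N)
    names(counts) <- c("asex", "fac")
    freq[g] <- counts["asex"] / N
    if (counts["asex"] == 0 || counts["fac"] == 0) {
      fixed <- if (counts["asex"] == N) "asexual" else "facultative"
      fix_gen <- g
      freq <- freq[seq_len(g)]
      break
    }
  }
  structure(list(freq = freq, fixed = fixed, fixation_generation = fix_gen,
                 fixation_years = fix_gen * config$division_interval_days /
                   365.25),
            class = "trajectory")
}

hwe_offspring <- function(n, q) {
  # offspring genotype counts for n meiotic products with allele freq q
  c(AA = n * (1 - q)^2, Aa = n * 2 * q * (1 - q), aa = n * q^2)
}

#' Advantageous-recessive reassembly scenario
#'
#' Tracks an advantageous Mendelian recessive allele `a` (advantageous only
#' when homozygous, modelled as a `recessive_advantage`-fold increase in the
#' time between meiotic events) separately from the lineage identity of the
#' original homozygous focal clone. Classes: `focal_aa` (the original
#' mitotically intact lineage), and reassembled backgrounds `AA`, `Aa`,
#' `aa_re`. During a sexual episode the participating genotypes pause
#' division, pool gametes and return Hardy-Weinberg offspring; focal members
#' that undergo meiosis lose their lineage identity (their `aa` offspring
#' join `aa_re`). With `obligate = TRUE` the focal clone never enters
#' meiosis.
#'
#' @param config a [sim_config()] with `recessive_advantage >= 1`.
#' @param seed integer seed.
#' @param obligate if TRUE the focal lineage is an obligate asexual.
#' @return a `trajectory` list: `allele_freq` and `focal_freq` per
#'   generation, `allele_fixed_generation`, `focal_extinct_generation` (NA if
#'   not reached), and `outcome`: "reassembled" when the allele fixed and the
#'   original focal lineage was displaced, "focal-retained" when an obligate
#'   focal clone swept to fixation with its genotype identity intact,
#'   "allele-lost" when drift removed the allele, NA if censored.
#' @export
recessive_reassembly <- function(config, seed = 1, obligate = FALSE) {
  set.seed(seed)
  N <- config$N
  f <- config$recessive_advantage
  T_int <- config$meiotic_interval
  d <- config$meiotic_cost
  n0 <- round(config$init_freq * N)
  counts <- c(focal_aa = n0, AA = N - n0, Aa = 0, aa_re = 0)
  allele_freq <- numeric(config$generations)
  focal_freq <- numeric(config$generations)
  allele_fix <- NA_integer_
  focal_ext <- NA_integer_
  # genotype-specific episode phase: aa genotypes meiose every f*T
  T_of <- c(focal_aa = f * T_int, AA = T_int, Aa = T_int, aa_re = f * T_int)
  for (g in seq_len(config$generations)) {
    # episodes occupy the last d generations of each genotype's interval
    in_ep <- d > 0 & ((g - 1) %% T_of) >= (T_of - d)
    ep_end <- d > 0 & ((g - 1) %% T_of) == (T_of - 1)
    if (obligate) { in_ep["focal_aa"] <- FALSE; ep_end["focal_aa"] <- FALSE }
    grown <- counts * ifelse(in_ep, 1, 2)
    # at episode end, the pausing genotypes recombine: pooled gametes ->
    # HWE offspring on non-focal backgrounds
    meiosed <- names(counts)[ep_end]
    if (length(meiosed) > 0) {
      pool <- grown[meiosed]
      n_pool <- sum(pool)
      if (n_pool > 0) {
        a_gam <- (sum(pool[meiosed %in% c("focal_aa", "aa_re")]) +
                    0.5 * sum(pool[meiosed == "Aa"])) / n_pool
        off <- hwe_offspring(n_pool, a_gam)
        grown[meiosed] <- 0
        grown["AA"] <- grown["AA"] + off["AA"]
        grown["Aa"] <- grown["Aa"] + off["Aa"]
        grown["aa_re"] <- grown["aa_re"] + off["aa"]
      }
    }
    counts <- resample(grown, N)
    names(counts) <- c("focal_aa", "AA", "Aa", "aa_re")
    a_freq <- (counts["focal_aa"] + counts["aa_re"] + 0.5 * counts["Aa"]) / N
    allele_freq[g] <- a_freq
    focal_freq[g] <- counts["focal_aa"] / N
    if (is.na(focal_ext) && counts["focal_aa"] == 0) focal_ext <- g
    if (is.na(allele_fix) && a_freq == 1) allele_fix <- g
    # run on past allele fixation until the lineage question is settled: a
    # facultative focal lineage still faces its own meiotic episodes, at
    # which its descendants join the reassembled backgrounds
    done <- a_freq == 0 ||
      (!is.na(allele_fix) && !is.na(focal_ext)) ||
      ((obligate || d == 0) && counts["focal_aa"] == N) ||
      (d == 0 && !is.na(allele_fix))
    if (done) {
      allele_freq <- allele_freq[seq_len(g)]
      focal_freq <- focal_freq[seq_len(g)]
      break
    }
  }
  last_focal <- focal_freq[length(focal_freq)]
  outcome <- if (allele_freq[length(allele_freq)] == 0) "allele-lost"
  else if (!is.na(allele_fix) && !is.na(focal_ext)) "reassembled"
  else if ((obligate || d == 0) && last_focal == 1) "focal-retained"
  else NA_character_
  structure(list(allele_freq = allele_freq, focal_freq = focal_freq,
                 allele_fixed_generation = allele_fix,
                 focal_extinct_generation = focal_ext, outcome = outcome),
            class = "trajectory")
}

#' Summarise replicate trajectories
#'
#' @param trajectories list of [run_competition()] results.
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return list: `n`, `n_fixed`, `n_censored`, `fixation_probability` (of the
#'   asexual/focal class) with bootstrap CI, `median_fixation_generations`
#'   and `median_fixation_years` (censored runs excluded) with bootstrap CI.
#' @export
summarize_trajectories <- function(trajectories, n_boot = 1000, conf = 0.95,
                                   seed = 1) {
  if (length(trajectories) == 0) stop("need at least one trajectory")
  set.seed(seed)
  fixed <- vapply(trajectories, function(t)
    identical(t$fixed, "asexual"), TRUE)
  gens <- vapply(trajectories, function(t)
    if (identical(t$fixed, "asexual")) t$fixation_generation else NA_real_,
    0)
  yrs <- vapply(trajectories, function(t)
    if (identical(t$fixed, "asexual")) t$fixation_years else NA_real_, 0)
  censored <- vapply(trajectories, function(t) is.na(t$fixed), TRUE)
  n <- length(trajectories)
  boot <- replicate(n_boot, {
    ix <- sample.int(n, n, replace = TRUE)
    c(p = mean(fixed[ix]),
      med = stats::median(gens[ix], na.rm = TRUE))
  })
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(n = n, n_fixed = sum(fixed), n_censored = sum(censored),
       fixation_probability = mean(fixed),
       fixation_probability_ci = unname(stats::quantile(boot["p", ], qs)),
       median_fixation_generations = stats::median(gens, na.rm = TRUE),
       median_fixation_generations_ci =
         unname(stats::quantile(boot["med", ], qs, na.rm = TRUE)),
       median_fixation_years = stats::median(yrs, na.rm = TRUE))
}
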