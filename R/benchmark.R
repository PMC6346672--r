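#' Known-origin parentage accuracy benchmark
#'
#' The standing evaluation design for the PBT engine: a synthetic world with
#' fully genotyped broodstocks, offspring drawn from random (polygamous)
#' parent pairs, genotyping error and missingness applied, and assignment
#' run against the pooled true parents plus unrelated decoy broodstock.
#' Reports, per seed and aggregated, the assignment rate (accepted /
#' genotyped) and the accuracy of accepted assignments with respect to
#' population and brood year jointly.
#'
#' @param seeds integer vector of simulation seeds (one world per seed).
#' @param n_broodstock_pops populations with genotyped broodstock
#'   (default 8).
#' @param pairs_per_pop dam/sire pairs per broodstock (default 50).
#' @param n_offspring offspring in the mixed sample (default 600).
#' @param n_decoys unrelated decoy parents added to the pool (default 1000).
#' @param config a \code{\link{sim_config}} (its seed field is overridden
#'   per run by \code{seeds}).
#' @param parentage a \code{\link{parentage_config}}.
#' @return list with \code{per_seed} (data frame: seed, n, accepted, rate,
#'   correct, accuracy) and aggregate \code{assignment_rate} and
#'   \code{accuracy} (both fractions, pooled over seeds).
#' @export
pbt_benchmark <- function(seeds = 1:10, n_broodstock_pops = 8L,
                          pairs_per_pop = 50L, n_offspring = 600L,
                          n_decoys = 1000L, config = sim_config(),
                          parentage = parentage_config()) {
  rows <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    s <- as.integer(seeds[si])
    cfg <- config
    cfg$seed <- s
    world <- simulate_baseline_freqs(cfg)
    pops <- rownames(world$freqs)
    bpops <- pops[seq_len(min(n_broodstock_pops, length(pops)))]
    true_pool <- do.call(bind_pools, lapply(bpops, function(p)
      simulate_broodstock(p, pairs_per_pop, pairs_per_pop, world$freqs[p, ])))
    per_pop <- ceiling(n_decoys / length(pops))
    decoys <- do.call(bind_pools, lapply(pops, function(p)
      simulate_broodstock(p, ceiling(per_pop / 2), floor(per_pop / 2),
                          world$freqs[p, ], label = paste0("decoy_", p))))
    decoys <- parent_pool(subset_indiv(decoys$genotypes, seq_len(n_decoys)),
                          decoys$meta[seq_len(n_decoys), ])
    pool <- bind_pools(true_pool, decoys)
    comp <- stats::setNames(rep(1 / length(bpops), length(bpops)), bpops)
    mix <- simulate_mixture(comp, n_offspring, world$freqs, pool = true_pool,
                            error_rate = cfg$genotype_error_rate,
                            missing_rate = cfg$missing_rate)
    qc <- qc_filter(mix$genotypes)
    res <- assign_parentage(qc$table, pool, world$freqs, parentage)
    sm <- pbt_summary(res, mix$truth)
    acc_rows <- res$mode %in% c("pair", "single")
    tr <- mix$truth[match(res$offspring_id, mix$truth$individual_id), ]
    correct <- sum(acc_rows & res$population == tr$population &
                     res$brood_year == tr$brood_year, na.rm = TRUE)
    rows[[si]] <- data.frame(seed = s, n = sm$n_genotyped,
                             accepted = sm$n_accepted,
                             rate = sm$assignment_rate,
                             correct = correct, accuracy = sm$accuracy)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       assignment_rate = sum(per_seed$accepted) / sum(per_seed$n),
       accuracy = sum(per_seed$correct) / sum(per_seed$accepted))
}
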