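test_that("baseline posterior frequencies follow the Beta posterior mean", {
  g <- matrix(c(rep(1L, 10), rep(NA, 2)), ncol = 1,
              dimnames = list(NULL, "L1"))
  base <- genotype_table(g, group = "popA")
  # 10 heterozygotes: 10 copies of B out of 20 called alleles
  expect_equal(baseline_posterior_freqs(base, 0.5)[1, 1], 10.5 / 21)
  # zero observations at a locus: prior mean 0.5
  g2 <- matrix(NA_integer_, 4, 1, dimnames = list(NULL, "L1"))
  expect_equal(baseline_posterior_freqs(genotype_table(g2, "popA"))[1, 1], 0.5)
  # monotone in the allele count
  set.seed(1)
  for (i in 1:20) {
    k <- sample(0:20, 2)
    fr <- vapply(sort(k), function(cnt) {
      gg <- matrix(c(rep(2L, cnt %/% 2), rep(1L, cnt %% 2),
                     rep(0L, 10 - cnt %/% 2 - cnt %% 2)), ncol = 1,
                   dimnames = list(NULL, "L1"))
      baseline_posterior_freqs(genotype_table(gg, "p"))[1, 1]
    }, numeric(1))
    expect_true(diff(fr) >= 0)
  }
})

test_that("locus_genotype_loglik matches Hardy-Weinberg class probabilities", {
  expect_equal(locus_genotype_loglik(1L, 0.5), log(0.5))
  expect_equal(locus_genotype_loglik(NA, 0.3), 0)
  for (p in c(0.2, 0.5, 0.8))
    expect_equal(sum(exp(locus_genotype_loglik(0:2, p))), 1)
})

test_that("the Gibbs sampler recovers a one-population mixture and is seeded", {
  cfg <- sim_config(n_cus = 2, pops_per_cu = 1, fst_between_cu = 0.15,
                    fst_within_cu = 0.001, n_loci = 150, seed = 31)
  world <- simulate_baseline_freqs(cfg)
  base <- bind_geno(sample_genotypes(world$freqs[1, ], 100, group = "pop_01", seed = 1),
                    sample_genotypes(world$freqs[2, ], 100, group = "pop_02", seed = 2))
  freqs <- baseline_posterior_freqs(base)
  mix <- simulate_mixture(c(pop_01 = 1), 120, world$freqs, seed = 3)
  gc1 <- gsi_config(burn_in = 500, keep = 300, seed = 9)
  r1 <- gsi_gibbs(mix$genotypes, freqs, gc1)
  expect_gt(r1$pi_mean["pop_01"], 0.95)
  # invariants: rows sum to 1, trace rows sum to 1, means sum to 1
  expect_lt(max(abs(rowSums(r1$indiv_posterior) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(r1$pi_trace) - 1)), 1e-6)
  expect_equal(sum(r1$pi_mean), 1, tolerance = 1e-6)
  # identical trace under the same seed
  r2 <- gsi_gibbs(mix$genotypes, freqs, gc1)
  expect_identical(r1$pi_trace, r2$pi_trace)
  expect_identical(r1$origins, r2$origins)
})

test_that("posterior SD of proportions shrinks as the mixture grows", {
  cfg <- sim_config(n_cus = 2, pops_per_cu = 1, fst_between_cu = 0.1,
                    fst_within_cu = 0.001, n_loci = 100, seed = 35)
  world <- simulate_baseline_freqs(cfg)
  base <- bind_geno(sample_genotypes(world$freqs[1, ], 150, group = "pop_01", seed = 4),
                    sample_genotypes(world$freqs[2, ], 150, group = "pop_02", seed = 5))
  freqs <- baseline_posterior_freqs(base)
  sds <- vapply(c(50, 400), function(n) {
    sd_n <- numeric(3)
    for (s in 1:3) {
      mix <- simulate_mixture(c(pop_01 = 0.5, pop_02 = 0.5), n, world$freqs,
                              seed = 100 + s)
      r <- gsi_gibbs(mix$genotypes, freqs, gsi_config(500, 300, seed = s))
      sd_n[s] <- r$pi_sd["pop_01"]
    }
    mean(sd_n)
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})

test_that("rollup sums allocations within groups and preserves the total", {
  cfg <- sim_config(n_cus = 2, pops_per_cu = 2, n_loci = 80, seed = 37)
  world <- simulate_baseline_freqs(cfg)
  base <- do.call(bind_geno, lapply(rownames(world$freqs), function(p)
    sample_genotypes(world$freqs[p, ], 60, group = p)))
  freqs <- baseline_posterior_freqs(base)
  truth_cu <- c(CU_01 = 0.7, CU_02 = 0.3)
  mix <- simulate_mixture(c(pop_01 = 0.35, pop_02 = 0.35, pop_03 = 0.2,
                            pop_04 = 0.1), 300, world$freqs, seed = 6)
  r <- gsi_gibbs(mix$genotypes, freqs, gsi_config(1000, 500, seed = 8))
  cu <- rollup(r, world$registry, "cu")
  expect_equal(sum(cu$mean), 1, tolerance = 1e-6)
  # group means are the sums of member means
  for (g in cu$unit) {
    members <- world$registry$population[world$registry$cu == g]
    expect_equal(cu$mean[cu$unit == g], sum(r$pi_mean[members]), tolerance = 1e-9)
  }
  # two-group recovery within 2 posterior SD
  for (g in names(truth_cu)) {
    row <- cu[cu$unit == g, ]
    expect_lt(abs(row$mean - truth_cu[[g]]), 2 * row$sd + 0.02)
  }
  # degenerate partition: everything in one group
  reg1 <- world$registry; reg1$cu <- "ALL"
  all1 <- rollup(r, as_registry(reg1), "cu")
  expect_equal(all1$mean, 1, tolerance = 1e-9)
  expect_lt(all1$sd, 1e-9)
})

test_that("self-assignment behaves at its analytic limits and calibration bound", {
  # indistinguishable populations: chance-level accuracy ~ 1/K
  flat <- simulate_baseline_freqs(sim_config(n_loci = 40, n_cus = 4,
                                             pops_per_cu = 1,
                                             fst_between_cu = 1e-6,
                                             fst_within_cu = 1e-6, seed = 41))
  base <- do.call(bind_geno, lapply(rownames(flat$freqs), function(p)
    sample_genotypes(flat$freqs[p, ], 50, group = p)))
  sa <- self_assignment(base, cutoffs = 0)
  expect_lt(abs(sa$accuracy$accuracy - 0.25), 0.12)
  # fully diagnostic loci: 100%
  diag_f <- matrix(1e-3, 4, 8)
  for (k in 1:4) diag_f[k, (2 * k - 1):(2 * k)] <- 1 - 1e-3
  dimnames(diag_f) <- list(sprintf("pop_%02d", 1:4), sprintf("Loc_%03d", 1:8))
  base_d <- do.call(bind_geno, lapply(rownames(diag_f), function(p)
    sample_genotypes(diag_f[p, ], 30, group = p)))
  sad <- self_assignment(base_d, cutoffs = 0.5)
  expect_equal(sad$accuracy$accuracy, 1)
  # default synthetic world: weighted accuracy comfortably above the 0.8 floor
  set.seed(43)
  world <- simulate_baseline_freqs(sim_config(seed = 43))
  base2 <- do.call(bind_geno, lapply(rownames(world$freqs), function(p)
    sample_genotypes(world$freqs[p, ], 30, group = p)))
  sa2 <- self_assignment(base2, cutoffs = c(0.5, 0.85))
  expect_gt(sa2$accuracy$accuracy[1], 0.80)
  # the stricter cutoff retains fewer fish but never lowers accuracy much:
  expect_lte(sa2$accuracy$n_retained[2], sa2$accuracy$n_retained[1])
})
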