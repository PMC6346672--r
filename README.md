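# pbtgsi

Genetic assessment of mixed-stock Pacific salmon fisheries from biallelic
SNP panels. The package implements the two identification engines used in
modern coho/Chinook assessment programmes and the fishery estimators built
on top of them:

- **PBT (parentage-based tagging).** When an entire hatchery broodstock is
  genotyped, every offspring is genetically tagged: a fishery or escapement
  sample can be assigned to its hatchery, population and brood year by
  parentage. `assign_parentage()` scores each sampled fish against a pooled
  broodstock by pairwise likelihood with a genotype-class error model,
  shortlists candidate parents, enumerates same-population/same-brood-year
  parent pairs, and accepts the best hypothesis when its posterior
  probability over the enumerated hypothesis set reaches 0.85.
- **GSI (genetic stock identification).** Fish without sampled parents are
  assigned by a Bayesian conditional mixture model (`gsi_gibbs()`): with
  baseline allele frequencies fixed at their posterior means, a Gibbs
  sampler alternates sampling individual origins z_i ~ Categorical(pi_k ·
  P(g_i | k)) and mixture proportions pi ~ Dirichlet(alpha + counts),
  reporting posterior means and SDs from the retained iterations (default
  burn-in 25,000, last 1,000 kept).
- **PBT-first combination.** `route()` fixes accepted PBT fish to their
  population with probability 1 (single-parent assignments must also agree
  with the fish's GSI conservation-unit assignment) and carries everyone
  else by their GSI posterior; `combined_composition()` and `rollup()`
  produce stock composition with SDs at population, conservation-unit (CU)
  and region level.
- **Fishery estimators.** Catch-weighted seasonal subsampling, hatchery-
  origin catch = catch × clip rate, population catch = hatchery catch ×
  composition, coded-wire-tag (CWT) expansion through loss/marking/sampling
  rates, exploitation rate ER = catch / (catch + escapement), stray rates,
  and PBT-vs-CWT yield comparisons.

A hierarchical F-model simulator (`simulate_baseline_freqs()`,
`simulate_broodstock()`, `simulate_mixture()`, ...) generates baselines,
broodstocks, Mendelian offspring, fishery mixtures and CWT observations
with full ground truth; it is the package's validation harness.

## Worked example

Twenty populations in four CUs, 302 SNPs; broodstocks of the first four
populations fully genotyped (50 pairs each); a 400-fish mixture that is 90%
hatchery offspring and 10% from a population with no genotyped broodstock;
1% genotyping error, 2% missingness.

```r
library(pbtgsi)
cfg   <- sim_config(seed = 42)
world <- simulate_baseline_freqs(cfg)
pops  <- rownames(world$freqs)
baseline <- do.call(bind_geno, lapply(pops, function(p)
  sample_genotypes(world$freqs[p, ], 60, group = p)))
pool <- do.call(bind_pools, lapply(pops[1:4], function(p)
  simulate_broodstock(p, 50, 50, world$freqs[p, ])))
mix <- simulate_mixture(
  c(pop_01 = 0.35, pop_02 = 0.25, pop_03 = 0.2, pop_04 = 0.1, pop_09 = 0.1),
  n = 400, world$freqs, pool = pool,
  error_rate = 0.01, missing_rate = 0.02, seed = 43)

mixture <- qc_filter(mix$genotypes)$table          # drop fish > 120 missing loci
freqs   <- baseline_posterior_freqs(baseline)
par_res <- assign_parentage(mixture, pool, freqs)  # PBT engine
table(par_res$mode)
#> none pair
#>   37  363
gsi     <- gsi_gibbs(mixture, freqs, gsi_config(burn_in = 2500, keep = 500, seed = 44))
records <- route(par_res, gsi, world$registry)     # PBT first, GSI for the rest
table(records$method)
#> GSI PBT
#>  37 363
comp <- combined_composition(records, gsi)
head(comp[order(-comp$mean), ], 6)
#>     unit      level   mean sd
#> 1 pop_01 population 0.3325  0
#> 2 pop_02 population 0.2600  0
#> 3 pop_03 population 0.1950  0
#> 4 pop_04 population 0.1200  0
#> 9 pop_09 population 0.0925  0
#> 5 pop_05 population 0.0000  0
rollup(comp, world$registry, "cu")[1:2, ]
#>    unit level   mean sd
#> 1 CU_01    cu 0.9075  0
#> 2 CU_02    cu 0.0925  0
```

All 363 offspring of genotyped parents are pair-assigned (and, against the
recorded truth, to the correct parents); the 37 fish from the un-genotyped
population are routed to GSI, which places them in `pop_09` — the estimated
composition equals the realized make-up of the sample. The SDs are 0 here
because PBT fish enter as constants and the GSI posteriors are essentially
degenerate at this level of divergence; with weaker structure or smaller
panels the GSI share carries visible SDs.

Downstream arithmetic, e.g. a population with a catch of 1,365 and a
hatchery-origin escapement of 4,834:

```r
exploitation_rate(1365, 4834)
#> [1] 22
seasonal_subsample(c(jul = 60, aug = 20), c(jul = 200, aug = 150))
#> jul aug
#> 200  67
```

## Command line

```sh
Rscript inst/cli/pbtgsi.R simulate --config run.json --out data/
Rscript inst/cli/pbtgsi.R identify --config run.json --data data/ --out out/
Rscript inst/cli/pbtgsi.R estimate --fishery months.csv --er er.csv --out out/
```

Exit codes: 0 success, 2 validation error, 3 runtime error. Every stage
writes a manifest (seed, config, output checksums) sufficient to reproduce
its outputs byte-identically.

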