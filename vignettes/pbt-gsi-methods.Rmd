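---
title: "Models and methods: parentage-based tagging with genetic stock identification"
author: "pbtgsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, the numerical choices,
and known limitations. Nothing stated here as an empirical result goes
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## 1. Setting

Mixed-stock salmon fisheries intercept fish from many source populations at
once. Management needs to know *which* populations are being harvested, at
what rate, and how hatchery production contributes. Two genetic methods
answer this from a shared SNP panel (302 analytic biallelic loci by
default; species-ID and sex-ID assays are carried on panels but dropped
before analysis, see `drop_non_analytic()`):

* **PBT** identifies a fish to hatchery, population and brood year by
  matching it to its genotyped parents. It requires (near-)complete
  broodstock genotyping but then tags every offspring, with age information
  for free (offspring brood year = parents' spawning year).
* **GSI** estimates the composition of the whole sample, and each fish's
  origin posterior, from baseline allele frequencies. It needs no
  broodstock but cannot give brood year and has population-level resolution
  limited by divergence.

The package's pipeline runs PBT first, passes the remainder to GSI, and
combines the two into composition estimates and downstream fishery
quantities.

## 2. Genotype representation and QC

Genotypes are unphased biallelic calls, stored as the count (0/1/2) of the
locus's second allele; missing is `NA`. On disk the package reads and
writes the archival two-columns-per-locus dialect (`<locus>`, `<locus>_1`
allele codes; empty/0 = missing) with a leading metadata block
(`sample_type`, `repunit`, `collection`, `indiv`), so tables round-trip
losslessly (a property test asserts this on random tables).

QC follows the programme rule: individuals with **more than 120** missing
genotypes (of the 302 analytic loci) are excluded; exactly 120 is retained
("more than" is strict). The threshold is applied after dropping the
non-analytic loci — the published account does not say in which order the
two filters were applied; applying it to the analytic panel matches the
120-of-302 framing and is stated here as the package's choice.

## 3. Parentage engine

### Likelihood model

Per locus, observed genotypes follow a **genotype-class error model**: the
observed class equals the true class with probability $1-\varepsilon$ and
is each other class with probability $\varepsilon/2$ (default
$\varepsilon = 0.01$, the error rate used in the assessment programme;
repeat-genotyping discrepancy rates of about 1.07% motivate it). Missing
observations contribute likelihood 1.

Three per-locus hypotheses are defined for an offspring observation $o$:

* **pair**: $\Pr(o \mid \text{Mendel}(g_m, g_f))$ blended with the error
  model (`pair_locus_likelihood`),
* **single**: one allele transmitted by the observed parent, the other
  drawn from background allele frequencies
  (`single_parent_locus_likelihood`),
* **unrelated**: Hardy–Weinberg at the background frequencies
  (`unrelated_locus_likelihood`).

Parental genotypes are treated as true (error is applied to the offspring
observation only). This is a deliberate simplification of a fully symmetric
error model: it keeps the pairwise likelihood a closed form, and at
$\varepsilon = 1\%$ over 302 loci the benchmark still reaches 100% accuracy
(criterion tested, not asserted by fiat). Background frequencies are the
**pooled mean** across baseline populations, mirroring the programme's
practice of running the parent search on all broodstocks pooled "as a
single unit".

### Search and acceptance

For each offspring, `assign_parentage()`:

1. scores every candidate parent by its summed single-vs-unrelated
   log-likelihood ratio (computed for the whole sample at once as a sparse
   one-hot indicator product — the only place the package leans on the
   Matrix package);
2. shortlists the top `max_candidate_singles` (default 10) candidates —
   with 302 informative loci the true parents are at the top of this list
   whenever they are in the pool, and an $O(P^2)$ pair enumeration over
   thousands of parents is avoided;
3. enumerates all shortlisted pairs sharing population and brood year, of
   opposite sex where sex is known (polygamous mating: parents may appear
   in many pairs; a parent is never paired with itself);
4. computes the posterior of each hypothesis as its likelihood normalized
   over {all enumerated pairs, all shortlisted singles, unrelated}, i.e. a
   uniform prior over the hypothesis set with the unrelated hypothesis
   counted once (the published account does not define the assignment
   probability; this posterior is the package's stated replacement,
   validated behaviorally: 100% accuracy and > 91% assignment in the
   known-origin benchmark);
5. accepts the best hypothesis if its posterior reaches `accept_prob`
   (default 0.85). Exact likelihood ties are broken by **rejection** —
   unassigned fish fall through to GSI, so rejection is the conservative
   tie-break. Loci where one pair-parent is missing fall back to the
   single-parent term, both-missing to the unrelated term, so all
   hypotheses are compared over the same locus set.

Pair acceptance requires both parents from the same population (enforced by
construction of the pair set). Single-parent acceptance is *provisional*
here: the routing stage additionally requires the assigned population to
lie in the conservation unit the fish is assigned to by GSI (the CU with
maximum summed posterior — the published rule does not define "CU assigned
via GSI"; max-posterior is the natural individual-level reading and is the
package's documented choice).

Brood-year handling: the pool may contain several brood years; pairs must
share one, and the winning parent's brood year is the assigned age. Typical
use matches fishery adults against the brood year three years prior and
jacks two years prior, by constructing the pool accordingly.

## 4. GSI: conditional Gibbs sampler

Baseline allele frequencies per population are Beta posterior means,
$(\text{count} + 0.5) / (2 n_{called} + 1)$ — a Jeffreys-style half-count
per allele, the conventional default. The mixture model is **conditional**:
frequencies stay fixed during the chain (no parametric bootstrap), which
matches the cited software's default behavior and keeps the sampler simple;
the cost is slightly understated uncertainty when baseline samples are
small.

The chain alternates origins $z_i \sim \text{Cat}(\pi_k P(g_i \mid k))$ and
proportions $\pi \sim \text{Dir}(\alpha + n_k)$ with $\alpha_k = 1/K$.
Defaults are burn-in 25,000 and 1,000 retained iterations (the programme's
setting), unthinned — no thinning is stated in the source programme and
none is applied. Tests run reduced chains (2,500/500) where the design
permits; the small-instance correctness check compares the sampler against
exact enumeration of the marginal posterior on a 3-population, 4-locus toy
(total variation < 0.02).

Per-individual posteriors are Rao-Blackwellized (averages of the
conditional membership probabilities over retained iterations), so rows sum
to 1 exactly. Composition SDs are SDs over the retained trace. CU/region
numbers only ever arise by **summation over member populations within each
iteration** (`rollup()`); individuals are never assigned directly to CUs.

Self-assignment (`self_assignment()`) is leave-one-out: each baseline fish
is scored with its own alleles removed from its population's counts,
assigned to the max-posterior population under a flat prior, and optionally
excluded below a probability cutoff (0.50 / 0.85 are the conventional
reporting cutoffs). Note a deliberate non-goal of calibration: a
20-population synthetic baseline under the default divergence self-assigns
in the high 90s, above the mid-80s figures reported for real baselines
with hundreds of populations — a 20-population world simply has fewer
weakly-diverged neighbours. The test suite asserts the floor (≥ 80%) and
the analytic limits (chance level as divergence → 0; 100% with diagnostic
loci), not a real-baseline match.

## 5. Combination and composition

`route()` is exhaustive and exclusive: every QC-passing individual gets
exactly one method. PBT fish enter the composition as probability-1
one-hots, iteration-constant, so reported SDs reflect only GSI uncertainty
(a direct reading of the probability-1.00 rule; propagating parentage
uncertainty into composition SDs is a non-goal). Per retained iteration,

$$\hat c_k^{(t)} = \frac{\#\{\text{PBT fish assigned } k\} + \#\{i \in
\text{GSI}: z_i^{(t)} = k\}}{n},$$

and the reported composition is the mean and SD over $t$. Fish failing QC
are excluded from denominators entirely.

In evaluation, estimates are compared against the **realized** composition
of the sample in hand (the estimand), not the generating proportions —
otherwise shared multinomial noise of order $\sqrt{c(1-c)/n}$ dominates
both methods equally and masks the comparison.

## 6. Fishery estimators

All reported counts and percents use round-half-away-from-zero
(`round_half_up()`; base R's banker's rounding does not reproduce published
tables). Internally everything is kept at full precision.

* **Seasonal subsampling**: the reference month is the sampled month with
  the largest catch share (it anchors the worked rule "200 × (20%/60%) =
  67"); it contributes all its genotypes, other months
  $\min(\text{available}, \text{round}(n_r \cdot c_m / c_r))$.
* **Hatchery-origin catch** = total catch × observed adipose-clip rate;
  **population catch** = hatchery-origin catch × composition.
* **CWT expansion** = $\sum_{\text{tag codes}} \frac{\text{count}}
  {(1-\text{loss})\,\text{mark rate}} \big/ \text{sampling rate}$; it is
  the exact inverse of the expectation of the tagging simulator, and a
  1,000-replicate unbiasedness check runs in the acceptance suite.
* **Exploitation rate** = $100\,c/(c+e)$. One published methods sentence
  prints a minus sign in this denominator; the package defines ER with the
  plus sign, which is the only form consistent with every published rate it
  reproduces (e.g. 1,365/(1,365+4,834) → 22%).
* **Stray rate** = accepted escapement assignments whose assigned
  population differs from the sampling site, over all accepted.

## 7. The synthetic world

`sim_config()` states the world once:

| parameter | default | meaning |
|---|---|---|
| `n_loci` | 302 | analytic SNPs, independent (no linkage) |
| `n_cus`, `pops_per_cu` | 4 × 5 | 20 populations in 4 CUs |
| `fst_between_cu` | 0.08 | drift of CU frequencies about the ancestral |
| `fst_within_cu` | 0.03 | drift of population frequencies about their CU |
| `ancestral_freq_range` | (0.1, 0.9) | uniform ancestral frequencies |
| `genotype_error_rate` | 0.01 | genotype-class error |
| `missing_rate` | 0.02 | per-call missingness |

Frequencies follow a hierarchical F-model: Beta draws with mean $p$ and
"effective size" $(1-F)/F$ at each level, clamped to $[10^{-3},
1-10^{-3}]$ to avoid zero likelihoods downstream. A moment-estimator check
on 10,000 simulated loci recovers `fst_within_cu` to ±0.01. The F-model
was chosen over coalescent simulation because the analysis consumes only
allele-frequency divergence; 0.08/0.03 gives the strong-but-imperfect
structure that supports realistic self-assignment, and 2% missingness is a
representative panel-level figure (the published QC threshold tolerates far
more). Genotyping error is a genotype-class replacement (uniform over the
other two classes), matching the discrepancy framing of repeat-genotyping
studies, rather than an allele-level dropout model.

What a green test does **not** establish: the generator draws independent
loci (no linkage disequilibrium), unstructured missingness, no selection or
age structure, single-brood-year pools, and Hardy–Weinberg populations.
Real-world assignment rates below 100% (91.6–94.8% in known-origin
samples) arise from incomplete broodstock sampling and genotyping failure,
which the benchmark deliberately excludes — with complete, error-free
parent sampling the benchmark's ~100% assignment rate is the expected
behavior, and the published accuracy figure (100%) is the quantity the
acceptance target compares.

## 8. Pipeline and reproducibility

`run_simulate()` / `run_identify()` / `run_estimate()` (and the CLI wrapper
`inst/cli/pbtgsi.R`) move data as CSV in the dialects above. Run
configuration is **JSON** (jsonlite) rather than YAML: the target
environment guarantees jsonlite but not a YAML parser, and the functional
contract (file-based config, flag overrides) is unchanged. Every stage
writes a manifest with the seed, the config and MD5 checksums of outputs;
a rerun with the same config is byte-identical (tested).

All generators and the Gibbs sampler are deterministic given seeds; derived
seeds stay below $2^{31}$.

## 9. Known limitations

* Parental genotyping error is not modeled (offspring-only error); severe
  broodstock error rates would erode the advertised accuracy before the
  acceptance threshold catches it.
* No sibship or full-pedigree reconstruction: a fish whose parents were not
  sampled can only fall through to GSI, never be linked via siblings.
* The conditional GSI model understates uncertainty from finite baselines
  and applies no bias correction for unsampled populations.
* Composition SDs exclude parentage-assignment uncertainty by design.
* CWT expansion variance is not estimated (point expansion only).
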