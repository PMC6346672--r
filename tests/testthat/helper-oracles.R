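# Independent brute-force oracles. These enumerate outcomes directly from
# first principles (allele draws, Dirichlet-multinomial marginals) and never
# call the package's likelihood internals beyond the published error-model
# definition, so they can arbitrate the vectorized implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# alleles (counts of allele B) carried by a genotype class
.alleles_of <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))

.obs_prob <- function(obs, true, eps) {
  if (is.na(obs)) return(1)
  if (obs == true) 1 - eps else eps / 2
}

# P(observed offspring class | both parents), enumerating transmitted alleles
oracle_pair_locus <- function(go, gm, gf, eps) {
  am <- .alleles_of(gm); af <- .alleles_of(gf)
  tot <- 0
  for (x in am) for (y in af) tot <- tot + 0.25 * .obs_prob(go, x + y, eps)
  tot
}

# P(observed | unrelated), enumerating two allele draws at frequency p
oracle_unrelated_locus <- function(go, p, eps) {
  tot <- 0
  for (x in 0:1) for (y in 0:1) {
    w <- (if (x == 1) p else 1 - p) * (if (y == 1) p else 1 - p)
    tot <- tot + w * .obs_prob(go, x + y, eps)
  }
  tot
}

# P(observed | single parent + background allele)
oracle_single_locus <- function(go, gp, p, eps) {
  ap <- .alleles_of(gp)
  tot <- 0
  for (x in ap) for (y in 0:1) {
    w <- 0.5 * (if (y == 1) p else 1 - p)
    tot <- tot + w * .obs_prob(go, x + y, eps)
  }
  tot
}

# Exact marginal posterior mean of mixture proportions for a tiny instance:
# enumerate all K^n origin vectors, weight by Dirichlet-multinomial prior
# times genotype likelihoods, and average the conditional posterior mean of
# pi. `loglik` is an n x K matrix of log P(genotype_i | population k).
oracle_mixture_posterior_mean <- function(loglik, alpha) {
  n <- nrow(loglik); K <- ncol(loglik)
  A <- sum(alpha)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  logw <- numeric(nrow(grid))
  post <- matrix(0, nrow(grid), K)
  for (r in seq_len(nrow(grid))) {
    z <- grid[r, ]
    nk <- tabulate(z, K)
    logw[r] <- sum(loglik[cbind(seq_len(n), z)]) +
      sum(lgamma(alpha + nk) - lgamma(alpha)) + lgamma(A) - lgamma(A + n)
    post[r, ] <- (alpha + nk) / (A + n)
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  colSums(post * w)
}

# Weir & Cockerham-style moment estimator of Fst from a set of population
# allele frequencies (parametric frequencies, so no sample-size correction):
# ratio of among-population variance to p(1-p), averaged over loci.
oracle_fst_moment <- function(freq_mat) {
  pbar <- colMeans(freq_mat)
  s2 <- apply(freq_mat, 2, stats::var)
  mean(s2) / mean(pbar * (1 - pbar))
}
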