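#' GSI sampler configuration
#'
#' @param burn_in iterations discarded before retention (default 25,000, the
#'   reported analysis setting).
#' @param keep retained iterations used for posterior means and SDs
#'   (default 1,000 — the "last 1,000 iterations"; no thinning).
#' @param freq_prior Dirichlet pseudo-count per allele for baseline
#'   frequency posteriors (default 0.5).
#' @param proportion_prior Dirichlet parameter per population for the
#'   mixture proportions; default NULL means 1/K for K baseline populations.
#' @param seed RNG seed for the chain.
#' @return list of class \code{gsi_config}.
#' @export
gsi_config <- function(burn_in = 25000L, keep = 1000L, freq_prior = 0.5,
                       proportion_prior = NULL, seed = 1L) {
  stopifnot(burn_in >= 0, keep >= 1, freq_prior > 0)
  structure(list(burn_in = as.integer(burn_in), keep = as.integer(keep),
                 freq_prior = freq_prior, proportion_prior = proportion_prior,
                 seed = as.integer(seed)),
            class = "gsi_config")
}

#' Posterior-mean baseline allele frequencies
#'
#' Per population and locus, the Beta posterior mean
#' (count + prior) / (2 * n_called + 2 * prior) of the second allele's
#' frequency, with a symmetric per-allele pseudo-count.
#'
#' @param baseline a \code{\link{genotype_table}} whose group labels are
#'   populations.
#' @param prior per-allele pseudo-count (default 0.5).
#' @return populations x loci matrix of posterior mean frequencies.
#' @export
baseline_posterior_freqs <- function(baseline, prior = 0.5) {
  stopifnot(inherits(baseline, "geno_table"), prior > 0)
  pops <- unique(baseline$group)
  g <- baseline$geno
  out <- matrix(NA_real_, length(pops), ncol(g),
                dimnames = list(pops, colnames(g)))
  for (k in seq_along(pops)) {
    rows <- baseline$group == pops[k]
    if (!any(rows)) stop("population with zero individuals: ", pops[k], call. = FALSE)
    sub <- g[rows, , drop = FALSE]
    cnt <- colSums(sub, na.rm = TRUE)
    ncall <- colSums(!is.na(sub))
    out[k, ] <- (cnt + prior) / (2 * ncall + 2 * prior)
  }
  out
}

#' Log-likelihood of a genotype under Hardy-Weinberg at a given frequency
#'
#' @param g genotype code (0/1/2/NA), vectorized; missing contributes 0.
#' @param p frequency of the second allele (vectorized).
#' @return numeric vector of log-probabilities.
#' @export
locus_genotype_loglik <- function(g, p) {
  p <- rep_len(p, length(g))
  out <- ifelse(g == 0L, 2 * log1p(-p),
         ifelse(g == 1L, log(2) + log(p) + log1p(-p), 2 * log(p)))
  out[is.na(g)] <- 0
  out
}

# n x K matrix of per-individual log-likelihoods against each population
.genotype_loglik_matrix <- function(x, freqs) {
  g <- x$geno
  stopifnot(identical(colnames(g), colnames(freqs)))
  G0 <- (!is.na(g) & g == 0L) + 0
  G1 <- (!is.na(g) & g == 1L) + 0
  G2 <- (!is.na(g) & g == 2L) + 0
  lp0 <- 2 * log1p(-freqs)              # K x L
  lp1 <- log(2) + log(freqs) + log1p(-freqs)
  lp2 <- 2 * log(freqs)
  ll <- G0 %*% t(lp0) + G1 %*% t(lp1) + G2 %*% t(lp2)
  if (any(!is.finite(ll))) stop("non-finite genotype likelihoods", call. = FALSE)
  dimnames(ll) <- list(rownames(g), rownames(freqs))
  ll
}

#' Conditional Gibbs sampler for mixed-stock composition
#'
#' The conditional mixture model: baseline allele frequencies are fixed at
#' their posterior means, and the chain alternates (a) sampling each mixture
#' individual's origin from the categorical distribution proportional to
#' pi_k * P(genotype | population k), and (b) sampling the mixture
#' proportions pi from Dirichlet(prior + origin counts). After
#' \code{burn_in} iterations, \code{keep} iterations are retained; reported
#' are Rao-Blackwellized per-individual posterior means, and proportion
#' means and SDs over the retained trace.
#'
#' @param mixture a \code{\link{genotype_table}} of individuals to assign.
#' @param freqs populations x loci baseline frequency matrix (e.g. from
#'   \code{\link{baseline_posterior_freqs}}); at least 2 populations.
#' @param config a \code{\link{gsi_config}}.
#' @return object of class \code{gsi_result}: list with
#'   \code{indiv_posterior} (n x K, rows sum to 1), \code{pi_mean},
#'   \code{pi_sd}, \code{pi_trace} (keep x K), \code{origins} (keep x n
#'   integer matrix of sampled origin indices), \code{populations}.
#' @export
gsi_gibbs <- function(mixture, freqs, config = gsi_config()) {
  stopifnot(inherits(mixture, "geno_table"), nrow(mixture$geno) >= 1,
            nrow(freqs) >= 2)
  .set_seed_if(config$seed)
  K <- nrow(freqs); n <- nrow(mixture$geno)
  alpha <- config$proportion_prior %||% (1 / K)
  alpha <- rep_len(alpha, K)
  ll <- .genotype_loglik_matrix(mixture, freqs)
  lik <- exp(ll - apply(ll, 1, max))          # row-rescaled, constant factors cancel
  pi_k <- rep(1 / K, K)
  keep <- config$keep; burn <- config$burn_in
  pi_trace <- matrix(NA_real_, keep, K, dimnames = list(NULL, rownames(freqs)))
  origins <- matrix(NA_integer_, keep, n)
  post_acc <- matrix(0, n, K)
  for (it in seq_len(burn + keep)) {
    P <- lik * rep(pi_k, each = n)
    rs <- rowSums(P)
    u <- stats::runif(n) * rs
    cnt <- integer(n)
    acc <- P[, 1L]
    if (K > 1L) for (k in 1:(K - 1L)) {
      cnt <- cnt + (u > acc)
      acc <- acc + P[, k + 1L]
    }
    z <- cnt + 1L
    nk <- tabulate(z, K)
    gam <- stats::rgamma(K, alpha + nk)
    pi_k <- gam / sum(gam)
    if (it > burn) {
      t <- it - burn
      pi_trace[t, ] <- pi_k
      origins[t, ] <- z
      post_acc <- post_acc + P / rs
    }
  }
  indiv_posterior <- post_acc / keep
  dimnames(indiv_posterior) <- list(rownames(mixture$geno), rownames(freqs))
  structure(list(indiv_posterior = indiv_posterior,
                 pi_mean = colMeans(pi_trace),
                 pi_sd = apply(pi_trace, 2, stats::sd),
                 pi_trace = pi_trace, origins = origins,
                 populations = rownames(freqs), config = config),
            class = "gsi_result")
}

#' @export
print.gsi_result <- function(x, ...) {
  cat(sprintf("<gsi_result> %d individuals, %d populations, %d retained iterations\n",
              nrow(x$indiv_posterior), length(x$populations), nrow(x$pi_trace)))
  invisible(x)
}

#' Composition table constructor (internal representation)
#'
#' @param mean named mean composition vector.
#' @param sd named SD vector.
#' @param level aggregation level label.
#' @param trace optional iterations x units trace retained for roll-up.
#' @return data frame of class \code{composition} with columns \code{unit},
#'   \code{level}, \code{mean}, \code{sd}; the trace is kept as an attribute.
#' @export
composition_table <- function(mean, sd, level = "population", trace = NULL) {
  out <- data.frame(unit = names(mean), level = level,
                    mean = as.numeric(mean), sd = as.numeric(sd),
                    stringsAsFactors = FALSE)
  attr(out, "trace") <- trace
  class(out) <- c("composition", "data.frame")
  out
}

#' Roll population-level composition up to CU or region
#'
#' Summation of allocations over the populations belonging to each group:
#' group means are sums of member means; group SDs are computed by summing
#' within each retained iteration and taking the SD across iterations.
#'
#' @param x a \code{gsi_result} or a \code{composition} carrying a trace.
#' @param registry a population registry (population, cu, region, country).
#' @param level \code{"cu"} or \code{"region"}.
#' @return a \code{\link{composition_table}} at the requested level.
#' @export
rollup <- function(x, registry, level = c("cu", "region")) {
  level <- match.arg(level)
  if (inherits(x, "gsi_result")) {
    trace <- x$pi_trace
  } else if (inherits(x, "composition")) {
    trace <- attr(x, "trace")
    if (is.null(trace)) stop("composition carries no trace to roll up", call. = FALSE)
  } else stop("cannot roll up this object", call. = FALSE)
  grp <- registry[[level]][match(colnames(trace), registry$population)]
  if (anyNA(grp)) stop("populations missing from registry", call. = FALSE)
  groups <- unique(grp)
  gtr <- sapply(groups, function(g) rowSums(trace[, grp == g, drop = FALSE]))
  gtr <- matrix(gtr, nrow = nrow(trace), dimnames = list(NULL, groups))
  composition_table(colMeans(gtr), apply(gtr, 2, stats::sd), level, trace = gtr)
}

#' Leave-one-out self-assignment of a baseline
#'
#' Each baseline individual is scored against every population with its own
#' alleles removed from its population's counts, and assigned to the
#' maximum-posterior population (flat prior over populations). Individuals
#' whose maximum posterior falls below a cutoff are excluded; accuracy is
#' the fraction of retained individuals assigned to their true population
#' (so the overall figure is weighted by population sample size).
#'
#' @param baseline a \code{\link{genotype_table}} grouped by population.
#' @param prior per-allele pseudo-count (default 0.5).
#' @param cutoffs assignment-probability cutoffs (default c(0.5, 0.85)).
#' @return list with \code{assigned} (data frame: individual_id, true
#'   population, assigned population, max posterior) and \code{accuracy}
#'   (data frame: cutoff, n_retained, accuracy).
#' @export
self_assignment <- function(baseline, prior = 0.5, cutoffs = c(0.5, 0.85)) {
  g <- baseline$geno
  pops <- unique(baseline$group)
  cnt <- matrix(0, length(pops), ncol(g), dimnames = list(pops, colnames(g)))
  ncall <- cnt
  for (k in seq_along(pops)) {
    sub <- g[baseline$group == pops[k], , drop = FALSE]
    cnt[k, ] <- colSums(sub, na.rm = TRUE)
    ncall[k, ] <- colSums(!is.na(sub))
  }
  freqs <- (cnt + prior) / (2 * ncall + 2 * prior)
  freqs <- pmin(pmax(freqs, 1e-12), 1 - 1e-12)
  ll <- .genotype_loglik_matrix(baseline, freqs)
  n <- nrow(g)
  ki <- match(baseline$group, pops)
  for (i in seq_len(n)) {
    k <- ki[i]
    called <- !is.na(g[i, ])
    cnt_i <- cnt[k, ] - ifelse(called, g[i, ], 0)
    ncall_i <- ncall[k, ] - called
    p_i <- (cnt_i + prior) / (2 * ncall_i + 2 * prior)
    p_i <- pmin(pmax(p_i, 1e-12), 1 - 1e-12)
    ll[i, k] <- sum(locus_genotype_loglik(g[i, ], p_i))
  }
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  amax <- max.col(post, ties.method = "first")
  pmax_i <- post[cbind(seq_len(n), amax)]
  assigned <- data.frame(individual_id = rownames(g), population = baseline$group,
                         assigned = pops[amax], posterior = pmax_i,
                         stringsAsFactors = FALSE)
  accuracy <- do.call(rbind, lapply(cutoffs, function(ct) {
    keep <- pmax_i >= ct
    data.frame(cutoff = ct, n_retained = sum(keep),
               accuracy = mean(assigned$assigned[keep] == assigned$population[keep]))
  }))
  list(assigned = assigned, accuracy = accuracy)
}
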