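#' Parentage-assignment configuration
#'
#' @param error_rate assumed genotype-class error rate epsilon (default 0.01,
#'   the rate used for assignment in the source programme).
#' @param accept_prob posterior probability required to accept an assignment
#'   (default 0.85).
#' @param max_candidate_singles shortlist size: the number of top
#'   single-parent candidates per offspring from which parent pairs are
#'   enumerated (default 10).
#' @param allow_single_parent accept single-parent assignments (subject to
#'   the downstream GSI conservation-unit concordance check)?
#' @return list of class \code{parentage_config}.
#' @export
parentage_config <- function(error_rate = 0.01, accept_prob = 0.85,
                             max_candidate_singles = 10L,
                             allow_single_parent = TRUE) {
  stopifnot(error_rate >= 0, error_rate < 0.5,
            accept_prob > 0, accept_prob <= 1, max_candidate_singles >= 1)
  structure(list(error_rate = error_rate, accept_prob = accept_prob,
                 max_candidate_singles = as.integer(max_candidate_singles),
                 allow_single_parent = isTRUE(allow_single_parent)),
            class = "parentage_config")
}

#' Probability of an observed genotype class given the true class
#'
#' Genotype-class error model: the observed class equals the true class with
#' probability 1 - epsilon, and is each of the other two classes with
#' probability epsilon/2. A missing observation contributes probability 1
#' (the locus is skipped).
#'
#' @param observed,true integer genotype codes (0/1/2 copies of the second
#'   allele) or NA; vectorized.
#' @param error_rate epsilon.
#' @return numeric vector of probabilities.
#' @export
obs_given_true <- function(observed, true, error_rate) {
  out <- ifelse(observed == true, 1 - error_rate, error_rate / 2)
  out[is.na(observed)] <- 1
  out
}

# blend a true-class probability q of the observed class with the error model
.with_error <- function(q, eps) (1 - eps) * q + (eps / 2) * (1 - q)

# probability of each true offspring class (rows 0,1,2) given parent classes
.mendel_pair <- function(gm, gf) {
  m <- gm / 2; f <- gf / 2
  rbind((1 - m) * (1 - f), m * (1 - f) + (1 - m) * f, m * f)
}

#' Likelihood of an offspring genotype given a parent pair
#'
#' Mendelian transmission from the two (assumed-true) parental genotypes,
#' with the genotype-class error model applied to the offspring observation.
#' A missing offspring genotype yields 1; a missing parental genotype yields
#' NA (the caller must fall back to a single-parent or background model).
#'
#' @param go observed offspring genotype code (0/1/2/NA), vectorized.
#' @param gm,gf parental genotype codes.
#' @param error_rate epsilon.
#' @return numeric vector of probabilities.
#' @export
pair_locus_likelihood <- function(go, gm, gf, error_rate) {
  q <- .mendel_pair(gm, gf)           # 3 x n true-class probabilities
  qo <- q[cbind(go + 1L, seq_along(go))]
  out <- .with_error(qo, error_rate)
  out[is.na(go) & !is.na(gm) & !is.na(gf)] <- 1
  out
}

#' Likelihood of an offspring genotype under the unrelated (background) model
#'
#' Hardy-Weinberg class probabilities at the background allele frequency,
#' blended with the genotype-class error model.
#'
#' @param go observed offspring genotype code (0/1/2/NA), vectorized.
#' @param p background frequency of the second allele (vectorized).
#' @param error_rate epsilon.
#' @return numeric vector of probabilities.
#' @export
unrelated_locus_likelihood <- function(go, p, error_rate) {
  p <- rep_len(p, length(go))
  hwe <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)
  qo <- hwe[cbind(go + 1L, seq_along(go))]
  out <- .with_error(qo, error_rate)
  out[is.na(go)] <- 1
  out
}

#' Likelihood of an offspring genotype given one parent
#'
#' One allele is transmitted from the observed parent, the other is drawn
#' from the background allele frequency; the error model applies to the
#' offspring observation.
#'
#' @param go observed offspring genotype code (0/1/2/NA), vectorized.
#' @param gp single parent's genotype code.
#' @param p background frequency of the second allele.
#' @param error_rate epsilon.
#' @return numeric vector of probabilities.
#' @export
single_parent_locus_likelihood <- function(go, gp, p, error_rate) {
  p <- rep_len(p, length(go))
  m <- gp / 2
  q <- rbind((1 - m) * (1 - p), m * (1 - p) + (1 - m) * p, m * p)
  qo <- q[cbind(go + 1L, seq_along(go))]
  out <- .with_error(qo, error_rate)
  out[is.na(go) & !is.na(gp)] <- 1
  out
}

# Per-locus lookup tables used by assign_parentage.
# Returns list(logU = 3 x L log unrelated likelihoods,
#              A = 4 x 4 x L single-vs-unrelated log-likelihood ratios
#                  indexed [parent state, offspring state, locus],
#              logTpair = 3 x 3 x 3 log pair likelihoods [gm, gf, go])
# States 1..3 are genotype classes 0..2; state 4 is missing (ratio 0).
.parentage_tables <- function(p, eps) {
  L <- length(p)
  hwe <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)
  U <- .with_error(hwe, eps)
  logU <- log(U)
  A <- array(0, c(4L, 4L, L))
  for (g in 0:2) {
    m <- g / 2
    q <- rbind((1 - m) * (1 - p), m * (1 - p) + (1 - m) * p, m * p)
    S <- .with_error(q, eps)
    A[g + 1L, 1:3, ] <- log(S) - logU
  }
  Tpair <- array(0, c(3L, 3L, 3L))
  for (gm in 0:2) for (gf in 0:2) {
    q <- .mendel_pair(gm, gf)
    Tpair[gm + 1L, gf + 1L, ] <- .with_error(drop(q), eps)
  }
  list(logU = logU, A = A, logTpair = log(Tpair))
}

.empty_parentage <- function(ids) {
  n <- length(ids)
  data.frame(offspring_id = ids, mode = rep("none", n),
             parent1 = rep(NA_character_, n), parent2 = rep(NA_character_, n),
             population = rep(NA_character_, n),
             brood_year = rep(NA_integer_, n),
             posterior_prob = rep(NA_real_, n), n_loci = rep(0L, n),
             stringsAsFactors = FALSE)
}

#' Assign mixture individuals to broodstock parents
#'
#' Pairwise-likelihood parentage against a pooled broodstock: (1) every
#' candidate parent is scored by its single-parent log-likelihood ratio
#' against the unrelated hypothesis, summed over the offspring's called
#' loci; (2) the top \code{max_candidate_singles} candidates are shortlisted;
#' (3) all shortlisted pairs sharing population and brood year (and of
#' opposite sex where sex is known — polygamous mating, so parents are free
#' to appear in many pairs) are enumerated; (4) the posterior probability of
#' each hypothesis is its likelihood normalized over all enumerated pairs,
#' all shortlisted singles, and the unrelated hypothesis (uniform prior);
#' (5) the best hypothesis is accepted when its posterior reaches
#' \code{accept_prob}. Exact likelihood ties are broken by rejection.
#' Parental genotypes are treated as true; the error model applies to the
#' offspring observation. A locus missing in one parent of a pair falls back
#' to the single-parent likelihood, missing in both to the background.
#'
#' @param offspring a \code{\link{genotype_table}} of individuals to assign
#'   (QC-filtered).
#' @param pool a \code{\link{parent_pool}} on the same locus set, or NULL.
#' @param freqs background allele frequencies: either a per-locus vector or
#'   a populations x loci matrix (column means are used, mirroring the
#'   pooled single-unit analysis).
#' @param config a \code{\link{parentage_config}}.
#' @return data frame of class \code{parentage_result}: one row per
#'   offspring with \code{offspring_id}, \code{mode} (pair/single/none),
#'   \code{parent1}, \code{parent2}, \code{population}, \code{brood_year},
#'   \code{posterior_prob}, \code{n_loci}.
#' @export
assign_parentage <- function(offspring, pool, freqs,
                             config = parentage_config()) {
  stopifnot(inherits(offspring, "geno_table"))
  ids <- rownames(offspring$geno)
  loci_ids <- colnames(offspring$geno)
  if (is.null(pool) || nrow(pool$meta) == 0L) {
    res <- .empty_parentage(ids)
    res$n_loci <- as.integer(rowSums(!is.na(offspring$geno)))
    class(res) <- c("parentage_result", "data.frame")
    return(res)
  }
  stopifnot(inherits(pool, "parent_pool"),
            identical(colnames(pool$genotypes$geno), loci_ids))
  pbar <- if (is.matrix(freqs)) colMeans(freqs) else freqs
  if (!is.null(names(pbar))) {
    if (!all(loci_ids %in% names(pbar)))
      stop("freqs do not cover the offspring loci", call. = FALSE)
    pbar <- pbar[loci_ids]
  }
  stopifnot(length(pbar) == length(loci_ids))
  eps <- config$error_rate
  L <- length(loci_ids)
  I <- nrow(offspring$geno)
  J <- nrow(pool$meta)
  tb <- .parentage_tables(pbar, eps)

  Ostate <- offspring$geno + 1L; Ostate[is.na(Ostate)] <- 4L
  Pstate <- pool$genotypes$geno + 1L; Pstate[is.na(Pstate)] <- 4L

  # single-vs-unrelated log-likelihood-ratio matrix via sparse one-hot product
  W <- matrix(0, 4L * L, I)
  tO <- t(Ostate)                                   # L x I
  off_idx <- (seq_len(L) - 1L) * 4L + tO            # recycles down columns
  for (s in 1:3) {
    As <- as.vector(tb$A[s, , ])                    # 4 (off state) x L, flattened
    W[seq.int(s, 4L * L, by = 4L), ] <- matrix(As[as.vector(off_idx)], L, I)
  }
  Xpar <- Matrix::sparseMatrix(
    i = rep.int(seq_len(J), L),
    j = (rep(seq_len(L), each = J) - 1L) * 4L + as.vector(Pstate),
    x = 1, dims = c(J, 4L * L)
  )
  Sllr <- as.matrix(Xpar %*% W)                     # J x I

  meta <- pool$meta
  m_top <- min(config$max_candidate_singles, J)
  res <- .empty_parentage(ids)
  res$n_loci <- as.integer(rowSums(Ostate != 4L))
  res$posterior_prob <- 0

  for (i in seq_len(I)) {
    if (res$n_loci[i] == 0L) next
    o <- Ostate[i, ]
    cand <- order(Sllr[, i], decreasing = TRUE)[seq_len(m_top)]
    v_single <- Sllr[cand, i]
    # enumerate compatible pairs among shortlisted candidates
    hyp_ll <- c(v_single, 0)            # singles then unrelated
    hyp_kind <- c(rep("single", m_top), "none")
    hyp_a <- c(cand, NA); hyp_b <- rep(NA_integer_, m_top + 1L)
    if (m_top >= 2L) {
      for (ai in 1:(m_top - 1L)) for (bi in (ai + 1L):m_top) {
        a <- cand[ai]; b <- cand[bi]
        if (meta$population[a] != meta$population[b]) next
        if (meta$brood_year[a] != meta$brood_year[b]) next
        sa <- meta$sex[a]; sb <- meta$sex[b]
        if (sa == sb && sa %in% c("F", "M")) next
        pa <- Pstate[a, ]; pb <- Pstate[b, ]
        ok_o <- o != 4L
        both <- ok_o & pa != 4L & pb != 4L
        onlya <- ok_o & pa != 4L & pb == 4L
        onlyb <- ok_o & pa == 4L & pb != 4L
        ll <- 0
        if (any(both))
          ll <- ll + sum(tb$logTpair[cbind(pa[both], pb[both], o[both])]) -
                     sum(tb$logU[cbind(o[both], which(both))])
        if (any(onlya))
          ll <- ll + sum(tb$A[cbind(pa[onlya], o[onlya], which(onlya))])
        if (any(onlyb))
          ll <- ll + sum(tb$A[cbind(pb[onlyb], o[onlyb], which(onlyb))])
        hyp_ll <- c(hyp_ll, ll)
        hyp_kind <- c(hyp_kind, "pair")
        hyp_a <- c(hyp_a, a); hyp_b <- c(hyp_b, b)
      }
    }
    post <- exp(hyp_ll - max(hyp_ll))
    post <- post / sum(post)
    best <- which.max(hyp_ll)
    tied <- sum(hyp_ll > hyp_ll[best] - 1e-9) > 1L
    res$posterior_prob[i] <- post[best]
    kind <- hyp_kind[best]
    accept_pair <- !tied && kind == "pair" && post[best] >= config$accept_prob
    if (accept_pair) {
      a <- hyp_a[best]; b <- hyp_b[best]
      # dam first when sexes known
      if (meta$sex[b] == "F" && meta$sex[a] != "F") { tmp <- a; a <- b; b <- tmp }
      res$mode[i] <- "pair"
      res$parent1[i] <- meta$id[a]; res$parent2[i] <- meta$id[b]
      res$population[i] <- meta$population[a]
      res$brood_year[i] <- meta$brood_year[a]
    } else if (!tied && config$allow_single_parent) {
      sbest <- which.max(hyp_ll[seq_len(m_top)])
      if (hyp_kind[best] != "pair" && post[sbest] >= config$accept_prob) {
        a <- hyp_a[sbest]
        res$mode[i] <- "single"
        res$posterior_prob[i] <- post[sbest]
        res$parent1[i] <- meta$id[a]
        res$population[i] <- meta$population[a]
        res$brood_year[i] <- meta$brood_year[a]
      }
    }
  }
  class(res) <- c("parentage_result", "data.frame")
  res
}

#' Summarize parentage assignment against ground truth
#'
#' @param results a \code{parentage_result} data frame.
#' @param truth data frame with \code{individual_id}, \code{population},
#'   \code{brood_year} (NA population/brood year marks individuals without
#'   sampled parents; any accepted assignment for them counts as an error).
#' @return list with \code{n_genotyped}, \code{n_accepted},
#'   \code{assignment_rate}, \code{accuracy} (population and brood year
#'   jointly correct among accepted; NA when nothing accepted) and
#'   \code{by_population} (per true population: n, accepted, rate, accuracy).
#' @export
pbt_summary <- function(results, truth) {
  m <- merge(results, truth, by.x = "offspring_id", by.y = "individual_id",
             suffixes = c("", ".true"))
  acc_rows <- m$mode %in% c("pair", "single")
  correct <- acc_rows & !is.na(m$population.true) & !is.na(m$brood_year.true) &
    m$population == m$population.true & m$brood_year == m$brood_year.true
  by_pop <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$population.true), function(ix) {
    data.frame(population = m$population.true[ix][1],
               n = length(ix), accepted = sum(acc_rows[ix]),
               rate = mean(acc_rows[ix]),
               accuracy = if (any(acc_rows[ix]))
                 sum(correct[ix]) / sum(acc_rows[ix]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_pop) <- NULL
  list(n_genotyped = nrow(m), n_accepted = sum(acc_rows),
       assignment_rate = mean(acc_rows),
       accuracy = if (any(acc_rows)) sum(correct) / sum(acc_rows) else NA_real_,
       by_population = by_pop)
}
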