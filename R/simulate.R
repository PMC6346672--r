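#' Simulation configuration
#'
#' Parameters of the synthetic world used throughout testing and
#' benchmarking: a 302-SNP biallelic panel scored on populations grouped into
#' conservation units (CUs), with hierarchical allele-frequency divergence
#' (an F-model: Beta draws around CU frequencies, which are Beta draws around
#' a shared ancestral frequency), a 1\% genotype-class error rate and
#' per-call missingness.
#'
#' @param n_loci number of analytic SNP loci (default 302).
#' @param n_cus number of conservation units (default 4).
#' @param pops_per_cu populations per CU (default 5, giving 20 populations).
#' @param fst_between_cu drift parameter of CU frequencies around the
#'   ancestral frequency, in (0,1); default 0.08.
#' @param fst_within_cu drift parameter of population frequencies around
#'   their CU frequency, in (0,1); default 0.03.
#' @param ancestral_freq_range interval in (0,1) from which ancestral
#'   frequencies are drawn uniformly; default c(0.1, 0.9).
#' @param genotype_error_rate probability a called genotype is replaced by
#'   one of the other two genotype classes; default 0.01.
#' @param missing_rate probability a call is missing; default 0.02.
#' @param seed integer RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_loci = 302L, n_cus = 4L, pops_per_cu = 5L,
                       fst_between_cu = 0.08, fst_within_cu = 0.03,
                       ancestral_freq_range = c(0.1, 0.9),
                       genotype_error_rate = 0.01, missing_rate = 0.02,
                       seed = 1L) {
  .assert_fraction(fst_between_cu, "fst_between_cu", TRUE, TRUE)
  .assert_fraction(fst_within_cu, "fst_within_cu", TRUE, TRUE)
  .assert_fraction(genotype_error_rate, "genotype_error_rate")
  .assert_fraction(missing_rate, "missing_rate")
  stopifnot(length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2],
            n_loci >= 1, n_cus >= 1, pops_per_cu >= 1)
  structure(list(
    n_loci = as.integer(n_loci), n_cus = as.integer(n_cus),
    pops_per_cu = as.integer(pops_per_cu),
    fst_between_cu = fst_between_cu, fst_within_cu = fst_within_cu,
    ancestral_freq_range = ancestral_freq_range,
    genotype_error_rate = genotype_error_rate, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

.beta_around <- function(mean, fst) {
  # F-model: Beta with mean `mean` and "sample size" (1-F)/F
  nu <- (1 - fst) / fst
  stats::rbeta(length(mean), mean * nu, (1 - mean) * nu)
}

#' Simulate hierarchically diverged baseline allele frequencies
#'
#' Draws, for every locus, an ancestral frequency p0 ~ Uniform on
#' \code{ancestral_freq_range}; a CU frequency ~ Beta with mean p0 and drift
#' \code{fst_between_cu}; and a population frequency ~ Beta with mean the CU
#' frequency and drift \code{fst_within_cu}. Frequencies are clamped to
#' [1e-3, 1 - 1e-3] to avoid zero-likelihood pathologies downstream.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{freqs} (populations x loci matrix of frequencies
#'   of the second allele), \code{registry} (a population registry data
#'   frame) and \code{panel} (the matching \code{\link{locus_panel}}).
#' @export
simulate_baseline_freqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed_if(config$seed)
  L <- config$n_loci
  panel <- default_panel(L)
  p0 <- stats::runif(L, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  pops <- character(0)
  rows <- vector("list", config$n_cus * config$pops_per_cu)
  reg <- vector("list", length(rows))
  k <- 0L
  for (cu in seq_len(config$n_cus)) {
    p_cu <- .beta_around(p0, config$fst_between_cu)
    for (j in seq_len(config$pops_per_cu)) {
      k <- k + 1L
      rows[[k]] <- .beta_around(p_cu, config$fst_within_cu)
      pops[k] <- sprintf("pop_%02d", k)
      reg[[k]] <- data.frame(
        population = pops[k], cu = sprintf("CU_%02d", cu),
        region = sprintf("region_%d", ceiling(cu / 2)), country = "CA",
        stringsAsFactors = FALSE
      )
    }
  }
  freqs <- do.call(rbind, rows)
  freqs <- pmin(pmax(freqs, 1e-3), 1 - 1e-3)
  dimnames(freqs) <- list(pops, panel$locus_id)
  list(freqs = freqs, registry = as_registry(do.call(rbind, reg)), panel = panel)
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Independent binomial(2, p) draws per locus.
#'
#' @param freqs numeric vector of per-locus frequencies of the second allele
#'   (names become locus ids).
#' @param n number of individuals.
#' @param seed optional RNG seed.
#' @param ids optional individual ids (default generated from \code{group}).
#' @param group group label for the table.
#' @return a \code{\link{genotype_table}}.
#' @export
sample_genotypes <- function(freqs, n, seed = NULL, ids = NULL, group = "pop") {
  stopifnot(all(freqs > 0 & freqs < 1), n >= 0)
  .set_seed_if(seed)
  L <- length(freqs)
  geno <- matrix(stats::rbinom(n * L, 2L, rep(freqs, each = n)), nrow = n, ncol = L)
  rownames(geno) <- ids %||% sprintf("%s_%04d", group, seq_len(n))
  colnames(geno) <- names(freqs) %||% sprintf("Loc_%03d", seq_len(L))
  genotype_table(geno, group)
}

#' Parent pool (broodstock reference)
#'
#' Bundles broodstock genotypes with their population, brood-year and sex
#' labels; the reference against which parentage assignment runs.
#'
#' @param genotypes a \code{\link{genotype_table}} of broodstock.
#' @param meta data frame with columns \code{id}, \code{population},
#'   \code{brood_year}, \code{sex} (\code{"F"}, \code{"M"} or
#'   \code{"unknown"}), one row per individual of \code{genotypes}.
#' @return object of class \code{parent_pool}.
#' @export
parent_pool <- function(genotypes, meta) {
  stopifnot(inherits(genotypes, "geno_table"),
            all(c("id", "population", "brood_year", "sex") %in% names(meta)),
            nrow(meta) == nrow(genotypes$geno))
  if (!all(meta$id == rownames(genotypes$geno)))
    stop("meta ids must match genotype rownames in order", call. = FALSE)
  if (!all(meta$sex %in% c("F", "M", "unknown")))
    stop("sex must be F, M or unknown", call. = FALSE)
  structure(list(genotypes = genotypes, meta = meta), class = "parent_pool")
}

#' Combine parent pools
#' @param ... \code{parent_pool} objects on the same locus set.
#' @return a pooled \code{parent_pool} (the "single unit" used in analysis).
#' @export
bind_pools <- function(...) {
  ps <- list(...)
  parent_pool(do.call(bind_geno, lapply(ps, `[[`, "genotypes")),
              do.call(rbind, lapply(ps, `[[`, "meta")))
}

#' @export
print.parent_pool <- function(x, ...) {
  cat(sprintf("<parent_pool> %d parents, %d populations, brood years %s\n",
              nrow(x$meta), length(unique(x$meta$population)),
              paste(sort(unique(x$meta$brood_year)), collapse = "/")))
  invisible(x)
}

#' Simulate a hatchery broodstock
#'
#' Hardy-Weinberg draws from one population's frequencies, labelled with sex
#' and brood year: the complete-broodstock-genotyping scenario that makes
#' all offspring genetically tagged.
#'
#' @param population population name.
#' @param n_females,n_males numbers of dams and sires.
#' @param freqs per-locus allele frequencies for the population.
#' @param brood_year brood year label (default 2014).
#' @param seed optional RNG seed.
#' @param label id prefix (default the population name); lets several pools
#'   from the same population coexist without id collisions.
#' @return a \code{\link{parent_pool}}.
#' @export
simulate_broodstock <- function(population, n_females, n_males, freqs,
                                brood_year = 2014L, seed = NULL,
                                label = population) {
  .set_seed_if(seed)
  ids <- c(sprintf("%s_%d_F%03d", label, brood_year, seq_len(n_females)),
           sprintf("%s_%d_M%03d", label, brood_year, seq_len(n_males)))
  gt <- sample_genotypes(freqs, n_females + n_males, ids = ids, group = population)
  meta <- data.frame(id = ids, population = population,
                     brood_year = as.integer(brood_year),
                     sex = c(rep("F", n_females), rep("M", n_males)),
                     stringsAsFactors = FALSE)
  parent_pool(gt, meta)
}

#' Simulate offspring of genotyped parent pairs
#'
#' Mendelian transmission: at each locus each offspring receives one allele
#' drawn uniformly from each parent's two alleles, independently across loci.
#' A locus missing in either parent is missing in the offspring.
#'
#' @param pool a \code{\link{parent_pool}} containing the parents.
#' @param pairs data frame with columns \code{mother_id}, \code{father_id}.
#' @param n_per_pair offspring per pair (recycled).
#' @param seed optional RNG seed.
#' @param group group label for the offspring table.
#' @return list with \code{genotypes} (a \code{geno_table}) and \code{truth}
#'   (data frame: individual_id, population, brood_year, mother_id,
#'   father_id).
#' @export
simulate_offspring <- function(pool, pairs, n_per_pair = 1L, seed = NULL,
                               group = "offspring") {
  stopifnot(inherits(pool, "parent_pool"))
  .set_seed_if(seed)
  n_per_pair <- rep_len(as.integer(n_per_pair), nrow(pairs))
  midx <- match(pairs$mother_id, pool$meta$id)
  fidx <- match(pairs$father_id, pool$meta$id)
  if (anyNA(midx) || anyNA(fidx)) stop("pair parents not found in pool", call. = FALSE)
  rep_pair <- rep.int(seq_len(nrow(pairs)), n_per_pair)
  gm <- pool$genotypes$geno[midx[rep_pair], , drop = FALSE]
  gf <- pool$genotypes$geno[fidx[rep_pair], , drop = FALSE]
  n <- nrow(gm); L <- ncol(gm)
  # rbinom warns on NA probabilities; NA propagation (missing parent locus ->
  # missing offspring locus) is exactly what we want
  am <- matrix(suppressWarnings(stats::rbinom(n * L, 1L, gm / 2)), n, L)
  af <- matrix(suppressWarnings(stats::rbinom(n * L, 1L, gf / 2)), n, L)
  geno <- am + af
  rownames(geno) <- sprintf("%s_%05d", group, seq_len(n))
  colnames(geno) <- colnames(pool$genotypes$geno)
  truth <- data.frame(
    individual_id = rownames(geno),
    population = pool$meta$population[midx[rep_pair]],
    brood_year = pool$meta$brood_year[midx[rep_pair]],
    mother_id = pairs$mother_id[rep_pair],
    father_id = pairs$father_id[rep_pair],
    stringsAsFactors = FALSE
  )
  list(genotypes = genotype_table(geno, group), truth = truth)
}

#' Apply genotyping error and missingness
#'
#' Per call, with probability \code{missing_rate} the genotype is set
#' missing; otherwise with probability \code{error_rate} it is replaced by
#' one of the other two genotype classes, uniformly (a genotype-class error
#' model matching the discrepancy framing of repeat-genotyping studies).
#'
#' @param x a \code{\link{genotype_table}}.
#' @param error_rate genotype-class error probability.
#' @param missing_rate missingness probability.
#' @param seed optional RNG seed.
#' @return a corrupted \code{geno_table}.
#' @export
corrupt <- function(x, error_rate, missing_rate = 0, seed = NULL) {
  .assert_fraction(error_rate, "error_rate")
  .assert_fraction(missing_rate, "missing_rate")
  .set_seed_if(seed)
  g <- x$geno
  n <- length(g)
  drop <- stats::runif(n) < missing_rate
  err <- !drop & (stats::runif(n) < error_rate)
  shift <- matrix(0L, nrow(g), ncol(g))
  shift[err] <- sample(1:2, sum(err), replace = TRUE)
  g <- (g + shift) %% 3L
  g[drop] <- NA_integer_
  genotype_table(matrix(g, nrow(x$geno), dimnames = dimnames(x$geno)), x$group)
}

#' Simulate a mixed-stock fishery sample
#'
#' Draws individual origins from a stated composition; origins with a
#' genotyped broodstock produce Mendelian offspring of randomly chosen
#' (polygamous) parent pairs from the pool, other origins are fresh
#' Hardy-Weinberg draws from the population's baseline frequencies.
#' Genotyping error/missingness is applied afterwards. Ground truth (origin,
#' parents, clip status) is recorded for every individual.
#'
#' @param composition named numeric vector of population proportions
#'   (must sum to 1 within 1e-9).
#' @param n sample size.
#' @param freqs populations x loci frequency matrix covering all composition
#'   populations.
#' @param pool optional \code{\link{parent_pool}}; populations present in the
#'   pool with at least one dam and one sire are PBT-able.
#' @param error_rate,missing_rate corruption rates applied to the sample.
#' @param clipped logical clip flag recorded in truth (recycled).
#' @param seed optional RNG seed.
#' @param group group label of the resulting table.
#' @return list with \code{genotypes} and \code{truth} (individual_id,
#'   population, brood_year, mother_id, father_id, clipped).
#' @export
simulate_mixture <- function(composition, n, freqs, pool = NULL,
                             error_rate = 0, missing_rate = 0,
                             clipped = TRUE, seed = NULL, group = "mixture") {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1", call. = FALSE)
  if (!all(names(composition) %in% rownames(freqs)))
    stop("composition populations missing from freqs", call. = FALSE)
  .set_seed_if(seed)
  origins <- sample(names(composition), n, replace = TRUE, prob = composition)
  L <- ncol(freqs)
  geno <- matrix(NA_integer_, n, L, dimnames = list(sprintf("%s_%05d", group, seq_len(n)),
                                                    colnames(freqs)))
  truth <- data.frame(individual_id = rownames(geno), population = origins,
                      brood_year = NA_integer_, mother_id = NA_character_,
                      father_id = NA_character_,
                      clipped = rep_len(clipped, n), stringsAsFactors = FALSE)
  pbt_pops <- character(0)
  if (!is.null(pool)) {
    nf <- tapply(pool$meta$sex == "F", pool$meta$population, sum)
    nm <- tapply(pool$meta$sex == "M", pool$meta$population, sum)
    pbt_pops <- names(nf)[nf > 0 & nm > 0]
  }
  for (pop in unique(origins)) {
    idx <- which(origins == pop)
    if (pop %in% pbt_pops) {
      dams <- pool$meta$id[pool$meta$population == pop & pool$meta$sex == "F"]
      sires <- pool$meta$id[pool$meta$population == pop & pool$meta$sex == "M"]
      pairs <- data.frame(mother_id = sample(dams, length(idx), replace = TRUE),
                          father_id = sample(sires, length(idx), replace = TRUE),
                          stringsAsFactors = FALSE)
      off <- simulate_offspring(pool, pairs, 1L, seed = NULL, group = pop)
      geno[idx, ] <- off$genotypes$geno
      truth$brood_year[idx] <- off$truth$brood_year
      truth$mother_id[idx] <- off$truth$mother_id
      truth$father_id[idx] <- off$truth$father_id
    } else {
      geno[idx, ] <- sample_genotypes(freqs[pop, ], length(idx), group = pop)$geno
    }
  }
  gt <- genotype_table(geno, group)
  if (error_rate > 0 || missing_rate > 0)
    gt <- corrupt(gt, error_rate, missing_rate)
  list(genotypes = gt, truth = truth)
}

#' Simulate coded-wire-tag recovery in a fishery
#'
#' The observed tag count is Binomial(true_catch, mark_rate * (1 -
#' tag_loss_rate) * sampling_rate): each caught fish of the population
#' carries a readable tag with the marking rate net of "no-pin" loss, and is
#' inspected with the fishery's sampling rate. \code{release_size} is carried
#' for bookkeeping only; recovery depends on the realized catch.
#'
#' @param true_catch true catch of the population in the fishery.
#' @param mark_rate fraction of the release tagged.
#' @param tag_loss_rate no-pin tag loss fraction.
#' @param sampling_rate fishery sampling fraction.
#' @param release_size optional release size (unused in the draw).
#' @param seed optional RNG seed.
#' @return integer observed tag count.
#' @export
simulate_cwt_program <- function(true_catch, mark_rate, tag_loss_rate,
                                 sampling_rate, release_size = NULL, seed = NULL) {
  .assert_fraction(mark_rate, "mark_rate")
  .assert_fraction(tag_loss_rate, "tag_loss_rate")
  .assert_fraction(sampling_rate, "sampling_rate")
  .set_seed_if(seed)
  stats::rbinom(1L, as.integer(true_catch),
                mark_rate * (1 - tag_loss_rate) * sampling_rate)
}
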