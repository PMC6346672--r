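#' Route individuals between PBT and GSI
#'
#' The PBT-first rule: accepted parent-pair assignments (posterior at or
#' above the acceptance threshold, both parents from the same population —
#' enforced at assignment) are fixed to their population with probability 1.
#' Accepted single-parent assignments are additionally required to lie
#' inside the conservation unit the individual is assigned to by GSI (the CU
#' with maximum summed posterior); otherwise, and for everyone else, the
#' individual is carried by its GSI posterior.
#'
#' @param parentage a \code{parentage_result} data frame covering the
#'   mixture.
#' @param gsi a \code{gsi_result} covering the same individuals.
#' @param registry population registry mapping populations to CUs.
#' @param config a \code{\link{parentage_config}} (supplies the acceptance
#'   threshold and the single-parent switch).
#' @return data frame of class \code{assignment_record}: one row per
#'   individual with \code{individual_id}, \code{method} ("PBT"/"GSI"),
#'   \code{population}, \code{brood_year} (PBT rows only).
#' @export
route <- function(parentage, gsi, registry, config = parentage_config()) {
  stopifnot(inherits(gsi, "gsi_result"))
  ids <- parentage$offspring_id
  if (!all(ids %in% rownames(gsi$indiv_posterior)))
    stop("every individual needs a GSI posterior", call. = FALSE)
  pbt_pops <- unique(parentage$population[!is.na(parentage$population)])
  if (length(bad <- setdiff(pbt_pops, registry$population)))
    stop("PBT population absent from registry: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cu_of <- registry$cu[match(gsi$populations, registry$population)]
  cus <- unique(cu_of)
  cu_post <- sapply(cus, function(cu)
    rowSums(gsi$indiv_posterior[, cu_of == cu, drop = FALSE]))
  cu_post <- matrix(cu_post, nrow = nrow(gsi$indiv_posterior),
                    dimnames = list(rownames(gsi$indiv_posterior), cus))
  gsi_cu <- cus[max.col(cu_post, ties.method = "first")]
  names(gsi_cu) <- rownames(gsi$indiv_posterior)

  method <- rep("GSI", length(ids))
  ok_pair <- parentage$mode == "pair" &
    parentage$posterior_prob >= config$accept_prob
  method[ok_pair] <- "PBT"
  if (config$allow_single_parent) {
    pop_cu <- registry$cu[match(parentage$population, registry$population)]
    ok_single <- parentage$mode == "single" &
      parentage$posterior_prob >= config$accept_prob &
      !is.na(pop_cu) & pop_cu == gsi_cu[ids]
    method[ok_single] <- "PBT"
  }
  out <- data.frame(individual_id = ids, method = method,
                    population = ifelse(method == "PBT", parentage$population,
                                        NA_character_),
                    brood_year = ifelse(method == "PBT", parentage$brood_year,
                                        NA_integer_),
                    stringsAsFactors = FALSE)
  class(out) <- c("assignment_record", "data.frame")
  out
}

#' Combined PBT + GSI stock composition
#'
#' Per retained GSI iteration, the composition is (PBT one-hot counts + the
#' GSI-routed individuals' sampled origins) / n; means and SDs are taken
#' over iterations. PBT individuals enter as iteration constants, so SDs
#' reflect only GSI uncertainty, and a sample that is 100\% PBT-assigned to
#' one population has SD 0.
#'
#' @param records an \code{assignment_record} data frame (from
#'   \code{\link{route}}).
#' @param gsi the \code{gsi_result} used in routing.
#' @param registry optional registry (unused at population level, accepted
#'   for symmetry with \code{\link{rollup}}).
#' @return a \code{\link{composition_table}} at population level carrying
#'   its iteration trace (so it can be rolled up to CU/region).
#' @export
combined_composition <- function(records, gsi, registry = NULL) {
  pops <- gsi$populations
  n <- nrow(records)
  pbt <- records$method == "PBT"
  pbt_counts <- tabulate(match(records$population[pbt], pops), length(pops))
  gsi_ids <- records$individual_id[!pbt]
  idx <- match(gsi_ids, rownames(gsi$indiv_posterior))
  keep <- nrow(gsi$pi_trace)
  trace <- matrix(0, keep, length(pops), dimnames = list(NULL, pops))
  for (t in seq_len(keep)) {
    cnts <- pbt_counts
    if (length(idx))
      cnts <- cnts + tabulate(gsi$origins[t, idx], length(pops))
    trace[t, ] <- cnts / n
  }
  composition_table(colMeans(trace), apply(trace, 2, stats::sd),
                    "population", trace = trace)
}

#' Mean absolute composition error
#'
#' @param estimate named numeric vector (or \code{composition} table) of
#'   estimated proportions.
#' @param truth named numeric vector of true proportions; units are aligned
#'   by name, missing units count as zero.
#' @param units optional unit subset over which to average.
#' @return mean absolute error (same scale as the inputs).
#' @export
composition_error <- function(estimate, truth, units = NULL) {
  if (inherits(estimate, "composition"))
    estimate <- stats::setNames(estimate$mean, estimate$unit)
  units <- units %||% union(names(estimate), names(truth))
  e <- ifelse(units %in% names(estimate), estimate[units], 0)
  t <- ifelse(units %in% names(truth), truth[units], 0)
  mean(abs(e - t))
}
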