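#' Catch-weighted seasonal subsampling of monthly genotypes
#'
#' Builds a seasonal sample whose monthly make-up mirrors the monthly catch:
#' the reference month is the sampled month with the largest catch share and
#' contributes all of its available genotypes; every other month m
#' contributes min(available_m, round(n_ref * catch_m / catch_ref))
#' genotypes. With 60\% of the catch in the reference month (200 genotypes)
#' and 20\% in another, the other month contributes 200 * (20/60) = 67.
#'
#' @param monthly_catch named numeric vector of catches (any common scale:
#'   counts or percentages).
#' @param monthly_available named integer vector of available genotypes per
#'   month (months absent or zero are unsampled).
#' @return named integer vector: genotypes to draw per sampled month.
#' @export
seasonal_subsample <- function(monthly_catch, monthly_available) {
  months <- names(monthly_available)[monthly_available > 0]
  if (!length(months)) stop("no month has available genotypes", call. = FALSE)
  if (!all(months %in% names(monthly_catch)))
    stop("catch missing for sampled month(s)", call. = FALSE)
  catch <- monthly_catch[months]
  r <- months[which.max(catch)]
  if (monthly_catch[r] <= 0) stop("zero catch in reference month", call. = FALSE)
  n_r <- monthly_available[r]
  out <- pmin(monthly_available[months],
              round_half_up(n_r * monthly_catch[months] / monthly_catch[r]))
  out[r] <- n_r
  stats::setNames(as.integer(out), months)
}

#' Hatchery-origin catch from the observed clip rate
#'
#' (total catch) x (observed adipose fin clip rate in the catch), rounded.
#'
#' @param total_catch total catch count.
#' @param clip_rate clip fraction in [0, 1].
#' @return integer count.
#' @export
hatchery_origin_catch <- function(total_catch, clip_rate) {
  .assert_fraction(clip_rate, "clip_rate")
  as.integer(round_half_up(total_catch * clip_rate))
}

#' Population-specific catch from stock composition
#'
#' (hatchery-origin catch) x (population-specific composition), rounded
#' per population.
#'
#' @param hatchery_catch hatchery-origin catch count.
#' @param composition named proportion vector (or \code{composition} table).
#' @return named integer vector of per-population catches.
#' @export
population_catch <- function(hatchery_catch, composition) {
  if (inherits(composition, "composition"))
    composition <- stats::setNames(composition$mean, composition$unit)
  stats::setNames(as.integer(round_half_up(hatchery_catch * composition)),
                  names(composition))
}

#' Expand observed coded-wire tags to estimated catch
#'
#' Observed tag counts (per tag code) are corrected for no-pin tag loss,
#' expanded by the tag-specific marking rate, summed over tag codes, and
#' expanded again by the fishery sampling rate.
#'
#' @param observed observed tag counts (vector over tag codes).
#' @param no_pin_loss_rate tag loss fraction (recycled over tag codes).
#' @param mark_rate marking rate per tag code (recycled), must be > 0.
#' @param sampling_rate fishery sampling fraction, must be > 0.
#' @return estimated catch (numeric, unrounded).
#' @export
cwt_expand <- function(observed, no_pin_loss_rate, mark_rate, sampling_rate) {
  if (any(mark_rate <= 0) || any(sampling_rate <= 0))
    stop("mark_rate and sampling_rate must be positive", call. = FALSE)
  .assert_fraction(no_pin_loss_rate, "no_pin_loss_rate", open_right = TRUE)
  sum(observed / (1 - no_pin_loss_rate) / mark_rate) / sampling_rate
}

#' Hatchery component of an escapement
#'
#' (estimated escapement) x (proportion adipose fin-clipped in the
#' escapement), rounded.
#'
#' @param total_escapement total escapement count.
#' @param clip_proportion clipped fraction in [0, 1].
#' @return integer count.
#' @export
hatchery_escapement <- function(total_escapement, clip_proportion) {
  .assert_fraction(clip_proportion, "clip_proportion")
  as.integer(round_half_up(total_escapement * clip_proportion))
}

#' Exploitation rate
#'
#' 100 * catch / (catch + escapement), rounded to the integer percent used
#' in reporting.
#'
#' @param catch adult catch of the population.
#' @param escapement hatchery-origin escapement of the population.
#' @return integer percent in [0, 100].
#' @export
exploitation_rate <- function(catch, escapement) {
  if (any(catch + escapement <= 0)) stop("catch + escapement must be > 0", call. = FALSE)
  as.integer(round_half_up(100 * catch / (catch + escapement)))
}

#' Stray rate from escapement parentage assignments
#'
#' A stray is an accepted PBT assignment whose assigned population differs
#' from the population where the fish was sampled.
#'
#' @param results a \code{parentage_result} data frame for escapement
#'   samples.
#' @param sampled_population character vector: population of the sampling
#'   site for each row of \code{results}.
#' @return list with \code{n_accepted}, \code{n_strays}, \code{rate}
#'   (fraction) and \code{pairs} (per assigned->sampled stray counts).
#' @export
stray_rate <- function(results, sampled_population) {
  stopifnot(nrow(results) == length(sampled_population))
  acc <- results$mode %in% c("pair", "single")
  stray <- acc & results$population != sampled_population
  pairs <- if (any(stray)) {
    as.data.frame(table(from = results$population[stray],
                        to = sampled_population[stray]),
                  stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0), Freq = integer(0))
  list(n_accepted = sum(acc), n_strays = sum(stray),
       rate = if (any(acc)) sum(stray) / sum(acc) else NA_real_,
       pairs = pairs[pairs$Freq > 0, , drop = FALSE])
}

#' Compare identification yield of PBT and CWTs
#'
#' Tabulates, from per-population counts, the information yield of
#' genotyping relative to tag recovery: tags observed/submitted/genotyped,
#' PBT identifications with and without a tag, and the published-style
#' ratios — percent genotyped, percent of genotyped fish PBT-assigned, the
#' excess of PBT identifications over tags for tagged populations
#' (100 * (pbt_tagged - submitted) / submitted), and the all-population
#' yield ratio (100 * pbt_total / submitted).
#'
#' @param counts data frame with columns \code{population},
#'   \code{cwt_observed}, \code{cwt_submitted}, \code{cwt_genotyped},
#'   \code{pbt_with_cwt}, \code{pbt_no_cwt}, and logical \code{tagged}
#'   (whether the population is CWT-marked).
#' @return list with \code{table} (the input plus per-population totals),
#'   \code{totals}, \code{pct_genotyped}, \code{pct_pbt_of_genotyped},
#'   \code{pct_more_tagged}, \code{pct_ratio_all}.
#' @export
pbt_vs_cwt_comparison <- function(counts) {
  need <- c("population", "cwt_observed", "cwt_submitted", "cwt_genotyped",
            "pbt_with_cwt", "pbt_no_cwt", "tagged")
  stopifnot(all(need %in% names(counts)))
  counts$pbt_total <- counts$pbt_with_cwt + counts$pbt_no_cwt
  tot <- colSums(counts[c("cwt_observed", "cwt_submitted", "cwt_genotyped",
                          "pbt_with_cwt", "pbt_no_cwt", "pbt_total")])
  pbt_tagged <- sum(counts$pbt_total[counts$tagged])
  submitted <- tot[["cwt_submitted"]]
  list(
    table = counts,
    totals = tot,
    pct_genotyped = 100 * tot[["cwt_genotyped"]] / submitted,
    pct_pbt_of_genotyped = 100 * tot[["pbt_with_cwt"]] / tot[["cwt_genotyped"]],
    pct_more_tagged = 100 * (pbt_tagged - submitted) / submitted,
    pct_ratio_all = 100 * tot[["pbt_total"]] / submitted
  )
}

#' Tagging cost per identified individual
#'
#' @param total_cost programme tagging/genotyping cost in dollars.
#' @param n_identified number of individuals identified in fishery samples.
#' @return integer dollars per identification (rounded).
#' @export
cost_per_identification <- function(total_cost, n_identified) {
  stopifnot(n_identified > 0)
  as.integer(round_half_up(total_cost / n_identified))
}
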