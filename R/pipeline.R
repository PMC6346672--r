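#' Read a pipeline run configuration
#'
#' Run configuration is a JSON file with blocks \code{sim} (arguments of
#' \code{\link{sim_config}}), \code{world} (baseline_n_per_pop,
#' n_broodstock_pops, pairs_per_pop, mixture_n, optional composition),
#' \code{parentage} (\code{\link{parentage_config}} arguments) and
#' \code{gsi} (\code{\link{gsi_config}} arguments), plus a top-level
#' \code{seed}. Any block may be omitted; defaults apply.
#'
#' @param path JSON file path.
#' @return a named list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

.cfg_get <- function(cfg, block, defaults) {
  vals <- cfg[[block]] %||% list()
  utils::modifyList(defaults, as.list(vals))
}

.write_manifest <- function(out_dir, stage, cfg, files) {
  files <- files[file.exists(files)]
  manifest <- list(stage = stage, seed = cfg$seed %||% NA,
                   config = cfg[setdiff(names(cfg), "seed")],
                   outputs = lapply(stats::setNames(nm = basename(files)), function(f)
                     unname(tools::md5sum(file.path(out_dir, f)))),
                   created = "run manifest")
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a synthetic dataset on disk
#'
#' Simulates baseline frequencies, per-population baseline reference
#' samples, fully genotyped broodstocks, and a mixed fishery sample with
#' ground truth, writing everything in the package's CSV dialects plus a
#' manifest with the seed and output checksums.
#'
#' @param config a \code{run_config} list (see
#'   \code{\link{read_run_config}}); may be a plain list.
#' @param out_dir output directory (created if needed).
#' @return invisible named vector of written file paths.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  simc <- do.call(sim_config, .cfg_get(config, "sim", list(seed = seed)))
  world <- .cfg_get(config, "world",
                    list(baseline_n_per_pop = 50L, n_broodstock_pops = 2L,
                         pairs_per_pop = 20L, mixture_n = 200L,
                         composition = NULL))
  sim <- simulate_baseline_freqs(simc)
  pops <- rownames(sim$freqs)

  baseline <- do.call(bind_geno, lapply(pops, function(p)
    sample_genotypes(sim$freqs[p, ], world$baseline_n_per_pop,
                     group = p, ids = sprintf("%s_ref_%03d", p,
                                              seq_len(world$baseline_n_per_pop)))))
  bpops <- pops[seq_len(min(world$n_broodstock_pops, length(pops)))]
  pool <- do.call(bind_pools, lapply(bpops, function(p)
    simulate_broodstock(p, world$pairs_per_pop, world$pairs_per_pop,
                        sim$freqs[p, ])))
  comp <- world$composition
  if (is.null(comp)) {
    comp <- stats::setNames(rep(1 / length(bpops), length(bpops)), bpops)
  } else comp <- unlist(comp)
  mix <- simulate_mixture(comp, world$mixture_n, sim$freqs, pool = pool,
                          error_rate = simc$genotype_error_rate,
                          missing_rate = simc$missing_rate)

  paths <- c(panel = "panel.csv", registry = "registry.csv",
             baseline = "baseline.csv", broodstock = "broodstock.csv",
             broodstock_meta = "broodstock_meta.csv", mixture = "mixture.csv",
             truth = "truth.csv")
  fp <- function(f) file.path(out_dir, f)
  utils::write.csv(as.data.frame(sim$panel), fp(paths["panel"]), row.names = FALSE)
  write_registry(sim$registry, fp(paths["registry"]))
  write_genotypes(baseline, fp(paths["baseline"]), sim$panel, "reference")
  write_genotypes(pool$genotypes, fp(paths["broodstock"]), sim$panel, "broodstock")
  utils::write.csv(pool$meta, fp(paths["broodstock_meta"]), row.names = FALSE)
  write_genotypes(mix$genotypes, fp(paths["mixture"]), sim$panel, "mixture")
  utils::write.csv(mix$truth, fp(paths["truth"]), row.names = FALSE)
  .write_manifest(out_dir, "simulate", config, fp(paths))
  invisible(stats::setNames(fp(paths), names(paths)))
}

#' Identify individuals in a mixture: PBT first, then GSI
#'
#' Reads a dataset directory written by \code{\link{run_simulate}} (or
#' hand-assembled in the same dialect), applies QC, runs parentage against
#' the pooled broodstock, runs the conditional GSI Gibbs sampler against
#' baseline posterior frequencies, routes every individual, and writes
#' assignment records plus population- and CU-level composition tables.
#'
#' @param config a \code{run_config} list (blocks \code{parentage},
#'   \code{gsi}; top-level \code{seed}).
#' @param data_dir directory holding panel/registry/baseline/broodstock/
#'   mixture files.
#' @param out_dir output directory.
#' @return invisible list with \code{records}, \code{parentage},
#'   \code{composition} (population level), \code{composition_cu}.
#' @export
run_identify <- function(config, data_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel_df <- utils::read.csv(file.path(data_dir, "panel.csv"),
                              stringsAsFactors = FALSE)
  panel <- locus_panel(panel_df$locus_id,
                       cbind(panel_df$allele_a, panel_df$allele_b),
                       panel_df$is_analytic)
  registry <- read_registry(file.path(data_dir, "registry.csv"))
  baseline <- drop_non_analytic(
    read_genotypes(file.path(data_dir, "baseline.csv"), panel), panel)
  brood <- drop_non_analytic(
    read_genotypes(file.path(data_dir, "broodstock.csv"), panel), panel)
  bmeta <- utils::read.csv(file.path(data_dir, "broodstock_meta.csv"),
                           stringsAsFactors = FALSE)
  pool <- parent_pool(brood, bmeta)
  mixture <- drop_non_analytic(
    read_genotypes(file.path(data_dir, "mixture.csv"), panel), panel)

  pcfg <- do.call(parentage_config, .cfg_get(config, "parentage", list()))
  gcfg <- do.call(gsi_config, .cfg_get(config, "gsi",
                                       list(seed = config$seed %||% 1L)))
  fp <- function(f) file.path(out_dir, f)
  if (nrow(mixture$geno) == 0L) {
    warning("empty mixture: writing empty outputs")
    utils::write.csv(.empty_parentage(character(0)), fp("parentage.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(individual_id = character(0), method = character(0),
                                population = character(0), brood_year = integer(0)),
                     fp("records.csv"), row.names = FALSE)
    .write_manifest(out_dir, "identify", config,
                    fp(c("parentage.csv", "records.csv")))
    return(invisible(NULL))
  }
  qc <- qc_filter(mixture)
  if (length(qc$excluded))
    message(length(qc$excluded), " individual(s) excluded by QC")
  mixture <- qc$table
  freqs <- baseline_posterior_freqs(baseline, gcfg$freq_prior)
  par_res <- assign_parentage(mixture, pool, freqs, pcfg)
  gsi_res <- gsi_gibbs(mixture, freqs, gcfg)
  records <- route(par_res, gsi_res, registry, pcfg)
  comp <- combined_composition(records, gsi_res)
  comp_cu <- rollup(comp, registry, "cu")

  utils::write.csv(par_res, fp("parentage.csv"), row.names = FALSE)
  utils::write.csv(records, fp("records.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(comp), fp("composition_population.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(comp_cu), fp("composition_cu.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(gsi_res$indiv_posterior),
                   fp("gsi_posterior.csv"))
  .write_manifest(out_dir, "identify", config,
                  fp(c("parentage.csv", "records.csv",
                       "composition_population.csv", "composition_cu.csv",
                       "gsi_posterior.csv")))
  invisible(list(records = records, parentage = par_res,
                 composition = comp, composition_cu = comp_cu, gsi = gsi_res))
}

#' Downstream fishery estimates
#'
#' From fishery metadata and (optionally) a composition table and
#' CWT/escapement inputs, computes seasonal sample sizes, hatchery-origin
#' catch, population-specific catch, CWT expansions, and exploitation rates
#' by both methods, writing one CSV per report.
#'
#' @param fishery_csv CSV with columns \code{fishery}, \code{month},
#'   \code{catch}, \code{n_genotypes}, \code{clip_rate} (fraction); or NULL.
#' @param composition_csv CSV with columns \code{unit}, \code{mean}
#'   (population-level composition); or NULL.
#' @param er_csv CSV with columns \code{population}, \code{cwt_catch},
#'   \code{cwt_hatchery_escapement}, \code{genetic_catch},
#'   \code{total_escapement}, \code{escapement_clip_rate} (fraction); or
#'   NULL. CWT columns may be NA for untagged populations.
#' @param out_dir output directory.
#' @return invisible list with \code{seasonal}, \code{fishery},
#'   \code{population_catch}, \code{er} data frames (NULL where inputs were
#'   not given).
#' @export
run_estimate <- function(fishery_csv = NULL, composition_csv = NULL,
                         er_csv = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  seasonal <- fishery <- popcatch <- er <- NULL
  if (!is.null(fishery_csv)) {
    fm <- utils::read.csv(fishery_csv, stringsAsFactors = FALSE)
    seasonal <- do.call(rbind, lapply(split(fm, fm$fishery), function(d) {
      if (all(d$n_genotypes == 0) || sum(d$catch) == 0)
        return(NULL)
      ss <- seasonal_subsample(stats::setNames(d$catch, d$month),
                               stats::setNames(d$n_genotypes, d$month))
      data.frame(fishery = d$fishery[1], month = names(ss), n_seasonal = ss,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    fishery <- do.call(rbind, lapply(split(fm, fm$fishery), function(d) {
      total <- sum(d$catch)
      data.frame(fishery = d$fishery[1], catch = total,
                 clip_rate = d$clip_rate[1],
                 hatchery_origin_catch = hatchery_origin_catch(total, d$clip_rate[1]),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    utils::write.csv(seasonal, fp("seasonal_samples.csv"), row.names = FALSE)
    utils::write.csv(fishery, fp("fishery_catch.csv"), row.names = FALSE)
    if (!is.null(composition_csv)) {
      comp <- utils::read.csv(composition_csv, stringsAsFactors = FALSE)
      compv <- stats::setNames(comp$mean, comp$unit)
      popcatch <- do.call(rbind, lapply(seq_len(nrow(fishery)), function(i) {
        data.frame(fishery = fishery$fishery[i], population = names(compv),
                   catch = population_catch(fishery$hatchery_origin_catch[i], compv),
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
      utils::write.csv(popcatch, fp("population_catch.csv"), row.names = FALSE)
    }
  }
  if (!is.null(er_csv)) {
    ei <- utils::read.csv(er_csv, stringsAsFactors = FALSE)
    ei$genetic_hatchery_escapement <-
      hatchery_escapement(ei$total_escapement, ei$escapement_clip_rate)
    ei$er_cwt <- ifelse(
      is.na(ei$cwt_catch), NA_integer_,
      exploitation_rate(ifelse(is.na(ei$cwt_catch), 1, ei$cwt_catch),
                        ifelse(is.na(ei$cwt_hatchery_escapement), 0,
                               ei$cwt_hatchery_escapement)))
    ei$er_genetic <- exploitation_rate(ei$genetic_catch,
                                       ei$genetic_hatchery_escapement)
    er <- ei
    utils::write.csv(er, fp("exploitation_rates.csv"), row.names = FALSE)
  }
  invisible(list(seasonal = seasonal, fishery = fishery,
                 population_catch = popcatch, er = er))
}
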