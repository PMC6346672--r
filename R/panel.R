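#' SNP locus panel
#'
#' Describes the biallelic SNP panel: one row per locus with its two allele
#' codes and a flag marking loci used in parentage/GSI analysis. Species-ID
#' and sex-ID assays are carried on amplicon panels but are excluded from
#' population-genetic analysis; they are flagged \code{is_analytic = FALSE}.
#'
#' @param locus_id character vector of unique locus names.
#' @param allele_codes two-column integer matrix of allele codes, one row per
#'   locus (recycled from a single row). Defaults to codes 1/2 at every locus.
#' @param is_analytic logical vector (recycled); at least one locus must be
#'   analytic.
#' @return a data frame of class \code{locus_panel} with columns
#'   \code{locus_id}, \code{allele_a}, \code{allele_b}, \code{is_analytic}.
#' @examples
#' locus_panel(c("Oki_1", "Oki_2", "Oki_sex"), is_analytic = c(TRUE, TRUE, FALSE))
#' @export
locus_panel <- function(locus_id, allele_codes = NULL, is_analytic = TRUE) {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id)) stop("locus ids must be unique", call. = FALSE)
  n <- length(locus_id)
  if (n < 1L) stop("panel must contain at least one locus", call. = FALSE)
  if (is.null(allele_codes)) allele_codes <- cbind(1L, 2L)
  allele_codes <- matrix(as.integer(allele_codes), ncol = 2L)
  if (nrow(allele_codes) == 1L) allele_codes <- allele_codes[rep(1L, n), , drop = FALSE]
  if (nrow(allele_codes) != n) stop("allele_codes must have one row per locus", call. = FALSE)
  if (any(allele_codes[, 1L] == allele_codes[, 2L]))
    stop("each locus needs two distinct allele codes", call. = FALSE)
  is_analytic <- rep_len(as.logical(is_analytic), n)
  if (!any(is_analytic)) stop("panel must contain at least one analytic locus", call. = FALSE)
  structure(
    data.frame(
      locus_id = locus_id,
      allele_a = allele_codes[, 1L],
      allele_b = allele_codes[, 2L],
      is_analytic = is_analytic,
      stringsAsFactors = FALSE
    ),
    class = c("locus_panel", "data.frame")
  )
}

#' Default synthetic SNP panel
#'
#' A panel of \code{n_loci} analytic biallelic SNPs (allele codes 1/2) plus
#' optionally \code{n_special} trailing non-analytic loci standing in for
#' species-ID / sex-ID assays.
#'
#' @param n_loci number of analytic loci (default 302).
#' @param n_special number of trailing non-analytic loci (default 0).
#' @return a \code{\link{locus_panel}}.
#' @export
default_panel <- function(n_loci = 302L, n_special = 0L) {
  ids <- sprintf("Loc_%03d", seq_len(n_loci + n_special))
  locus_panel(ids, is_analytic = c(rep(TRUE, n_loci), rep(FALSE, n_special)))
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf(
    "<locus_panel> %d loci (%d analytic)\n", nrow(x), sum(x$is_analytic)
  ))
  invisible(x)
}
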