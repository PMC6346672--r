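#' Read a genotype table from delimited text
#'
#' Reads the two-integer-columns-per-locus dialect used for archived salmon
#' SNP data: a leading metadata block (any of \code{sample_type},
#' \code{repunit}, \code{collection}, \code{indiv}) followed, for each locus
#' \code{L} in the panel, by columns \code{L} and \code{L_1} holding the two
#' allele codes. Missing genotypes are encoded as empty fields, \code{NA} or
#' \code{0}. The delimiter is chosen by file extension (\code{.csv} comma,
#' otherwise tab).
#'
#' @param path path to a CSV/TSV file.
#' @param panel a \code{\link{locus_panel}}; loci present in the file but not
#'   in the panel are an error, panel loci absent from the file are an error.
#' @return a \code{\link{genotype_table}} whose group labels are the
#'   \code{collection} column (empty string if absent).
#' @export
read_genotypes <- function(path, panel) {
  stopifnot(inherits(panel, "locus_panel"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  meta_cols <- intersect(c("sample_type", "repunit", "collection", "indiv"), names(raw))
  locus_cols <- setdiff(names(raw), meta_cols)
  want <- as.vector(rbind(panel$locus_id, paste0(panel$locus_id, "_1")))
  unknown <- setdiff(locus_cols, want)
  if (length(unknown))
    stop("unknown loci in file (not in panel): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(want, locus_cols)
  if (length(absent))
    stop("panel loci absent from file: ", paste(absent, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  ids <- if ("indiv" %in% meta_cols) raw$indiv else sprintf("ind_%d", seq_len(n))
  group <- if ("collection" %in% meta_cols) raw$collection else ""
  group[is.na(group)] <- ""

  geno <- matrix(NA_integer_, n, nrow(panel),
                 dimnames = list(ids, panel$locus_id))
  for (j in seq_len(nrow(panel))) {
    loc <- panel$locus_id[j]
    a1 <- suppressWarnings(as.integer(raw[[loc]]))
    a2 <- suppressWarnings(as.integer(raw[[paste0(loc, "_1")]]))
    a1[!is.na(a1) & a1 == 0L] <- NA_integer_
    a2[!is.na(a2) & a2 == 0L] <- NA_integer_
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      stop(sprintf("malformed row %d: half-missing genotype at locus %s",
                   which(half)[1], loc), call. = FALSE)
    called <- !is.na(a1)
    ok <- c(panel$allele_a[j], panel$allele_b[j])
    bad <- called & (!(a1 %in% ok) | !(a2 %in% ok))
    if (any(bad))
      stop(sprintf("allele code outside panel at locus %s (row %d)",
                   loc, which(bad)[1]), call. = FALSE)
    geno[called, j] <- (a1[called] == panel$allele_b[j]) +
                       (a2[called] == panel$allele_b[j])
  }
  genotype_table(geno, group)
}

#' Write a genotype table in the archival two-column dialect
#'
#' Inverse of \code{\link{read_genotypes}}: metadata columns
#' \code{sample_type}, \code{repunit}, \code{collection}, \code{indiv}
#' followed by \code{<locus>}/\code{<locus>_1} allele-code pairs (heterozygotes
#' written allele_a then allele_b). Missing genotypes are written as empty
#' fields.
#'
#' @param x a \code{\link{genotype_table}}.
#' @param path output path; extension selects comma (\code{.csv}) or tab.
#' @param panel the \code{\link{locus_panel}} matching \code{x}'s loci.
#' @param sample_type value for the \code{sample_type} column
#'   (e.g. "reference" or "mixture").
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(x, path, panel, sample_type = "reference") {
  stopifnot(inherits(x, "geno_table"), inherits(panel, "locus_panel"))
  idx <- match(colnames(x$geno), panel$locus_id)
  if (anyNA(idx)) stop("table contains loci not in panel", call. = FALSE)
  n <- nrow(x$geno)
  out <- data.frame(sample_type = rep(sample_type, n),
                    repunit = rep(NA_character_, n),
                    collection = x$group,
                    indiv = rownames(x$geno),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_along(idx)) {
    j <- idx[k]
    g <- x$geno[, k]
    a1 <- ifelse(is.na(g), NA_integer_,
                 ifelse(g == 2L, panel$allele_b[j], panel$allele_a[j]))
    a2 <- ifelse(is.na(g), NA_integer_,
                 ifelse(g == 0L, panel$allele_a[j], panel$allele_b[j]))
    out[[panel$locus_id[j]]] <- a1
    out[[paste0(panel$locus_id[j], "_1")]] <- a2
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a population registry
#'
#' CSV with columns \code{population}, \code{cu}, \code{region},
#' \code{country} mapping each baseline population to exactly one
#' conservation unit (CU) and reporting region.
#'
#' @param path CSV path.
#' @return data frame of class \code{baseline_registry}.
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  need <- c("population", "cu", "region", "country")
  if (!all(need %in% names(reg)))
    stop("registry must have columns ", paste(need, collapse = ", "), call. = FALSE)
  as_registry(reg[need])
}

#' Construct/validate a population registry
#' @param reg data frame with columns population, cu, region, country.
#' @return data frame of class \code{baseline_registry}.
#' @export
as_registry <- function(reg) {
  if (anyDuplicated(reg$population))
    stop("each population must map to exactly one CU/region", call. = FALSE)
  structure(reg, class = c("baseline_registry", "data.frame"))
}

#' Write a population registry
#' @param reg a registry data frame.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(reg, path) {
  utils::write.csv(reg, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude individuals with excessive missing genotypes
#'
#' Individuals with strictly more than \code{max_missing} missing genotypes
#' (the published rule: more than 120 of 302) are removed before any
#' parentage or GSI analysis.
#'
#' @param x a \code{\link{genotype_table}} (analytic loci only; apply
#'   \code{\link{drop_non_analytic}} first).
#' @param max_missing integer threshold, default 120; exclusion is strict
#'   (exactly \code{max_missing} missing is retained).
#' @return list with elements \code{table} (filtered \code{geno_table}) and
#'   \code{excluded} (character ids removed).
#' @export
qc_filter <- function(x, max_missing = 120L) {
  stopifnot(inherits(x, "geno_table"), max_missing >= 0)
  nmiss <- missing_counts(x)
  drop <- nmiss > max_missing
  list(table = subset_indiv(x, !drop), excluded = rownames(x$geno)[drop])
}

#' Drop species-ID / sex-ID loci
#'
#' Restricts a genotype table to the panel's analytic loci (preserving locus
#' order), the set used for parentage and GSI.
#'
#' @param x a \code{\link{genotype_table}}.
#' @param panel a \code{\link{locus_panel}}.
#' @return a \code{geno_table} with only analytic loci.
#' @export
drop_non_analytic <- function(x, panel) {
  stopifnot(inherits(x, "geno_table"), inherits(panel, "locus_panel"))
  keep <- panel$locus_id[panel$is_analytic]
  keep <- keep[keep %in% colnames(x$geno)]
  if (!length(keep)) stop("no analytic loci present", call. = FALSE)
  genotype_table(x$geno[, keep, drop = FALSE], x$group)
}
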