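#' Genotype table
#'
#' The common currency of the pipeline: an individuals-by-loci matrix of
#' unphased biallelic genotypes. Genotypes are stored as the integer count of
#' the locus's second allele code (0, 1 or 2); \code{NA} is a missing
#' genotype. Because alleles are unordered, this encoding is lossless for
#' biallelic SNPs.
#'
#' @param geno integer matrix, individuals in rows (rownames are individual
#'   ids), loci in columns (colnames are locus ids); entries in \{0, 1, 2, NA\}.
#' @param group character vector of group labels (population for
#'   baseline/broodstock tables, fishery stratum for mixtures), recycled.
#' @return an object of class \code{geno_table}.
#' @export
genotype_table <- function(geno, group = "") {
  if (!is.matrix(geno)) stop("geno must be a matrix", call. = FALSE)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("ind_%d", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("Loc_%03d", seq_len(ncol(geno)))
  if (anyDuplicated(rownames(geno))) stop("individual ids must be unique", call. = FALSE)
  vals <- geno[!is.na(geno)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  group <- rep_len(as.character(group), nrow(geno))
  structure(list(geno = geno, group = group), class = "geno_table")
}

#' @export
print.geno_table <- function(x, ...) {
  cat(sprintf(
    "<geno_table> %d individuals x %d loci, %.1f%% missing, %d group(s)\n",
    nrow(x$geno), ncol(x$geno),
    100 * mean(is.na(x$geno)), length(unique(x$group))
  ))
  invisible(x)
}

#' @export
dim.geno_table <- function(x) dim(x$geno)

#' Individual ids of a genotype table
#' @param x a \code{geno_table}.
#' @return character vector.
#' @export
indiv_ids <- function(x) rownames(x$geno)

#' Locus ids of a genotype table
#' @param x a \code{geno_table}.
#' @return character vector.
#' @export
loci <- function(x) colnames(x$geno)

#' Per-individual count of missing genotypes
#' @param x a \code{geno_table}.
#' @return named integer vector.
#' @export
missing_counts <- function(x) rowSums(is.na(x$geno))

#' Subset a genotype table by individuals
#' @param x a \code{geno_table}.
#' @param i row index (integer, logical or character).
#' @return a \code{geno_table}.
#' @export
subset_indiv <- function(x, i) {
  if (is.character(i)) i <- match(i, rownames(x$geno))
  genotype_table(x$geno[i, , drop = FALSE], x$group[i])
}

#' Row-bind genotype tables sharing a locus set
#' @param ... \code{geno_table} objects with identical loci.
#' @return a \code{geno_table}.
#' @export
bind_geno <- function(...) {
  xs <- list(...)
  ln <- lapply(xs, function(x) colnames(x$geno))
  if (!all(vapply(ln, identical, logical(1), ln[[1]])))
    stop("genotype tables must share an identical locus set", call. = FALSE)
  genotype_table(do.call(rbind, lapply(xs, `[[`, "geno")),
                 unlist(lapply(xs, `[[`, "group"), use.names = FALSE))
}
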