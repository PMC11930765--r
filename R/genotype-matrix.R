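#' Construct a genotype matrix
#'
#' The central container for diploid SNP data: an individuals-by-loci
#' matrix of alternate-allele dosages (0, 1, 2 or NA for missing calls)
#' plus locus metadata (chromosome, position and optional effect
#' annotation) and individual metadata (at minimum a `site_id`).
#'
#' @param dosage integer/numeric matrix, individuals in rows, loci in
#'   columns; entries in \{0, 1, 2, NA\}
#' @param loci data frame with columns `chrom`, `pos` (1-based) and
#'   optionally `effect`; one row per column of `dosage`
#' @param individuals data frame with columns `id`, `site_id`; one row
#'   per row of `dosage`
#' @return object of class `genotype_matrix`
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2),
#'                      loci = data.frame(chrom = "1", pos = c(100, 200)),
#'                      individuals = data.frame(id = c("a", "b"),
#'                                               site_id = "s1"))
#' individual_heterozygosity(g)
#' @export
genotype_matrix <- function(dosage, loci, individuals) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  stopifnot(ncol(dosage) == nrow(loci), nrow(dosage) == nrow(individuals))
  if (is.null(loci$chrom) || is.null(loci$pos)) {
    stop("loci metadata needs 'chrom' and 'pos'")
  }
  if (any(loci$pos < 1)) stop("positions are 1-based; pos >= 1 required")
  if (is.null(individuals$id) || is.null(individuals$site_id)) {
    stop("individual metadata needs 'id' and 'site_id'")
  }
  ord <- order(loci$chrom, loci$pos)
  structure(list(dosage = dosage[, ord, drop = FALSE],
                 loci = loci[ord, , drop = FALSE],
                 individuals = as.data.frame(individuals)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d sites, %.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$individuals$site_id)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or loci
#' @param x a [genotype_matrix()]
#' @param individuals logical/integer index over individuals
#' @param loci logical/integer index over loci
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage; li <- x$loci; ii <- x$individuals
  if (!is.null(loci)) {
    d <- d[, loci, drop = FALSE]
    li <- li[loci, , drop = FALSE]
  }
  if (!is.null(individuals)) {
    d <- d[individuals, , drop = FALSE]
    ii <- ii[individuals, , drop = FALSE]
  }
  structure(list(dosage = d, loci = li, individuals = ii),
            class = "genotype_matrix")
}

#' Per-locus minor allele frequency
#' @param x a [genotype_matrix()]
#' @return numeric vector, one MAF per locus (NA where no calls)
#' @export
locus_maf <- function(x) {
  p <- colMeans(x$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-locus call rate
#' @param x a [genotype_matrix()]
#' @return fraction of non-missing calls per locus
#' @export
locus_call_rate <- function(x) colMeans(!is.na(x$dosage))
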