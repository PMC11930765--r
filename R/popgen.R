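#' Linearize an FST value
#'
#' Rousset's transform f / (1 - f) used as the response in
#' isolation-by-distance regressions. Negative estimates are truncated
#' at 0 before linearization (keeping responses finite); f = 1 maps to
#' `Inf`.
#'
#' @param f FST value(s)
#' @return linearized value(s)
#' @export
linearize_fst <- function(f) {
  f <- pmax(f, 0)
  ifelse(f >= 1, Inf, f / (1 - f))
}

#' Filter and prune SNPs by call rate, MAF, proximity and LD
#'
#' Four sequential filters: (1) drop loci genotyped in fewer than
#' `min_call` of individuals; (2) drop loci with minor allele frequency
#' below `maf`; (3) within each chromosome, a greedy proximity scan that
#' keeps the first locus of any run of loci spaced closer than
#' `proximity_bp`; (4) greedy LD pruning that, for each same-chromosome
#' pair with squared dosage correlation above `ld_threshold`, drops the
#' lower-MAF member (ties drop the downstream locus). Counts removed at
#' each step are attached as attribute `prune_report`.
#'
#' @param gm a [genotype_matrix()] with loci sorted by (chrom, pos)
#' @param min_call minimum per-locus call rate (default 0.8)
#' @param maf minimum minor allele frequency (default 0.05)
#' @param proximity_bp minimum spacing between retained loci (default 2000)
#' @param ld_threshold r-squared above which one of a pair is dropped
#'   (default 0.5)
#' @return pruned `genotype_matrix` with a `prune_report` attribute
#' @export
prune_snps <- function(gm, min_call = 0.8, maf = 0.05,
                       proximity_bp = 2000, ld_threshold = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (min_call < 0 || min_call > 1 || maf < 0 || maf > 0.5 ||
      ld_threshold < 0 || ld_threshold > 1) {
    stop("rate thresholds must lie in [0, 1] (maf in [0, 0.5])")
  }
  if (proximity_bp < 0) stop("proximity_bp must be >= 0")
  n0 <- ncol(gm$dosage)
  keep <- locus_call_rate(gm) >= min_call
  n_call <- sum(!keep)
  m <- locus_maf(gm)
  keep <- keep & !is.na(m) & m >= maf
  n_maf <- sum(!keep) - n_call
  gm <- subset_genotypes(gm, loci = keep)

  # greedy proximity scan per chromosome (loci are sorted)
  keep2 <- rep(TRUE, ncol(gm$dosage))
  for (ch in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == ch)
    last_kept <- -Inf
    for (i in idx) {
      if (gm$loci$pos[i] - last_kept < proximity_bp) {
        keep2[i] <- FALSE
      } else {
        last_kept <- gm$loci$pos[i]
      }
    }
  }
  n_prox <- sum(!keep2)
  gm <- subset_genotypes(gm, loci = keep2)

  # greedy LD pruning among remaining same-chromosome pairs
  alive <- rep(TRUE, ncol(gm$dosage))
  mafs <- locus_maf(gm)
  for (ch in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == ch)
    if (length(idx) < 2) next
    r2 <- suppressWarnings(
      cor(gm$dosage[, idx, drop = FALSE],
          use = "pairwise.complete.obs"))^2
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (!alive[i] || !alive[j]) next
        if (!is.na(r2[a, b]) && r2[a, b] > ld_threshold) {
          drop <- if (mafs[i] < mafs[j]) i else if (mafs[j] < mafs[i]) j else j
          alive[drop] <- FALSE
        }
      }
    }
  }
  n_ld <- sum(!alive)
  gm <- subset_genotypes(gm, loci = alive)
  attr(gm, "prune_report") <- data.frame(
    step = c("call_rate", "maf", "proximity", "ld"),
    removed = c(n_call, n_maf, n_prox, n_ld),
    remaining = c(n0 - n_call, n0 - n_call - n_maf,
                  n0 - n_call - n_maf - n_prox, ncol(gm$dosage)))
  gm
}

#' @keywords internal
#' @noRd
resolve_grouping <- function(gm, grouping) {
  if (length(grouping) == 1 && grouping %in% names(gm$individuals)) {
    return(as.character(gm$individuals[[grouping]]))
  }
  if (length(grouping) == nrow(gm$dosage)) return(as.character(grouping))
  stop("grouping must be a metadata column name or a per-individual vector")
}

#' Expected heterozygosity (Hs) per group
#'
#' Per-locus gene diversity with the Nei & Chesser (1983) small-sample
#' correction, `(n/(n-1)) * (1 - sum(p^2) - Ho/(2n))`, averaged over loci
#' with at least two genotyped individuals in the group. `naive = TRUE`
#' gives the uncorrected `1 - sum(p^2)`.
#'
#' @param gm a [genotype_matrix()]
#' @param grouping metadata column name (default `"site_id"`) or a
#'   per-individual label vector
#' @param naive use the uncorrected estimator
#' @return data frame `group`, `hs`, `n_loci`
#' @export
expected_heterozygosity <- function(gm, grouping = "site_id", naive = FALSE) {
  gl <- resolve_grouping(gm, grouping)
  out <- lapply(sort(unique(gl)), function(g) {
    d <- gm$dosage[gl == g, , drop = FALSE]
    if (nrow(d) == 0) stop("empty group: ", g)
    n <- colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    ho <- colMeans(d == 1, na.rm = TRUE)
    use <- n >= 2
    hs <- if (naive) {
      1 - (p^2 + (1 - p)^2)
    } else {
      (n / (n - 1)) * (1 - (p^2 + (1 - p)^2) - ho / (2 * n))
    }
    data.frame(group = g, hs = mean(hs[use]), n_loci = sum(use),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-individual heterozygosity
#'
#' Fraction of non-missing loci at which the individual is heterozygous.
#'
#' @param gm a [genotype_matrix()]
#' @return data frame `id`, `site_id`, `heterozygosity`, `n_loci`
#' @export
individual_heterozygosity <- function(gm) {
  n <- rowSums(!is.na(gm$dosage))
  h <- rowSums(gm$dosage == 1, na.rm = TRUE) / n
  if (any(n == 0)) {
    warning("individual(s) with zero genotyped loci: ",
            paste(gm$individuals$id[n == 0], collapse = ", "))
    h[n == 0] <- NA_real_
  }
  data.frame(id = gm$individuals$id, site_id = gm$individuals$site_id,
             heterozygosity = unname(h), n_loci = unname(n),
             stringsAsFactors = FALSE)
}

# Per-locus FST components for a pair (or set) of groups.
# Returns num/den vectors such that the multilocus estimate is
# sum(num)/sum(den) (ratio-of-sums over loci).
#' @keywords internal
#' @noRd
fst_components <- function(dos_list, estimator = "wc", naive = FALSE) {
  L <- ncol(dos_list[[1]])
  r <- length(dos_list)
  n <- sapply(dos_list, function(d) colSums(!is.na(d)))        # L x r
  p <- sapply(dos_list, function(d) colMeans(d, na.rm = TRUE) / 2)
  ho <- sapply(dos_list, function(d) colMeans(d == 1, na.rm = TRUE))
  if (L == 1) { n <- rbind(n); p <- rbind(p); ho <- rbind(ho) }
  use <- rowSums(n >= 2) == r
  num <- den <- rep(NA_real_, L)
  if (estimator == "nei") {
    nh <- r / rowSums(1 / n)                       # harmonic mean size
    msp <- rowMeans(p^2 + (1 - p)^2)
    hom <- rowMeans(ho)
    pbar <- rowMeans(p)
    if (naive) {
      hs <- 1 - msp
      ht <- 1 - (pbar^2 + (1 - pbar)^2)
    } else {
      hs <- (nh / (nh - 1)) * (1 - msp - hom / (2 * nh))
      ht <- 1 - (pbar^2 + (1 - pbar)^2) + hs / (nh * r) - hom / (2 * nh * r)
    }
    num <- ht - hs
    den <- ht
  } else if (estimator == "wc") {
    nbar <- rowMeans(n)
    nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
    pbar <- rowSums(n * p) / (r * nbar)
    s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- rowSums(n * ho) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- a
    den <- a + b + cc
  } else stop("unknown estimator: ", estimator)
  num[!use] <- NA_real_
  den[!use] <- NA_real_
  list(num = num, den = den, use = use)
}

#' Pairwise FST among groups
#'
#' Two multilocus estimators: `"wc"`, Weir & Cockerham's (1984)
#' variance-components theta (ratio of summed components over loci), and
#' `"nei"`, the Nei gene-diversity form (Ht - Hs)/Ht with Nei & Chesser
#' (1983) sample-size corrections (`naive = TRUE` disables them).
#' Missing dosages are excluded per locus and pair; loci need at least
#' two genotyped individuals in both groups. Linearized values
#' (see [linearize_fst()]) are attached.
#'
#' @param gm a [genotype_matrix()]
#' @param grouping metadata column name or per-individual labels
#' @param estimator `"wc"` or `"nei"`
#' @param naive for `"nei"`, skip the small-sample corrections
#' @return object of class `fst_matrix`: symmetric `est` and `linear`
#'   matrices, group labels, estimator tag
#' @export
pairwise_fst <- function(gm, grouping = "site_id",
                         estimator = c("wc", "nei"), naive = FALSE) {
  estimator <- match.arg(estimator)
  gl <- resolve_grouping(gm, grouping)
  groups <- sort(unique(gl))
  if (length(groups) < 2) stop("need at least two groups")
  k <- length(groups)
  est <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    da <- gm$dosage[gl == groups[i], , drop = FALSE]
    db <- gm$dosage[gl == groups[j], , drop = FALSE]
    comp <- fst_components(list(da, db), estimator, naive)
    den <- sum(comp$den, na.rm = TRUE)
    if (!any(comp$use) || den == 0) {
      warning("FST undefined for pair ", groups[i], "-", groups[j],
              " (no usable polymorphic loci)")
      est[i, j] <- est[j, i] <- NA_real_
    } else {
      est[i, j] <- est[j, i] <- sum(comp$num, na.rm = TRUE) / den
    }
  }
  structure(list(est = est, linear = linearize_fst(est),
                 groups = groups, estimator = estimator, naive = naive,
                 ci_lower = NULL, ci_upper = NULL),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("fst_matrix (%s%s): %d groups\n", x$estimator,
              if (isTRUE(x$naive)) ", naive" else "", length(x$groups)))
  print(round(x$est, 4))
  invisible(x)
}

#' Bootstrap confidence intervals for pairwise FST
#'
#' Percentile bootstrap over loci: per pair, loci are resampled with
#' replacement `n_boot` times, the multilocus ratio-of-sums recomputed,
#' and the `conf` percentile interval taken.
#'
#' @inheritParams pairwise_fst
#' @param n_boot bootstrap replicates (default 100)
#' @param conf confidence level (default 0.95)
#' @param seed integer seed
#' @return an `fst_matrix` with `ci_lower`/`ci_upper` matrices
#' @export
bootstrap_fst_ci <- function(gm, grouping = "site_id",
                             estimator = c("wc", "nei"), naive = FALSE,
                             n_boot = 100, conf = 0.95, seed = 1) {
  estimator <- match.arg(estimator)
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (ncol(gm$dosage) < 2) stop("need >= 2 loci to bootstrap")
  fst <- pairwise_fst(gm, grouping, estimator, naive)
  gl <- resolve_grouping(gm, grouping)
  groups <- fst$groups
  k <- length(groups)
  lo <- hi <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  diag(lo) <- diag(hi) <- 0
  alpha <- (1 - conf) / 2
  set.seed(seed)
  L <- ncol(gm$dosage)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    da <- gm$dosage[gl == groups[i], , drop = FALSE]
    db <- gm$dosage[gl == groups[j], , drop = FALSE]
    comp <- fst_components(list(da, db), estimator, naive)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      sum(comp$num[idx], na.rm = TRUE) / sum(comp$den[idx], na.rm = TRUE)
    }, numeric(1))
    q <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    lo[i, j] <- lo[j, i] <- q[1]
    hi[i, j] <- hi[j, i] <- q[2]
  }
  fst$ci_lower <- lo
  fst$ci_upper <- hi
  fst$n_boot <- n_boot
  fst$conf <- conf
  fst$seed <- seed
  fst
}
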