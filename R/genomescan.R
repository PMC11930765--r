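#' Detect runs of homozygosity by sliding SNP windows
#'
#' plink-style scanner: a window of `window_snps` consecutive SNPs is
#' homozygosity-compatible when it contains at most `max_het`
#' heterozygous and at most `max_missing` missing calls; a SNP is
#' in-ROH when at least `hit_fraction` of the windows covering it are
#' compatible; maximal runs of in-ROH SNPs become segments, retained
#' when they span at least `min_length_bp` and contain at least
#' `min_snps` SNPs. Coordinates are 1-based inclusive.
#'
#' @param gm a [genotype_matrix()] of per-individual calls
#' @param window_snps window size in SNPs (default 100)
#' @param max_het maximum heterozygotes per compatible window (default 1)
#' @param max_missing maximum missing calls per compatible window
#'   (default 5)
#' @param min_length_bp minimum segment span (default 100000)
#' @param min_snps minimum SNPs per segment (default 25)
#' @param hit_fraction minimum fraction of compatible covering windows
#'   (default 0.05)
#' @param assayed_bp total assayed genome length for the percent-in-ROH
#'   summary; default the sum of per-chromosome observed spans
#' @return list: `segments` (individual, chrom, start, end, n_snps,
#'   n_het) and `summary` (per individual: n_segments, roh_bp,
#'   pct_genome)
#' @export
detect_roh <- function(gm, window_snps = 100, max_het = 1, max_missing = 5,
                       min_length_bp = 1e5, min_snps = 25,
                       hit_fraction = 0.05, assayed_bp = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(assayed_bp)) {
    spans <- tapply(gm$loci$pos, gm$loci$chrom,
                    function(p) max(p) - min(p) + 1)
    assayed_bp <- sum(spans)
  }
  segs <- list()
  for (ii in seq_len(nrow(gm$dosage))) {
    id <- gm$individuals$id[ii]
    for (ch in unique(gm$loci$chrom)) {
      sel <- gm$loci$chrom == ch
      pos <- gm$loci$pos[sel]
      if (is.unsorted(pos)) stop("loci not sorted within chromosome ", ch)
      d <- gm$dosage[ii, sel]
      L <- length(d)
      W <- window_snps
      if (L < W) {
        message(sprintf("detect_roh: %s shorter than one window; skipped", ch))
        next
      }
      het <- as.numeric(d == 1); het[is.na(het)] <- 0
      mis <- as.numeric(is.na(d))
      chet <- c(0, cumsum(het)); cmis <- c(0, cumsum(mis))
      nW <- L - W + 1
      wh <- chet[(W + 1):(L + 1)] - chet[1:nW]
      wm <- cmis[(W + 1):(L + 1)] - cmis[1:nW]
      compat <- as.numeric(wh <= max_het & wm <= max_missing)
      cc <- c(0, cumsum(compat))
      i <- seq_len(L)
      lo <- pmax(1L, i - W + 1L); hi <- pmin(i, nW)
      hits <- cc[hi + 1] - cc[lo]
      in_roh <- hits / (hi - lo + 1) >= hit_fraction
      r <- rle(in_roh)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        a <- starts[k]; b <- ends[k]
        span <- pos[b] - pos[a] + 1
        if (span >= min_length_bp && (b - a + 1) >= min_snps) {
          segs[[length(segs) + 1]] <- data.frame(
            individual = id, chrom = ch, start = pos[a], end = pos[b],
            n_snps = b - a + 1, n_het = sum(het[a:b]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(individual = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_snps = integer(0),
               n_het = numeric(0), stringsAsFactors = FALSE)
  roh_bp <- tapply(segments$end - segments$start + 1, segments$individual, sum)
  summary <- data.frame(individual = gm$individuals$id,
                        n_segments = 0L, roh_bp = 0, pct_genome = 0,
                        stringsAsFactors = FALSE)
  if (nrow(segments)) {
    cnt <- table(segments$individual)
    m <- match(names(cnt), summary$individual)
    summary$n_segments[m] <- as.integer(cnt)
    summary$roh_bp[match(names(roh_bp), summary$individual)] <- roh_bp
    summary$pct_genome <- 100 * summary$roh_bp / assayed_bp
  }
  list(segments = segments, summary = summary)
}

#' Classify annotation effect terms into impact classes
#'
#' Fixed mapping in the dominant annotator's dialect: stop gain/loss,
#' frameshift and splice-site disruptions are high impact; missense and
#' in-frame indels moderate; synonymous and stop-retained low;
#' everything else (including unknown terms, tallied with a message) is
#' a modifier. Ampersand-joined multi-term annotations take the most
#' severe class present.
#'
#' @param effect_terms character vector of effect terms
#' @return factor with levels `high`, `moderate`, `low`, `modifier`
#' @export
classify_effects <- function(effect_terms) {
  map <- c(stop_gained = "high", stop_lost = "high",
           frameshift_variant = "high",
           splice_acceptor_variant = "high", splice_donor_variant = "high",
           missense_variant = "moderate",
           inframe_insertion = "moderate", inframe_deletion = "moderate",
           synonymous_variant = "low", stop_retained_variant = "low",
           stop_retained = "low",
           intergenic_region = "modifier", intergenic_variant = "modifier",
           intron_variant = "modifier",
           upstream_gene_variant = "modifier",
           downstream_gene_variant = "modifier",
           `3_prime_UTR_variant` = "modifier",
           `5_prime_UTR_variant` = "modifier")
  rank <- c(high = 1, moderate = 2, low = 3, modifier = 4)
  known <- character(0)
  out <- vapply(effect_terms, function(tt) {
    if (is.na(tt)) return("modifier")
    parts <- strsplit(tt, "&", fixed = TRUE)[[1]]
    cl <- unname(map[parts])
    cl[is.na(cl)] <- "modifier"
    names(rank)[min(rank[cl])]
  }, character(1), USE.NAMES = FALSE)
  unknown <- setdiff(unique(unlist(strsplit(
    effect_terms[!is.na(effect_terms)], "&", fixed = TRUE))), names(map))
  unknown <- setdiff(unknown, c("", NA))
  if (length(unknown)) {
    message("classify_effects: ", length(unknown),
            " term(s) outside the mapping treated as modifier: ",
            paste(head(unknown, 5), collapse = ", "))
  }
  factor(out, levels = c("high", "moderate", "low", "modifier"))
}

#' Per-individual genetic-load proportions and their association with
#' heterozygosity
#'
#' Counts alternate alleles per effect class for each individual
#' (dosage-weighted: a homozygous alternate high-effect genotype
#' contributes 2), forms the deleterious proportion
#' `(high + moderate + low alleles) / n_noncoding_genotyped`, and
#' regresses it on individual heterozygosity. With
#' `denominator = "all"` the denominator is instead the total number of
#' SNPs genotyped.
#'
#' @param gm a [genotype_matrix()] whose loci carry an `effect` column
#' @param heterozygosity optional per-individual values (default
#'   computed with [individual_heterozygosity()])
#' @param denominator `"noncoding"` (default) or `"all"`
#' @return list: `table` (per-individual counts, proportion,
#'   heterozygosity) and `fit` (slope, se, p from the OLS regression; NA
#'   with fewer than 3 usable individuals)
#' @export
load_proportions <- function(gm, heterozygosity = NULL,
                             denominator = c("noncoding", "all")) {
  denominator <- match.arg(denominator)
  if (is.null(gm$loci$effect)) stop("loci lack an 'effect' column")
  cls <- classify_effects(gm$loci$effect)
  obs <- !is.na(gm$dosage)
  d0 <- gm$dosage; d0[!obs] <- 0
  cnt <- sapply(levels(cls), function(cl) {
    rowSums(d0[, cls == cl, drop = FALSE])
  })
  if (nrow(gm$dosage) == 1) cnt <- rbind(cnt)
  n_noncod <- rowSums(obs[, cls == "modifier", drop = FALSE])
  n_all <- rowSums(obs)
  denom <- if (denominator == "noncoding") n_noncod else n_all
  prop <- (cnt[, "high"] + cnt[, "moderate"] + cnt[, "low"]) / denom
  if (any(denom == 0)) {
    warning("individual(s) with zero denominator variants: ",
            paste(gm$individuals$id[denom == 0], collapse = ", "))
    prop[denom == 0] <- NA_real_
  }
  if (is.null(heterozygosity)) {
    heterozygosity <- individual_heterozygosity(gm)$heterozygosity
  }
  tab <- data.frame(id = gm$individuals$id,
                    high = cnt[, "high"], moderate = cnt[, "moderate"],
                    low = cnt[, "low"], modifier = cnt[, "modifier"],
                    n_noncoding_genotyped = n_noncod,
                    heterozygosity = heterozygosity,
                    deleterious_proportion = unname(prop),
                    stringsAsFactors = FALSE)
  ok <- complete.cases(tab[, c("heterozygosity", "deleterious_proportion")])
  fit <- list(slope = NA_real_, se = NA_real_, p = NA_real_)
  if (sum(ok) >= 3) {
    lm_fit <- lm(deleterious_proportion ~ heterozygosity, data = tab[ok, ])
    sm <- summary(lm_fit)$coefficients
    fit <- list(slope = sm[2, 1], se = sm[2, 2], p = sm[2, 4])
  }
  list(table = tab, fit = fit)
}

#' Summarize structural variants per individual with divergence
#' regressions
#'
#' Counts insertions/deletions (indels), tandem duplications and
#' breakend events per individual; breakend records are paired by
#' `mate_id` so one inversion/translocation junction counts once, with
#' unpaired records counted singly under a warning. Indel sizes are
#' absolute `sv_len`. When a divergence table is supplied, each count is
#' regressed on each divergence covariate.
#'
#' @param sv list of `records` and `carriers` as returned by
#'   [read_vcf()] or [simulate_genomes()]
#' @param divergence optional data frame keyed by `id` with numeric
#'   divergence covariates (e.g. `fst_to_reference`, `divergence_time`)
#' @param min_sv_len size floor in bp for indels/duplications (default 50)
#' @return list: `per_individual`, `indel_lengths`, `median_indel_bp`,
#'   `regressions` (slope, se, p per count x covariate)
#' @export
summarize_svs <- function(sv, divergence = NULL, min_sv_len = 50) {
  r <- sv$records
  car <- sv$carriers > 0 & !is.na(sv$carriers)
  keep <- !(r$sv_type %in% c("INS", "DEL", "DUP")) | abs(r$sv_len) >= min_sv_len
  r <- r[keep, , drop = FALSE]
  car <- car[, keep, drop = FALSE]
  ids <- rownames(car)
  is_indel <- r$sv_type %in% c("INS", "DEL")
  is_dup <- r$sv_type == "DUP"
  is_bnd <- r$sv_type == "BND"
  # pair breakends by mate_id
  paired <- rep(FALSE, nrow(r))
  if (any(is_bnd)) {
    m <- match(r$mate_id, r$id)
    reciprocal <- !is.na(m) & !is.na(r$mate_id[m]) & r$mate_id[m] == r$id
    paired <- is_bnd & reciprocal
    if (any(is_bnd & !paired)) {
      warning(sum(is_bnd & !paired),
              " breakend record(s) without a mate; counted singly")
    }
  }
  bnd_weight <- ifelse(paired, 0.5, 1)
  per <- data.frame(
    id = ids,
    n_indels = as.integer(car[, is_indel, drop = FALSE] %*%
                            rep(1, sum(is_indel))),
    n_duplications = as.integer(car[, is_dup, drop = FALSE] %*%
                                  rep(1, sum(is_dup))),
    n_breakend_events = as.numeric(car[, is_bnd, drop = FALSE] %*%
                                     bnd_weight[is_bnd]),
    stringsAsFactors = FALSE)
  lens <- abs(r$sv_len[is_indel])
  regs <- NULL
  if (!is.null(divergence)) {
    d <- merge(per, divergence, by = "id")
    covars <- setdiff(names(divergence), "id")
    covars <- covars[vapply(covars, function(v) is.numeric(d[[v]]),
                            logical(1))]
    rows <- list()
    for (resp in c("n_indels", "n_duplications", "n_breakend_events")) {
      for (v in covars) {
        if (nrow(d) < 3 || sd(d[[v]]) == 0) next
        sm <- summary(lm(d[[resp]] ~ d[[v]]))$coefficients
        rows[[length(rows) + 1]] <- data.frame(
          count = resp, covariate = v, slope = sm[2, 1], se = sm[2, 2],
          p = sm[2, 4], stringsAsFactors = FALSE)
      }
    }
    regs <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(per_individual = per, indel_lengths = lens,
       median_indel_bp = if (length(lens)) median(lens) else NA_real_,
       regressions = regs)
}
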