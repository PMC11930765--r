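#' Build the design data for landscape regressions
#'
#' For the pairwise (isolation-by-distance) model: starts from a
#' [pair_table()], drops metapopulations with `min_sites` or fewer sites
#' (too few pairs to estimate a within-drainage slope), removes every
#' pair involving a flagged outlier site, and encodes metapopulation as
#' a factor so the global model can carry a distance-by-metapopulation
#' interaction. For the site-level (Hs) model: joins a site table with
#' per-site heterozygosity and upstream distances.
#'
#' @param pairs a [pair_table()] data frame
#' @param min_sites metapopulations with this many sites or fewer are
#'   excluded (default 4)
#' @param exclude_sites character vector of outlier site ids whose pairs
#'   are removed
#' @return data frame ready for [fit_ols()] / [dredge_models()], with a
#'   `response` attribute naming the response column
#' @export
build_pair_design <- function(pairs, min_sites = 4, exclude_sites = character(0)) {
  sites_per_mp <- tapply(c(pairs$site_a, pairs$site_b),
                         c(pairs$metapopulation, pairs$metapopulation),
                         function(x) length(unique(x)))
  keep_mp <- names(sites_per_mp)[sites_per_mp > min_sites]
  d <- pairs[pairs$metapopulation %in% keep_mp, , drop = FALSE]
  d <- d[!(d$site_a %in% exclude_sites) & !(d$site_b %in% exclude_sites), ,
         drop = FALSE]
  d <- d[is.finite(d$fst_linear), , drop = FALSE]
  if (nrow(d) == 0) stop("empty design after exclusions")
  d$metapopulation <- factor(d$metapopulation)
  d$dam_flag <- as.numeric(d$dam_flag)
  d$reservoir_flag <- as.numeric(d$reservoir_flag)
  rownames(d) <- NULL
  attr(d, "response") <- "fst_linear"
  d
}

#' @rdname build_pair_design
#' @param sites site table
#' @param hs [expected_heterozygosity()] output keyed by site
#' @param upstream [upstream_distance()] output
#' @export
build_site_design <- function(sites, hs, upstream) {
  d <- merge(sites, stats::setNames(hs[, c("group", "hs")],
                                    c("site_id", "hs")), by = "site_id")
  d <- merge(d, upstream[, c("site_id", "upstream_km")], by = "site_id")
  if (nrow(d) == 0) stop("empty design after joins")
  d$metapopulation <- factor(d$metapopulation)
  d$above_dam <- as.numeric(d$above_dam)
  d$reservoir_adjacent <- as.numeric(d$reservoir_adjacent)
  attr(d, "response") <- "hs"
  d
}

#' Ordinary least squares fit with Gaussian AIC and R-squared
#'
#' Thin wrapper over [stats::lm()] returning the pieces the model-search
#' machinery needs: coefficients with standard errors and p-values, the
#' Gaussian AIC `n*log(RSS/n) + n*log(2*pi) + n + 2k` (k counting
#' coefficients plus the variance), and R-squared. Note that per-term
#' p-values are not valid for pairwise-distance responses (rows are not
#' independent); use [permutation_r2_test()] there.
#'
#' @param design design data frame
#' @param terms character vector of model terms (may include `a:b`
#'   interactions); empty for the intercept-only model
#' @param response response column; default from the design attribute
#' @return list of class `model_fit`: `fit`, `terms`, `coefficients`,
#'   `aic`, `r2`, `n`
#' @export
fit_ols <- function(design, terms = character(0), response = NULL) {
  response <- response %||% attr(design, "response")
  if (is.null(response)) stop("no response column identified")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- as.formula(paste(response, "~", rhs))
  fit <- lm(f, data = design)
  if (fit$df.residual <= 0) stop("fewer residual df than 1; reduce terms")
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  structure(list(fit = fit, terms = terms, response = response,
                 coefficients = as.data.frame(sm$coefficients),
                 aic = AIC(fit), r2 = sm$r.squared, n = nrow(fit$model)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %s ~ %s\n  n = %d, R2 = %.4f, AIC = %.2f\n",
              x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$n, x$r2, x$aic))
  invisible(x)
}

# subsets of global terms respecting marginality: an interaction enters
# only when both of its main effects do
#' @keywords internal
#' @noRd
term_subsets <- function(global_terms) {
  is_int <- grepl(":", global_terms)
  mains <- global_terms[!is_int]
  ints <- global_terms[is_int]
  subs <- list(character(0))
  for (m in mains) subs <- c(subs, lapply(subs, c, m))
  out <- list()
  for (s in subs) {
    valid_ints <- ints[vapply(strsplit(ints, ":", fixed = TRUE),
                              function(p) all(p %in% s), logical(1))]
    isubs <- list(character(0))
    for (iv in valid_ints) isubs <- c(isubs, lapply(isubs, c, iv))
    for (is_ in isubs) out[[length(out) + 1]] <- c(s, is_)
  }
  out
}

#' Exhaustive AIC model selection over a global model
#'
#' Enumerates every subset of the global terms that respects marginality
#' (an interaction only with both main effects present), fits each by
#' OLS, ranks by AIC and reports delta-AIC. For each model the maximum
#' absolute pairwise correlation among its continuous predictors is
#' recorded as a collinearity screen.
#'
#' @param design design data frame
#' @param global_terms character vector; at most 20 terms
#' @param response response column; default from the design attribute
#' @return data frame of class `selection_table`, ranked by AIC, with
#'   columns `model`, `k`, `aic`, `delta_aic`, `r2`, `max_abs_cor`; the
#'   fitted [fit_ols()] objects are attached as attribute `fits`
#' @export
dredge_models <- function(design, global_terms, response = NULL) {
  if (length(global_terms) > 20) {
    stop("more than 20 candidate terms; reduce the global model")
  }
  subs <- term_subsets(global_terms)
  fits <- lapply(subs, function(s) fit_ols(design, s, response))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  cors <- vapply(subs, function(s) {
    mains <- unique(unlist(strsplit(s, ":", fixed = TRUE)))
    num <- mains[vapply(mains, function(m) is.numeric(design[[m]]),
                        logical(1))]
    if (length(num) < 2) return(0)
    cm <- cor(design[, num, drop = FALSE])
    max(abs(cm[upper.tri(cm)]))
  }, numeric(1))
  tab <- data.frame(
    model = vapply(subs, function(s)
      if (length(s)) paste(sort(s), collapse = " + ") else "(intercept)",
      character(1)),
    k = lengths(subs), aic = aics, r2 = r2s, max_abs_cor = cors,
    stringsAsFactors = FALSE)
  o <- order(tab$aic, tab$k)
  tab <- tab[o, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[o]
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Within-group permutation test of model R-squared
#'
#' Pairwise distance data are non-independent, so per-coefficient OLS
#' p-values overstate significance. Instead the response values are
#' randomly permuted among rows *within each group* (metapopulation),
#' the chosen model refitted, and the observed R-squared compared with
#' the permutation distribution. The p-value uses the add-one estimator
#' `(1 + #\{R2_perm >= R2_obs\}) / (n_perm + 1)`.
#'
#' @param design design data frame
#' @param terms model terms of the model under test
#' @param group column name holding the permutation groups (default
#'   `"metapopulation"`)
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @param response response column; default from the design attribute
#' @return list of class `permutation_result`: `r2_obs`, `r2_perm`,
#'   `p_value`, `n_perm`, `seed`
#' @export
permutation_r2_test <- function(design, terms, group = "metapopulation",
                                n_perm = 999, seed = 1, response = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  response <- response %||% attr(design, "response")
  obs <- fit_ols(design, terms, response)
  X <- stats::model.matrix(obs$fit)
  y <- design[[response]]
  gl <- as.character(design[[group]])
  idx_by_g <- split(seq_along(y), gl)
  r2_of <- function(yy) {
    fit <- stats::lm.fit(X, yy)
    1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
  }
  set.seed(seed)
  r2_perm <- vapply(seq_len(n_perm), function(b) {
    yy <- y
    for (ix in idx_by_g) yy[ix] <- yy[ix][sample.int(length(ix))]
    r2_of(yy)
  }, numeric(1))
  p <- (1 + sum(r2_perm >= obs$r2)) / (n_perm + 1)
  structure(list(r2_obs = obs$r2, r2_perm = r2_perm, p_value = p,
                 n_perm = n_perm, seed = seed, terms = terms),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: R2_obs = %.4f, permuted R2 in [%.4f, %.4f] (mean %.4f), p = %.4g (n_perm = %d)\n",
    x$r2_obs, min(x$r2_perm), max(x$r2_perm), mean(x$r2_perm),
    x$p_value, x$n_perm))
  invisible(x)
}
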