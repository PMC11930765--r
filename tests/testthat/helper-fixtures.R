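# Shared fixtures and independent oracle implementations. Oracles are
# deliberately written loop-wise from the textbook formulas, separate
# from the package's vectorized code paths.

make_gm <- function(dosage, chrom = NULL, pos = NULL, site = NULL) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  genotype_matrix(
    dosage,
    loci = data.frame(chrom = chrom %||% rep("chr1", L),
                      pos = pos %||% seq(1e4, by = 1e4, length.out = L)),
    individuals = data.frame(id = sprintf("i%02d", seq_len(nrow(dosage))),
                             site_id = site %||% rep("s1", nrow(dosage))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Y-shaped 3-edge network: two arms joining at node c, then to outlet o
y_network <- function(arm1 = 4, arm2 = 5, trunk = 6) {
  river_network(data.frame(
    edge_id = c("a1", "a2", "tr"),
    from_node = c("h1", "h2", "c"),
    to_node = c("c", "c", "o"),
    length_km = c(arm1, arm2, trunk),
    intermittent_fraction = c(1, 0, 0.5),
    cover_developed = 0.1, cover_grassland = 0.4,
    cover_cropland = 0.4, cover_forest = 0.1,
    barrier = c(TRUE, FALSE, FALSE)))
}

site_on <- function(site_id, edge_id, offset_km, metapop = "m1",
                    intermittent = FALSE, above_dam = FALSE,
                    reservoir = FALSE) {
  data.frame(site_id = site_id, metapopulation = metapop,
             edge_id = edge_id, offset_km = offset_km,
             intermittent = intermittent, above_dam = above_dam,
             reservoir_adjacent = reservoir,
             cover_developed = 0.1, cover_grassland = 0.4,
             cover_cropland = 0.4, cover_forest = 0.1,
             stringsAsFactors = FALSE)
}

# --- oracles ---------------------------------------------------------

# Nei / Nei-Chesser FST for two groups, straight transcription of the
# gene-diversity formulas, one locus at a time
oracle_nei_fst <- function(da, db, naive = FALSE) {
  L <- ncol(da)
  hs_l <- ht_l <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    xa <- da[, l][!is.na(da[, l])]; xb <- db[, l][!is.na(db[, l])]
    na <- length(xa); nb <- length(xb)
    if (na < 2 || nb < 2) next
    pa <- sum(xa) / (2 * na); pb <- sum(xb) / (2 * nb)
    hoa <- mean(xa == 1); hob <- mean(xb == 1)
    if (naive) {
      hs <- mean(c(1 - pa^2 - (1 - pa)^2, 1 - pb^2 - (1 - pb)^2))
      pm <- (pa + pb) / 2
      ht <- 1 - pm^2 - (1 - pm)^2
    } else {
      nh <- 2 / (1 / na + 1 / nb)
      msp <- mean(c(pa^2 + (1 - pa)^2, pb^2 + (1 - pb)^2))
      hom <- mean(c(hoa, hob))
      hs <- (nh / (nh - 1)) * (1 - msp - hom / (2 * nh))
      pm <- (pa + pb) / 2
      ht <- 1 - pm^2 - (1 - pm)^2 + hs / (nh * 2) - hom / (2 * nh * 2)
    }
    hs_l[l] <- hs; ht_l[l] <- ht
  }
  sum(ht_l - hs_l, na.rm = TRUE) / sum(ht_l, na.rm = TRUE)
}

# Weir & Cockerham theta for r groups, per-locus a/b/c components
oracle_wc_fst <- function(dlist) {
  r <- length(dlist)
  L <- ncol(dlist[[1]])
  num <- den <- 0
  for (l in seq_len(L)) {
    n <- p <- h <- numeric(r)
    ok <- TRUE
    for (k in seq_len(r)) {
      x <- dlist[[k]][, l][!is.na(dlist[[k]][, l])]
      if (length(x) < 2) { ok <- FALSE; break }
      n[k] <- length(x); p[k] <- sum(x) / (2 * length(x))
      h[k] <- mean(x == 1)
    }
    if (!ok) next
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Burrows composite r2 from the textbook estimator
# Delta = S/(S-1) * (sum(XY)/(2S) - 2*p*q)
oracle_burrows_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  S <- length(x)
  p <- sum(x) / (2 * S); q <- sum(y) / (2 * S)
  delta <- S / (S - 1) * (sum(x * y) / (2 * S) - 2 * p * q)
  delta^2 / (p * (1 - p) * q * (1 - q))
}

# OLS by explicit normal equations
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# marginality-respecting subset count by brute force over the power set
oracle_subset_count <- function(global_terms) {
  k <- length(global_terms)
  cnt <- 0
  for (mask in 0:(2^k - 1)) {
    s <- global_terms[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    ints <- s[grepl(":", s)]
    ok <- all(vapply(strsplit(ints, ":", fixed = TRUE),
                     function(p) all(p %in% s), logical(1)))
    if (ok) cnt <- cnt + 1
  }
  cnt
}

# SNP pruning oracle: same rules, independent bookkeeping
oracle_prune <- function(dosage, chrom, pos, min_call, maf_min,
                         prox, ld_thr) {
  L <- ncol(dosage)
  call <- colMeans(!is.na(dosage))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  alive <- call >= min_call & !is.na(maf) & maf >= maf_min
  for (ch in unique(chrom)) {
    last <- -Inf
    for (i in order(pos)[chrom[order(pos)] == ch]) {
      if (!alive[i]) next
      if (pos[i] - last < prox) alive[i] <- FALSE else last <- pos[i]
    }
  }
  idx <- which(alive)
  for (ai in seq_along(idx)) {
    for (bi in seq_along(idx)) {
      if (bi <= ai) next
      i <- idx[ai]; j <- idx[bi]
      if (!alive[i] || !alive[j] || chrom[i] != chrom[j]) next
      r <- suppressWarnings(cor(dosage[, i], dosage[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > ld_thr) {
        if (maf[i] < maf[j]) alive[i] <- FALSE else alive[j] <- FALSE
      }
    }
  }
  which(alive)
}

# splice sites into their edges as nodes; igraph shortest paths on the
# refined graph are an independent distance oracle
oracle_site_distances <- function(network, sites) {
  ed <- network$edges
  verts <- unique(c(ed$from_node, ed$to_node, sites$site_id))
  el <- list()
  for (i in seq_len(nrow(ed))) {
    on_e <- sites[sites$edge_id == ed$edge_id[i], , drop = FALSE]
    on_e <- on_e[order(on_e$offset_km), , drop = FALSE]
    chain <- c(ed$from_node[i], on_e$site_id, ed$to_node[i])
    offs <- c(0, on_e$offset_km, ed$length_km[i])
    for (k in seq_len(length(chain) - 1)) {
      el[[length(el) + 1]] <- data.frame(a = chain[k], b = chain[k + 1],
                                         w = offs[k + 1] - offs[k])
    }
  }
  el <- do.call(rbind, el)
  el <- el[el$w > 0 | el$a != el$b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::distances(g, v = sites$site_id, to = sites$site_id,
                    weights = el$w)
}
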