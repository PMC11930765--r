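# diversity and differentiation statistics

test_that("snp pruning applies proximity, MAF and LD rules", {
  # loci at 100 and 1500 on one chromosome, 2 kb proximity: second dropped
  gm <- make_gm(rbind(c(0, 0), c(1, 1), c(2, 2), c(1, 1)),
                pos = c(100, 1500))
  pr <- prune_snps(gm, min_call = 0, maf = 0, proximity_bp = 2000,
                   ld_threshold = 1)
  expect_equal(pr$loci$pos, 100)

  # near-duplicate columns (r2 ~ 0.8 > 0.5): the lower-MAF member dropped
  gm2 <- make_gm(cbind(c(0, 0, 1, 1, 2, 2),      # maf 0.5
                       c(0, 0, 1, 1, 2, 1)),     # maf 5/12
                 pos = c(1000, 50000))
  maf <- locus_maf(gm2)
  pr2 <- prune_snps(gm2, min_call = 0, maf = 0, proximity_bp = 0,
                    ld_threshold = 0.5)
  expect_equal(ncol(pr2$dosage), 1)
  expect_equal(pr2$loci$pos,
               gm2$loci$pos[which.max(maf)])

  # thresholds out of range error
  expect_error(prune_snps(gm, maf = 0.9), "maf")
  expect_error(prune_snps(gm, proximity_bp = -5), "proximity")
})

test_that("pruned locus set equals the brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    L <- 20
    chrom <- sort(sample(c("chr1", "chr2"), L, replace = TRUE))
    pos <- unlist(tapply(seq_len(L), chrom, function(ix)
      sort(sample.int(20000, length(ix)))))
    d <- matrix(rbinom(30 * L, 2, runif(L, 0.1, 0.9)[rep(1:L, each = 30)]),
                30, L)
    d[sample(length(d), 30)] <- NA
    gm <- make_gm(d, chrom = chrom, pos = as.numeric(pos))
    pr <- prune_snps(gm, min_call = 0.8, maf = 0.05,
                     proximity_bp = 2000, ld_threshold = 0.5)
    want <- oracle_prune(gm$dosage, gm$loci$chrom, gm$loci$pos,
                         0.8, 0.05, 2000, 0.5)
    expect_equal(paste(pr$loci$chrom, pr$loci$pos),
                 paste(gm$loci$chrom[want], gm$loci$pos[want]))
  }
})

test_that("expected heterozygosity matches hand evaluations", {
  # monomorphic locus
  gm <- make_gm(matrix(c(2, 2, 2, 2), 4))
  expect_equal(expected_heterozygosity(gm)$hs, 0)
  # AA, AB, AB, BB: Nei-Chesser (n/(n-1)) * (1 - sum(p^2) - Ho/(2n))
  #   = (4/3) * (1 - 0.5 - 0.5/8) = 7/12
  gm2 <- make_gm(matrix(c(0, 1, 1, 2), 4))
  expect_equal(expected_heterozygosity(gm2)$hs, 7 / 12)
  # naive mode at p = 0.5 gives 2pq = 0.5
  expect_equal(expected_heterozygosity(gm2, naive = TRUE)$hs, 0.5)
  # label swap invariance (0 <-> 2)
  set.seed(9)
  d <- matrix(rbinom(200, 2, 0.3), 20)
  expect_equal(expected_heterozygosity(make_gm(d))$hs,
               expected_heterozygosity(make_gm(2 - d))$hs)
  expect_error(expected_heterozygosity(make_gm(d), grouping = rep("g", 21)),
               "grouping")
})

test_that("pairwise FST reproduces hand-derived values", {
  # identical samples in both groups: FST ~ 0
  d <- rbind(c(0, 1, 2, 1), c(1, 2, 0, 1), c(0, 1, 2, 1), c(1, 2, 0, 1))
  gm <- make_gm(d, site = c("a", "a", "b", "b"))
  # make the two groups identical
  gm$dosage[3:4, ] <- gm$dosage[1:2, ]
  f <- pairwise_fst(gm, "site_id", "nei", naive = TRUE)
  expect_lt(abs(f$est["a", "b"]), 1e-12)

  # fixed alternative alleles: naive Nei FST = 1, linearized Inf
  gm2 <- make_gm(rbind(c(2, 2), c(2, 2), c(0, 0), c(0, 0)),
                 site = c("a", "a", "b", "b"))
  f2 <- pairwise_fst(gm2, "site_id", "nei", naive = TRUE)
  expect_equal(f2$est["a", "b"], 1)
  expect_equal(f2$linear["a", "b"], Inf)

  # p = 0.2 vs 0.8 in large equal samples: (0.5 - 0.32)/0.5 = 0.36
  n <- 500
  da <- matrix(rep(c(rep(0, 0.64 * n), rep(1, 0.32 * n), rep(2, 0.04 * n))), n, 1)
  db <- matrix(rep(c(rep(2, 0.64 * n), rep(1, 0.32 * n), rep(0, 0.04 * n))), n, 1)
  gm3 <- make_gm(rbind(da, db), site = rep(c("a", "b"), each = n))
  f3 <- pairwise_fst(gm3, "site_id", "nei", naive = TRUE)
  expect_equal(f3$est["a", "b"], 0.36, tolerance = 1e-12)
  expect_equal(f3$linear["a", "b"], 0.5625, tolerance = 1e-12)
})

test_that("both estimators agree with loop-wise oracles to 1e-12", {
  set.seed(11)
  for (rep in 1:4) {
    L <- 20
    sites <- rep(c("a", "b", "c", "d")[1:sample(2:4, 1)], each = 8)
    p <- matrix(runif(length(unique(sites)) * L, 0.05, 0.95),
                length(unique(sites)), L)
    d <- do.call(rbind, lapply(seq_along(unique(sites)), function(k) {
      matrix(rbinom(8 * L, 2, rep(p[k, ], each = 8)), 8, L)
    }))
    d[sample(length(d), 20)] <- NA
    gm <- make_gm(d, site = sites)
    gl <- sort(unique(sites))
    fw <- pairwise_fst(gm, "site_id", "wc")
    fn <- pairwise_fst(gm, "site_id", "nei")
    for (i in 1:(length(gl) - 1)) for (j in (i + 1):length(gl)) {
      da <- gm$dosage[sites == gl[i], , drop = FALSE]
      db <- gm$dosage[sites == gl[j], , drop = FALSE]
      expect_equal(fw$est[gl[i], gl[j]], oracle_wc_fst(list(da, db)),
                   tolerance = 1e-12)
      expect_equal(fn$est[gl[i], gl[j]], oracle_nei_fst(da, db),
                   tolerance = 1e-12)
    }
  }
})

test_that("FST rises with divergence time in the simulator", {
  cfg0 <- sim_config(seed = 5, n_metapops = 1, sites_per_metapop = 2,
                     deme_size = 50, m0 = 0, n_loci = 150, sample_size = 15)
  tgrid <- c(5, 20, 60, 150)
  med <- vapply(tgrid, function(tt) {
    f <- vapply(1:6, function(r) {
      cfg <- sim_config(seed = 100 * r + tt, n_metapops = 1,
                        sites_per_metapop = 2, deme_size = 50, m0 = 0,
                        n_generations = tt, n_loci = 150, sample_size = 15)
      dat <- simulate_dataset(cfg)
      pairwise_fst(dat$genotypes, "site_id", "wc")$est[1, 2]
    }, numeric(1))
    median(f)
  }, numeric(1))
  expect_gt(cor(med, tgrid, method = "spearman"), 0.9)
})

test_that("bootstrap CIs are seeded, degenerate when loci agree, and match the oracle", {
  # loci with identical per-locus components give a zero-width CI
  d <- rbind(c(0, 0), c(1, 1), c(2, 2), c(2, 2), c(0, 0), c(1, 1))
  gm <- make_gm(d, chrom = c("chr1", "chr2"), site = c("a", "a", "a", "b", "b", "b"))
  ci <- bootstrap_fst_ci(gm, "site_id", "wc", n_boot = 50, seed = 3)
  expect_equal(ci$ci_lower["a", "b"], ci$ci_upper["a", "b"])
  expect_equal(ci$ci_lower["a", "b"], ci$est["a", "b"])

  set.seed(2)
  d2 <- matrix(rbinom(20 * 50, 2, rep(runif(50, 0.2, 0.8), each = 20)), 20, 50)
  gm2 <- make_gm(d2, site = rep(c("a", "b"), each = 10))
  ci1 <- bootstrap_fst_ci(gm2, "site_id", "nei", n_boot = 100, seed = 7)
  ci2 <- bootstrap_fst_ci(gm2, "site_id", "nei", n_boot = 100, seed = 7)
  expect_identical(ci1$ci_lower, ci2$ci_lower)

  # oracle: same resampling scheme re-derived from per-locus Hs/Ht sums
  set.seed(7)
  da <- gm2$dosage[1:10, ]; db <- gm2$dosage[11:20, ]
  L <- ncol(da)
  reps <- vapply(1:100, function(b) {
    idx <- sample.int(L, L, replace = TRUE)
    oracle_nei_fst(da[, idx, drop = FALSE], db[, idx, drop = FALSE])
  }, numeric(1))
  q <- quantile(reps, c(0.025, 0.975), names = FALSE)
  expect_equal(ci1$ci_lower["a", "b"], q[1], tolerance = 1e-12)
  expect_equal(ci1$ci_upper["a", "b"], q[2], tolerance = 1e-12)
  expect_error(bootstrap_fst_ci(gm2, n_boot = 1), "n_boot")
})

test_that("individual heterozygosity counts het calls over non-missing loci", {
  gm <- make_gm(rbind(c(1, 1, 1, 1), c(0, 1, 2, NA), c(NA, NA, NA, NA)),
                chrom = rep("chr1", 4))
  expect_warning(h <- individual_heterozygosity(gm), "zero genotyped")
  expect_equal(h$heterozygosity[1], 1)
  expect_equal(h$heterozygosity[2], 1 / 3)
  expect_true(is.na(h$heterozygosity[3]))
  # brute-force count on a random fixture
  set.seed(14)
  d <- matrix(sample(c(0, 1, 2, NA), 5 * 30, TRUE), 5, 30)
  gm2 <- make_gm(d)
  h2 <- individual_heterozygosity(gm2)
  for (i in 1:5) {
    expect_equal(h2$heterozygosity[i],
                 sum(d[i, ] == 1, na.rm = TRUE) / sum(!is.na(d[i, ])))
  }
})
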