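# ROH detection, effect classification, load and SV summaries

roh_gm <- function(dosage_list, pos, chrom = "chr1") {
  # dosage_list: one vector per individual over shared positions
  make_gm(do.call(rbind, dosage_list), chrom = rep(chrom, length(pos)),
          pos = pos)
}

test_that("an all-heterozygous individual yields no ROH segments", {
  pos <- sort(sample.int(1e6, 600))
  gm <- roh_gm(list(rep(1, 600)), pos)
  out <- detect_roh(gm)
  expect_equal(nrow(out$segments), 0)
  expect_equal(out$summary$pct_genome, 0)
})

test_that("planted tracts are recovered and sub-threshold tracts rejected", {
  ind <- data.frame(id = c("A", "B"), metapopulation = "m1",
                    heterozygosity = 0.35, divergence_time = 1)
  plants <- data.frame(individual = c("A", "A"),
                       chrom = c("chr1", "chr2"),
                       start = c(6e5, 4e5), length = c(2e5, 9e4))
  g <- simulate_genomes(ind, n_chroms = 2, chrom_length_bp = 2e6,
                        snp_density = 1 / 1000, roh_plants = plants,
                        epsilon = 0, seed = 9)
  out <- detect_roh(g$calls)
  seg_a <- out$segments[out$segments$individual == "A", ]
  # exactly one segment: the 200 kb tract on chr1; the 90 kb tract on
  # chr2 is below the 100 kb minimum
  expect_equal(seg_a$chrom, "chr1")
  expect_equal(nrow(seg_a), 1)
  overlap <- min(seg_a$end, 8e5 - 1) - max(seg_a$start, 6e5) + 1
  expect_gte(overlap / 2e5, 0.9)
  expect_equal(nrow(out$segments[out$segments$individual == "B", ]), 0)
})

test_that("segments never overlap and are invariant to chromosome order", {
  ind <- data.frame(id = "A", metapopulation = "m1", heterozygosity = 0.3,
                    divergence_time = 1)
  plants <- data.frame(individual = "A", chrom = c("chr1", "chr1"),
                       start = c(2e5, 9e5), length = c(2e5, 3e5))
  g <- simulate_genomes(ind, n_chroms = 2, chrom_length_bp = 2e6,
                        roh_plants = plants, epsilon = 0.001, seed = 10)
  out <- detect_roh(g$calls)
  seg <- out$segments[order(out$segments$start), ]
  if (nrow(seg) > 1) {
    expect_true(all(seg$start[-1] > seg$end[-nrow(seg)] |
                      seg$chrom[-1] != seg$chrom[-nrow(seg)]))
  }
  # reorder chromosomes: identical segment set
  gm2 <- g$calls
  ord <- order(match(gm2$loci$chrom, c("chr2", "chr1")), gm2$loci$pos)
  gm2 <- subset_genotypes(gm2, loci = ord)
  out2 <- detect_roh(gm2)
  key <- function(s) paste(s$individual, s$chrom, s$start, s$end)
  expect_setequal(key(out2$segments), key(out$segments))
})

test_that("short chromosomes are skipped and unsorted input rejected", {
  pos <- sort(sample.int(1e5, 50))
  gm <- roh_gm(list(rep(0, 50)), pos)
  expect_message(out <- detect_roh(gm), "skipped")
  expect_equal(nrow(out$segments), 0)
  gm_bad <- roh_gm(list(rep(0, 200)), sort(sample.int(1e6, 200)))
  gm_bad$loci$pos[5] <- gm_bad$loci$pos[10] + 1  # corrupt sortedness
  expect_error(detect_roh(gm_bad), "sorted")
})

test_that("effect terms map to their impact classes", {
  expect_equal(as.character(classify_effects(
    c("stop_gained", "frameshift_variant", "splice_donor_variant"))),
    rep("high", 3))
  expect_equal(as.character(classify_effects("missense_variant")), "moderate")
  expect_equal(as.character(classify_effects("synonymous_variant")), "low")
  expect_equal(as.character(classify_effects("intergenic_region")), "modifier")
  expect_message(
    cl <- classify_effects(c("weird_term", "missense_variant&weird_term")),
    "outside the mapping")
  expect_equal(as.character(cl), c("modifier", "moderate"))
})

test_that("load proportions: hand fixture recovers slope 0.2 exactly", {
  # counts 2/100, 4/100, 6/100 at heterozygosity 0.1/0.2/0.3
  L_eff <- 10; L_mod <- 100
  eff_terms <- c(rep("missense_variant", L_eff),
                 rep("intergenic_region", L_mod))
  mk_row <- function(n_alt) c(rep(1, n_alt), rep(0, L_eff - n_alt),
                              rep(0, L_mod))
  d <- rbind(mk_row(2), mk_row(4), mk_row(6))
  gm <- make_gm(d, chrom = rep("chr1", L_eff + L_mod),
                pos = seq(1e4, by = 1e4, length.out = L_eff + L_mod))
  gm$loci$effect <- eff_terms[order(seq_along(eff_terms))]
  # loci were sorted by pos at construction; positions are already ordered
  lp <- suppressWarnings(   # summary.lm flags the exact fit
    load_proportions(gm, heterozygosity = c(0.1, 0.2, 0.3)))
  expect_equal(lp$table$deleterious_proportion, c(0.02, 0.04, 0.06))
  expect_equal(lp$fit$slope, 0.2, tolerance = 1e-12)
})

test_that("class counts are dosage-weighted and conserved", {
  terms <- c("stop_gained", "missense_variant", "synonymous_variant",
             "intergenic_region")
  d <- rbind(c(2, 1, 0, 1), c(0, 2, 2, 2))
  gm <- make_gm(d, chrom = rep("chr1", 4))
  gm$loci$effect <- terms
  lp <- suppressWarnings(load_proportions(gm))
  tab <- lp$table
  expect_equal(tab$high, c(2, 0))
  expect_equal(tab$moderate, c(1, 2))
  expect_equal(tab$low, c(0, 2))
  expect_equal(tab$modifier, c(1, 2))
  # conservation: class counts sum to total non-missing alleles
  expect_equal(tab$high + tab$moderate + tab$low + tab$modifier,
               rowSums(d))
  # zero coding-class alleles -> proportion 0
  gm0 <- make_gm(rbind(c(0, 0, 0, 2)), chrom = rep("chr1", 4))
  gm0$loci$effect <- terms
  lp0 <- load_proportions(gm0, heterozygosity = 0.2)
  expect_equal(lp0$table$deleterious_proportion, 0)
})

test_that("SV summaries count types, pair breakends and take medians", {
  rec <- data.frame(
    id = c("d1", "d2", "d3", "i1", "i2", "b1", "b2", "b3", "b4", "u1"),
    chrom = "chr1", pos = 1:10 * 100,
    sv_type = c("DEL", "DEL", "DEL", "INS", "INS", rep("BND", 4), "DUP"),
    sv_len = c(-50, -95, -975, 60, 120, NA, NA, NA, NA, 80),
    mate_id = c(NA, NA, NA, NA, NA, "b2", "b1", "b4", "b3", NA),
    stringsAsFactors = FALSE)
  car <- matrix(1, 1, 10, dimnames = list("A", rec$id))
  sv <- summarize_svs(list(records = rec, carriers = car))
  expect_equal(sv$per_individual$n_indels, 5)
  expect_equal(sv$per_individual$n_breakend_events, 2)
  expect_equal(sv$per_individual$n_duplications, 1)
  expect_equal(sv$median_indel_bp, 95)

  # unpaired breakend counts singly with a warning
  rec2 <- rec; rec2$mate_id[rec2$id == "b4"] <- "missing"
  expect_warning(sv2 <- summarize_svs(list(records = rec2, carriers = car)),
                 "without a mate")
  expect_equal(sv2$per_individual$n_breakend_events, 1 + 2 * 1)
})

test_that("SV size floor drops sub-threshold indels", {
  rec <- data.frame(id = c("a", "b"), chrom = "chr1", pos = c(1, 2),
                    sv_type = c("DEL", "INS"), sv_len = c(-30, 70),
                    mate_id = NA_character_, stringsAsFactors = FALSE)
  car <- matrix(1, 1, 2, dimnames = list("A", rec$id))
  sv <- summarize_svs(list(records = rec, carriers = car), min_sv_len = 50)
  expect_equal(sv$per_individual$n_indels, 1)
  expect_equal(sv$indel_lengths, 70)
})
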