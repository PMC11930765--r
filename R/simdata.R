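#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic riverscape
#' generator. Defaults emulate a fragmented Great Plains stream system:
#' several strongly diverged drainage metapopulations (drainage-level
#' FST spanning roughly 0.08 to > 0.8), within-drainage isolation by
#' distance modulated by stream intermittency and barriers, and deme
#' effective sizes from tens to hundreds.
#'
#' @param seed integer seed
#' @param n_metapops number of drainage metapopulations
#' @param sites_per_metapop sites (demes) per metapopulation
#' @param deme_size diploid deme size N; scalar or one per
#'   metapopulation (default: a geometric ramp from 12 to 400)
#' @param m0 baseline per-generation migration rate between demes
#' @param lambda_km exponential distance-decay scale of migration (km)
#' @param psi intermittency penalty in (0, 1]: migration is multiplied
#'   by `psi ^ (proportion of intermittent stream on the path)`
#' @param beta barrier penalty in (0, 1]: multiplied per barrier crossed
#' @param n_generations forward generations T
#' @param n_loci unlinked SNP loci L
#' @param sample_size individuals sampled per site S
#' @param ancestral_freq function(n) drawing ancestral allele frequencies
#' @param edge_length_meanlog,edge_length_sdlog lognormal edge lengths (km)
#' @param connector_km length of the mainstem edges joining drainages
#' @param intermittent_prob probability an edge is largely intermittent
#' @param barrier_prob probability a headwater edge carries a barrier
#' @param cover_alpha Dirichlet concentration for the four cover classes
#' @param edges_per_metapop tributary edges per drainage tree (default
#'   `sites_per_metapop + 1`, so every site can sit on its own edge)
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       n_metapops = 4,
                       sites_per_metapop = 8,
                       deme_size = NULL,
                       m0 = 0.03,
                       lambda_km = 30,
                       psi = 0.1,
                       beta = 0.3,
                       n_generations = 600,
                       n_loci = 300,
                       sample_size = 20,
                       ancestral_freq = function(n) runif(n, 0.1, 0.9),
                       edge_length_meanlog = log(8),
                       edge_length_sdlog = 0.5,
                       connector_km = 250,
                       intermittent_prob = 0.4,
                       barrier_prob = 0.2,
                       cover_alpha = c(developed = 0.6, grassland = 2.5,
                                       cropland = 2.5, forest = 0.6),
                       edges_per_metapop = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$deme_size)) {
    # geometric ramp from small to large drainages, emulating strong
    # variation in drift intensity across the range
    cfg$deme_size <- round(exp(seq(log(12), log(400),
                                   length.out = cfg$n_metapops)))
  }
  stopifnot(cfg$n_metapops >= 1, cfg$sites_per_metapop >= 1,
            all(cfg$deme_size >= 1), cfg$n_generations >= 0,
            cfg$n_loci >= 1, cfg$sample_size >= 1,
            cfg$m0 >= 0, cfg$lambda_km > 0,
            cfg$psi > 0, cfg$psi <= 1, cfg$beta > 0, cfg$beta <= 1)
  if (length(cfg$deme_size) == 1) {
    cfg$deme_size <- rep(cfg$deme_size, cfg$n_metapops)
  }
  if (length(cfg$deme_size) != cfg$n_metapops) {
    stop("deme_size must be scalar or length n_metapops")
  }
  if (cfg$m0 * (cfg$n_metapops * cfg$sites_per_metapop - 1) > 1) {
    stop("m0 too large: total emigration could exceed 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic dendritic river network with sites
#'
#' Builds one random dendritic tree per metapopulation by recursive
#' tributary attachment (each new edge joins a uniformly chosen existing
#' node, so every node keeps a single downstream edge), joins drainage
#' outlets along a long mainstem so the network is a single connected
#' tree, draws lognormal edge lengths, per-edge intermittency, Dirichlet
#' land-cover fractions and barrier flags on a subset of headwater
#' edges, and places sites at random offsets on within-drainage edges.
#'
#' @param config a [sim_config()]
#' @return list with `network` (a [river_network()]) and `sites` (a site
#'   table)
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_edges_per <- config$edges_per_metapop %||%
    max(config$sites_per_metapop + 1, 4)
  edges <- list(); sites <- list()
  prev_outlet <- NULL
  for (mp in seq_len(config$n_metapops)) {
    pref <- sprintf("d%d", mp)
    nodes <- paste0(pref, "_n", 1:2)
    e <- data.frame(edge_id = paste0(pref, "_e1"),
                    from_node = nodes[2], to_node = nodes[1],
                    stringsAsFactors = FALSE)
    for (k in 2:n_edges_per) {
      attach_to <- sample(nodes, 1)
      newn <- paste0(pref, "_n", length(nodes) + 1)
      nodes <- c(nodes, newn)
      e <- rbind(e, data.frame(edge_id = paste0(pref, "_e", k),
                               from_node = newn, to_node = attach_to,
                               stringsAsFactors = FALSE))
    }
    e$length_km <- rlnorm(nrow(e), config$edge_length_meanlog,
                          config$edge_length_sdlog)
    intermit <- runif(nrow(e)) < config$intermittent_prob
    e$intermittent_fraction <- ifelse(intermit, runif(nrow(e), 0.5, 1),
                                      runif(nrow(e), 0, 0.1))
    cov <- rdirichlet(nrow(e), config$cover_alpha)
    e$cover_developed <- cov[, 1]; e$cover_grassland <- cov[, 2]
    e$cover_cropland <- cov[, 3]; e$cover_forest <- cov[, 4]
    headwater <- !(e$from_node %in% e$to_node)
    e$barrier <- headwater & runif(nrow(e)) < config$barrier_prob
    edges[[mp]] <- e

    if (config$sites_per_metapop > nrow(e)) {
      stop("infeasible site count for tree size")
    }
    on_edges <- sample(e$edge_id, config$sites_per_metapop)
    idx <- match(on_edges, e$edge_id)
    sites[[mp]] <- data.frame(
      site_id = sprintf("%s_s%02d", pref, seq_len(config$sites_per_metapop)),
      metapopulation = sprintf("metapop%d", mp),
      edge_id = on_edges,
      offset_km = runif(config$sites_per_metapop) * e$length_km[idx],
      intermittent = e$intermittent_fraction[idx] > 0.5,
      above_dam = e$barrier[idx],
      reservoir_adjacent = FALSE,
      cover_developed = e$cover_developed[idx],
      cover_grassland = e$cover_grassland[idx],
      cover_cropland = e$cover_cropland[idx],
      cover_forest = e$cover_forest[idx],
      stringsAsFactors = FALSE)
  }
  # mainstem connectors: drainage mp's outlet (node d<mp>_n1) flows into
  # the previous drainage's outlet, keeping one global outlet
  conn <- list()
  for (mp in seq_len(config$n_metapops)[-1]) {
    conn[[mp - 1]] <- data.frame(
      edge_id = sprintf("conn_e%d", mp - 1),
      from_node = sprintf("d%d_n1", mp),
      to_node = sprintf("d%d_n1", mp - 1),
      length_km = config$connector_km,
      intermittent_fraction = 0.5,
      cover_developed = 0.25, cover_grassland = 0.25,
      cover_cropland = 0.25, cover_forest = 0.25,
      barrier = FALSE, stringsAsFactors = FALSE)
  }
  all_edges <- do.call(rbind, c(edges, conn))
  net <- river_network(all_edges)
  site_tab <- do.call(rbind, sites)
  rownames(site_tab) <- NULL
  list(network = net, sites = place_sites(net, site_tab))
}

#' Migration matrix over sites from network geometry
#'
#' `m[i, j] = m0 * exp(-d_ij / lambda) * psi^(intermittent path
#' fraction) * beta^(barriers crossed)` for i != j, with the residual on
#' the diagonal. Errors if any row's emigration exceeds 1.
#'
#' @param network a [river_network()]
#' @param sites site table
#' @param config a [sim_config()]
#' @return row-stochastic matrix, sites in table order
#' @export
migration_matrix <- function(network, sites, config) {
  n <- nrow(sites)
  M <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pc <- path_covariates(network, sites, sites$site_id[i], sites$site_id[j])
    m <- config$m0 * exp(-pc$distance_km / config$lambda_km) *
      config$psi^pc$prop_intermittent * config$beta^pc$barriers_crossed
    M[i, j] <- M[j, i] <- m
  }
  emig <- rowSums(M)
  if (any(emig > 1)) {
    stop("migration matrix row sum exceeds 1 for site(s): ",
         paste(sites$site_id[emig > 1], collapse = ", "))
  }
  diag(M) <- 1 - emig
  M
}

#' Simulate genotypes under a stepping-stone Wright-Fisher model
#'
#' Frequency-based forward simulation: each generation, deme allele
#' frequencies are mixed by the migration matrix and then drift by
#' binomial sampling of 2N gametes; after T generations, S diploids per
#' site are drawn with Hardy-Weinberg genotypes. Loci are unlinked and
#' independent. All simulation parameters are retained in a `truth`
#' attribute.
#'
#' @param network a [river_network()]
#' @param sites site table
#' @param config a [sim_config()]
#' @return a [genotype_matrix()] with attribute `truth`
#' @export
simulate_genotypes <- function(network, sites, config) {
  stopifnot(inherits(config, "sim_config"))
  M <- migration_matrix(network, sites, config)
  set.seed(config$seed + 1)
  n <- nrow(sites); L <- config$n_loci
  mp_index <- match(sites$metapopulation,
                    sprintf("metapop%d", seq_len(config$n_metapops)))
  N <- config$deme_size[mp_index]
  p0 <- config$ancestral_freq(L)
  p <- matrix(rep(p0, each = n), n, L)
  t <- 0
  while (t < config$n_generations) {
    p <- pmin(pmax(M %*% p, 0), 1)   # guard fp drift in the row sums
    p <- matrix(rbinom(n * L, 2 * N, p) / (2 * N), n, L)
    t <- t + 1
  }
  S <- config$sample_size
  dos <- matrix(NA_real_, n * S, L)
  for (i in seq_len(n)) {
    dos[(i - 1) * S + seq_len(S), ] <-
      matrix(rbinom(S * L, 2, rep(p[i, ], each = S)), S, L)
  }
  ind <- data.frame(id = sprintf("%s_i%02d", rep(sites$site_id, each = S),
                                 rep(seq_len(S), n)),
                    site_id = rep(sites$site_id, each = S),
                    metapopulation = rep(sites$metapopulation, each = S),
                    stringsAsFactors = FALSE)
  loci <- data.frame(chrom = sprintf("chr%d", rep(seq_len(10), length.out = L)),
                     pos = 10000 * (seq_len(L) %/% 10 + 1) + seq_len(L),
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, loci, ind)
  attr(gm, "truth") <- list(config = unclass(config), final_freqs = p,
                            ancestral = p0, migration = M, deme_size = N)
  gm
}

#' Individual-based Wright-Fisher deme
#'
#' Forward simulation of a single closed random-mating deme of N
#' diploids with L unlinked loci and Mendelian segregation. Unlike the
#' frequency-based stepping-stone engine, finite parent numbers generate
#' genuine drift linkage disequilibrium among unlinked loci, which is
#' the signal the LD method for effective population size estimates.
#'
#' @param N diploid population size (the true Ne under random mating)
#' @param S diploids sampled at the end (S <= N)
#' @param L unlinked loci
#' @param T_gen generations to run
#' @param seed integer seed
#' @param p0 optional ancestral frequencies (default Unif(0.2, 0.8))
#' @return a [genotype_matrix()] with one pseudo-chromosome per locus
#'   (loci are unlinked)
#' @export
simulate_wf_deme <- function(N, S, L, T_gen, seed = 1, p0 = NULL) {
  stopifnot(S <= N, N >= 2)
  set.seed(seed)
  if (is.null(p0)) p0 <- runif(L, 0.2, 0.8)
  G <- matrix(rbinom(N * L, 2, rep(p0, each = N)), N, L)
  gamete <- function(H) {
    (H == 2) + (H == 1) * matrix(rbinom(length(H), 1, 0.5), nrow(H))
  }
  for (t in seq_len(T_gen)) {
    mo <- sample.int(N, N, replace = TRUE)
    fa <- sample.int(N, N, replace = TRUE)
    G <- gamete(G[mo, , drop = FALSE]) + gamete(G[fa, , drop = FALSE])
  }
  take <- sample.int(N, S)
  loci <- data.frame(chrom = sprintf("u%04d", seq_len(L)), pos = 1L)
  ind <- data.frame(id = sprintf("ind%03d", seq_len(S)), site_id = "deme",
                    stringsAsFactors = FALSE)
  genotype_matrix(G[take, , drop = FALSE], loci, ind)
}

#' Simulate per-individual genomes with planted ROH, effect classes and
#' structural variants
#'
#' SNPs are placed uniformly at random at `snp_density` along each
#' chromosome, shared across individuals. Each individual is
#' heterozygous at a SNP with its baseline probability, except inside a
#' planted run-of-homozygosity tract where heterozygotes occur at error
#' rate `epsilon`. Each SNP is assigned an effect class with
#' `effect_class_probs`; per-individual alternate-allele frequencies at
#' effect-class loci are tuned so the expected deleterious proportion
#' follows `load_intercept + load_slope * heterozygosity`. Per-individual
#' structural-variant counts are Poisson with mean
#' `sv_base + sv_rate_slope * divergence_time`.
#'
#' @param individuals data frame: `id`, `metapopulation`,
#'   `heterozygosity` (baseline per-SNP het probability),
#'   `divergence_time` (e.g. Myr to the reference lineage)
#' @param n_chroms,chrom_length_bp,snp_density genome panel layout
#' @param roh_plants data frame `individual`, `chrom`, `start`,
#'   `length` of forced-homozygous tracts (may be empty)
#' @param epsilon per-SNP heterozygote error rate inside planted tracts
#' @param effect_class_probs named probabilities for classes
#'   `high`, `moderate`, `low`, `modifier` (sums to 1)
#' @param load_intercept,load_slope planted linear relation between
#'   individual heterozygosity and deleterious proportion
#' @param sv_base,sv_rate_slope Poisson mean of per-individual SV count
#'   as a linear function of divergence time
#' @param sv_type_probs probabilities of `indel`, `bnd`, `dup` records
#' @param seed integer seed
#' @return list: `calls` (a [genotype_matrix()] with `effect` in loci),
#'   `sv` (`records` + `carriers` as in [read_vcf()]), `truth`
#' @export
simulate_genomes <- function(individuals,
                             n_chroms = 2,
                             chrom_length_bp = 2e6,
                             snp_density = 1 / 1000,
                             roh_plants = NULL,
                             epsilon = 0.001,
                             effect_class_probs = c(high = 0.00026,
                                                    moderate = 0.01163,
                                                    low = 0.01671,
                                                    modifier = 0.9714),
                             load_intercept = 0.02,
                             load_slope = 0.05,
                             sv_base = 30,
                             sv_rate_slope = 40,
                             sv_type_probs = c(indel = 0.85, bnd = 0.1,
                                               dup = 0.05),
                             seed = 1) {
  stopifnot(abs(sum(effect_class_probs) - 1) < 1e-8,
            all(effect_class_probs >= 0), epsilon >= 0, epsilon <= 1)
  set.seed(seed)
  if (is.null(individuals$heterozygosity)) individuals$heterozygosity <- 0.2
  if (is.null(individuals$divergence_time)) individuals$divergence_time <- 1
  n_ind <- nrow(individuals)
  if (!is.null(roh_plants) && nrow(roh_plants)) {
    key <- split(roh_plants, list(roh_plants$individual, roh_plants$chrom),
                 drop = TRUE)
    for (k in key) {
      if (nrow(k) > 1) {
        o <- order(k$start)
        ends <- k$start[o] + k$length[o] - 1
        if (any(k$start[o][-1] <= ends[-nrow(k)])) {
          stop("overlapping planted ROH tracts for individual ",
               k$individual[1], " on ", k$chrom[1])
        }
      }
    }
  }

  n_per <- round(chrom_length_bp * snp_density)
  loci <- do.call(rbind, lapply(seq_len(n_chroms), function(ch) {
    data.frame(chrom = sprintf("chr%d", ch),
               pos = sort(sample.int(chrom_length_bp, n_per)),
               stringsAsFactors = FALSE)
  }))
  L <- nrow(loci)
  classes <- c("high", "moderate", "low", "modifier")
  cls <- classes[apply(rmultinom(L, 1, effect_class_probs), 2, which.max)]
  term_map <- c(high = "stop_gained", moderate = "missense_variant",
                low = "synonymous_variant", modifier = "intergenic_region")
  loci$effect <- unname(term_map[cls])

  eff <- cls != "modifier"
  n_eff <- sum(eff); n_mod <- sum(!eff)
  dos <- matrix(NA_real_, n_ind, L)
  for (i in seq_len(n_ind)) {
    h <- individuals$heterozygosity[i]
    phet <- rep(h, L)
    in_tract <- rep(FALSE, L)
    if (!is.null(roh_plants) && nrow(roh_plants)) {
      mine <- roh_plants[roh_plants$individual == individuals$id[i], ,
                         drop = FALSE]
      for (r in seq_len(nrow(mine))) {
        inside <- loci$chrom == mine$chrom[r] &
          loci$pos >= mine$start[r] &
          loci$pos <= mine$start[r] + mine$length[r] - 1
        phet[inside] <- epsilon
        in_tract <- in_tract | inside
      }
    }
    is_het <- rbinom(L, 1, phet) == 1
    hom <- 2 * rbinom(L, 1, 0.5)
    g <- ifelse(is_het, 1, hom)
    # plant the heterozygosity-load relation at effect-class loci;
    # planted ROH tracts keep their (near-)homozygous genotypes
    free <- eff & !in_tract
    if (any(free)) {
      q <- load_intercept + load_slope * h
      f <- min(max(q * n_mod / (2 * sum(free)), 0), 1)
      g[free] <- rbinom(sum(free), 2, f)
    }
    dos[i, ] <- g
  }
  ind_meta <- data.frame(id = individuals$id,
                         site_id = individuals$metapopulation,
                         stringsAsFactors = FALSE)
  calls <- genotype_matrix(dos, loci, ind_meta)

  # structural variants: per-individual records
  recs <- list(); owner <- integer(0)
  for (i in seq_len(n_ind)) {
    lam <- sv_base + sv_rate_slope * individuals$divergence_time[i]
    n_sv <- rpois(1, max(lam, 0))
    if (n_sv == 0) next
    type <- sample(c("indel", "bnd", "dup"), n_sv, replace = TRUE,
                   prob = sv_type_probs)
    n_bnd <- sum(type == "bnd")
    if (n_bnd %% 2 == 1) { type[which(type == "bnd")[1]] <- "indel" }
    df <- data.frame(
      id = sprintf("sv_%s_%03d", individuals$id[i], seq_len(n_sv)),
      chrom = sprintf("chr%d", sample.int(n_chroms, n_sv, replace = TRUE)),
      pos = sample.int(chrom_length_bp, n_sv, replace = TRUE),
      sv_type = NA_character_, sv_len = NA_real_, mate_id = NA_character_,
      stringsAsFactors = FALSE)
    isz <- pmin(pmax(round(rlnorm(n_sv, log(95), 0.55)), 50), 975)
    ins <- type == "indel" & runif(n_sv) < 0.5
    df$sv_type[type == "indel"] <- ifelse(ins[type == "indel"], "INS", "DEL")
    df$sv_len[type == "indel"] <- ifelse(ins[type == "indel"], 1, -1) *
      isz[type == "indel"]
    df$sv_type[type == "dup"] <- "DUP"
    df$sv_len[type == "dup"] <- isz[type == "dup"]
    bnd_idx <- which(type == "bnd")
    if (length(bnd_idx)) {
      df$sv_type[bnd_idx] <- "BND"
      a <- bnd_idx[seq(1, length(bnd_idx), by = 2)]
      b <- bnd_idx[seq(2, length(bnd_idx), by = 2)]
      df$mate_id[a] <- df$id[b]
      df$mate_id[b] <- df$id[a]
    }
    recs[[length(recs) + 1]] <- df
    owner <- c(owner, rep(i, n_sv))
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = character(0), chrom = character(0), pos = numeric(0),
               sv_type = character(0), sv_len = numeric(0),
               mate_id = character(0), stringsAsFactors = FALSE)
  carriers <- matrix(0, n_ind, nrow(records),
                     dimnames = list(individuals$id, records$id))
  if (nrow(records)) carriers[cbind(owner, seq_len(nrow(records)))] <- 1

  list(calls = calls,
       sv = list(records = records, carriers = carriers),
       truth = list(individuals = individuals, roh_plants = roh_plants,
                    epsilon = epsilon, effect_class_probs = effect_class_probs,
                    load_intercept = load_intercept, load_slope = load_slope,
                    sv_base = sv_base, sv_rate_slope = sv_rate_slope,
                    seed = seed, classes = cls))
}

#' One-call synthetic dataset: network, sites and genotypes
#'
#' Convenience wrapper chaining [generate_network()] and
#' [simulate_genotypes()].
#'
#' @param config a [sim_config()]
#' @return list `network`, `sites`, `genotypes`
#' @export
simulate_dataset <- function(config = sim_config()) {
  nw <- generate_network(config)
  gm <- simulate_genotypes(nw$network, nw$sites, config)
  list(network = nw$network, sites = nw$sites, genotypes = gm)
}
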