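#' @keywords internal
#' @noRd
site_row <- function(sites, site_id) {
  i <- match(site_id, sites$site_id)
  if (is.na(i)) stop("unknown site: ", site_id)
  sites[i, , drop = FALSE]
}

# geodesic between two points on the network tree, with per-edge
# traversed lengths (partial host edges included)
#' @keywords internal
#' @noRd
point_path <- function(network, sites, site_a, site_b) {
  ea <- site_row(sites, site_a); eb <- site_row(sites, site_b)
  ia <- match(ea$edge_id, network$edges$edge_id)
  ib <- match(eb$edge_id, network$edges$edge_id)
  la <- network$edges$length_km[ia]; lb <- network$edges$length_km[ib]
  oa <- ea$offset_km; ob <- eb$offset_km
  if (oa < 0 || oa > la || ob < 0 || ob > lb) {
    stop("site offset beyond edge length")
  }
  if (ia == ib) {
    d <- abs(oa - ob)
    return(list(distance = d,
                contrib = data.frame(edge = ia, len = d)[d > 0, , drop = FALSE]))
  }
  na_ <- c(network$edges$from_node[ia], network$edges$to_node[ia])
  nb_ <- c(network$edges$from_node[ib], network$edges$to_node[ib])
  offa <- c(oa, la - oa); offb <- c(ob, lb - ob)
  D <- igraph::distances(network$graph, v = na_, to = nb_,
                         weights = igraph::E(network$graph)$length_km)
  cost <- outer(offa, rep(1, 2)) * 0 + D +
    matrix(offa, 2, 2) + matrix(offb, 2, 2, byrow = TRUE)
  k <- arrayInd(which.min(cost), c(2, 2))
  i <- k[1]; j <- k[2]
  sp <- igraph::shortest_paths(network$graph, from = na_[i], to = nb_[j],
                               weights = igraph::E(network$graph)$length_km,
                               output = "epath")$epath[[1]]
  mid_ids <- igraph::edge_attr(network$graph, "edge_id", sp)
  mid <- match(mid_ids, network$edges$edge_id)
  contrib <- data.frame(edge = c(ia, mid, ib),
                        len = c(offa[i], network$edges$length_km[mid], offb[j]))
  contrib <- contrib[contrib$len > 0, , drop = FALSE]
  contrib <- stats::aggregate(len ~ edge, contrib, sum)
  list(distance = cost[i, j], contrib = contrib)
}

#' River distance between two sites
#'
#' Length (km) of the unique path through the network tree between two
#' sites, accounting for partial traversal of the edges the sites sit
#' on. Symmetric; 0 for identical placements. Flow direction is ignored
#' (fish move both ways).
#'
#' @param network a [river_network()]
#' @param sites site table (see [read_site_table()])
#' @param site_a,site_b site ids
#' @return distance in km
#' @export
river_distance <- function(network, sites, site_a, site_b) {
  point_path(network, sites, site_a, site_b)$distance
}

#' All pairwise river distances among sites
#' @param network a [river_network()]
#' @param sites site table
#' @return symmetric matrix of km, site ids as dimnames
#' @export
river_distance_matrix <- function(network, sites) {
  n <- nrow(sites)
  d <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- river_distance(network, sites,
                                         sites$site_id[i], sites$site_id[j])
  }
  d
}

#' Upstream distance of each site within its metapopulation
#'
#' The furthest-downstream site of a metapopulation is the one closest
#' to the network outlet; its upstream distance is 0 and every other
#' site's upstream distance is its river distance to that reference
#' site. Ties for furthest-downstream are broken by site id order with a
#' warning.
#'
#' @param network a [river_network()]
#' @param sites site table
#' @param metapop optional single metapopulation label; default all
#' @return data frame `site_id`, `metapopulation`, `upstream_km`
#' @export
upstream_distance <- function(network, sites, metapop = NULL) {
  if (!is.null(metapop)) sites <- sites[sites$metapopulation %in% metapop, ]
  if (nrow(sites) == 0) stop("no sites in requested metapopulation")
  out <- lapply(split(sites, sites$metapopulation), function(s) {
    idx <- match(s$edge_id, network$edges$edge_id)
    Dv <- igraph::distances(network$graph,
                            v = network$edges$to_node[idx],
                            to = network$outlet,
                            weights = igraph::E(network$graph)$length_km)[, 1]
    Du <- igraph::distances(network$graph,
                            v = network$edges$from_node[idx],
                            to = network$outlet,
                            weights = igraph::E(network$graph)$length_km)[, 1]
    len <- network$edges$length_km[idx]
    to_outlet <- pmin(s$offset_km + Du, (len - s$offset_km) + Dv)
    ref_candidates <- which(to_outlet == min(to_outlet))
    if (length(ref_candidates) > 1) {
      ref_candidates <- ref_candidates[order(s$site_id[ref_candidates])]
      warning("tie for furthest-downstream site in metapopulation '",
              s$metapopulation[1], "'; resolved by site_id order (",
              s$site_id[ref_candidates[1]], ")")
    }
    ref <- s$site_id[ref_candidates[1]]
    up <- vapply(s$site_id, function(id) {
      if (id == ref) 0 else river_distance(network, s, id, ref)
    }, numeric(1))
    data.frame(site_id = s$site_id, metapopulation = s$metapopulation,
               upstream_km = unname(up), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[match(sites$site_id, out$site_id), , drop = FALSE]
}

#' Path-level habitat covariates for a site pair
#'
#' Length-weighted means of per-edge attributes along the geodesic
#' (partial host edges weighted by the traversed length), a count of
#' barrier edges crossed, and endpoint dam/reservoir flags.
#'
#' @param network a [river_network()]
#' @param sites site table
#' @param site_a,site_b site ids
#' @return one-row data frame (a PathSummary)
#' @export
path_covariates <- function(network, sites, site_a, site_b) {
  pp <- point_path(network, sites, site_a, site_b)
  e <- network$edges
  if (nrow(pp$contrib) == 0) {
    # coincident sites: attributes of the host edge, zero distance
    i <- match(site_row(sites, site_a)$edge_id, e$edge_id)
    w <- stats::setNames(1, i)
    idx <- i; len <- 1
  } else {
    idx <- pp$contrib$edge; len <- pp$contrib$len
  }
  wmean <- function(a) sum(len * a[idx]) / sum(len)
  ra <- site_row(sites, site_a); rb <- site_row(sites, site_b)
  data.frame(
    site_a = site_a, site_b = site_b,
    distance_km = pp$distance,
    prop_intermittent = wmean(e$intermittent_fraction),
    prop_developed = wmean(e$cover_developed),
    prop_grassland = wmean(e$cover_grassland),
    prop_cropland = wmean(e$cover_cropland),
    prop_forest = wmean(e$cover_forest),
    barriers_crossed = sum(e$barrier[idx] & len > 0),
    dam_flag = isTRUE(ra$above_dam) || isTRUE(rb$above_dam),
    reservoir_flag = isTRUE(ra$reservoir_adjacent) || isTRUE(rb$reservoir_adjacent),
    stringsAsFactors = FALSE)
}

#' Build the site-pair table for isolation-by-distance models
#'
#' Joins linearized pairwise FST with river distance and path covariates
#' for every pair of sites within the same metapopulation.
#'
#' @param network a [river_network()]
#' @param sites site table
#' @param fst a [pairwise_fst()] result grouped by site
#' @return data frame with one row per within-metapopulation site pair
#' @export
pair_table <- function(network, sites, fst) {
  stopifnot(inherits(fst, "fst_matrix"))
  rows <- list()
  for (mp in unique(sites$metapopulation)) {
    s <- sites[sites$metapopulation == mp, ]
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
      a <- s$site_id[i]; b <- s$site_id[j]
      pc <- path_covariates(network, sites, a, b)
      pc$metapopulation <- mp
      pc$fst <- fst$est[a, b]
      pc$fst_linear <- linearize_fst(fst$est[a, b])
      rows[[length(rows) + 1]] <- pc
    }
  }
  if (!length(rows)) stop("no within-metapopulation site pairs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
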