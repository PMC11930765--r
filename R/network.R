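#' Construct and validate a river network
#'
#' A river network is a downstream-oriented tree: each edge runs from its
#' upstream node (`from_node`) to its downstream node (`to_node`), every
#' node has at most one downstream edge (no braided channels), the graph
#' is connected and acyclic, and edge lengths are positive. Per-edge
#' habitat attributes (intermittency fraction, land-cover fractions and a
#' barrier flag) ride along for path summaries.
#'
#' @param edges data frame with columns `edge_id`, `from_node`, `to_node`,
#'   `length_km`, `intermittent_fraction`, `cover_developed`,
#'   `cover_grassland`, `cover_cropland`, `cover_forest`, `barrier`
#' @return object of class `river_network` holding the edge table, an
#'   undirected `igraph` (for distances) and the outlet node
#' @export
river_network <- function(edges) {
  req <- c("edge_id", "from_node", "to_node", "length_km",
           "intermittent_fraction", "cover_developed", "cover_grassland",
           "cover_cropland", "cover_forest", "barrier")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop("edge table missing columns: ",
                         paste(miss, collapse = ", "))
  edges <- as.data.frame(edges)
  edges$edge_id <- as.character(edges$edge_id)
  edges$from_node <- as.character(edges$from_node)
  edges$to_node <- as.character(edges$to_node)
  edges$barrier <- parse_bool(edges$barrier)
  if (anyDuplicated(edges$edge_id)) stop("duplicate edge_id")
  if (any(edges$length_km <= 0)) stop("edge lengths must be > 0")
  fr <- c(edges$intermittent_fraction, edges$cover_developed,
          edges$cover_grassland, edges$cover_cropland, edges$cover_forest)
  if (any(fr < 0 | fr > 1)) stop("edge fractions must lie in [0, 1]")

  # braided-channel check: at most one downstream (outgoing) edge per node
  multi <- names(which(table(edges$from_node) > 1))
  if (length(multi)) {
    stop("node(s) with more than one downstream edge: ",
         paste(multi, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from_node", "to_node", "edge_id", "length_km")],
    directed = FALSE)
  comps <- igraph::components(g)
  if (comps$no > 1) {
    lab <- vapply(seq_len(comps$no), function(k) {
      paste(head(names(comps$membership)[comps$membership == k], 4),
            collapse = "+")
    }, character(1))
    stop("network is disconnected; components: ", paste(lab, collapse = " | "))
  }
  n_nodes <- igraph::vcount(g)
  if (nrow(edges) >= n_nodes) stop("cycle detected: edges >= nodes in a connected graph")
  outlet <- setdiff(edges$to_node, edges$from_node)
  outlet <- unique(c(outlet, setdiff(unique(c(edges$from_node, edges$to_node)),
                                     edges$from_node)))
  outlet <- intersect(unique(c(edges$from_node, edges$to_node)), outlet)
  # the outlet is the unique node with no outgoing (downstream) edge
  outlet <- setdiff(unique(c(edges$from_node, edges$to_node)), edges$from_node)
  if (length(outlet) != 1) stop("expected exactly one outlet node, found ",
                                length(outlet))
  structure(list(edges = edges, graph = g, outlet = outlet),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf("river_network: %d edges, %d nodes, outlet '%s', %.1f km total\n",
              nrow(x$edges), igraph::vcount(x$graph), x$outlet,
              sum(x$edges$length_km)))
  invisible(x)
}

#' @keywords internal
#' @noRd
parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t")] <- TRUE
  out[v %in% c("0", "false", "f")] <- FALSE
  if (anyNA(out)) stop("could not parse boolean values: ",
                       paste(unique(v[is.na(out)]), collapse = ", "))
  out
}

#' Attach site records to a network, validating placement
#'
#' @param network a [river_network()]
#' @param sites data frame of site records (see [read_site_table()])
#' @return `sites` with offsets validated against edge lengths
#' @export
place_sites <- function(network, sites) {
  stopifnot(inherits(network, "river_network"))
  idx <- match(sites$edge_id, network$edges$edge_id)
  if (anyNA(idx)) {
    stop("site(s) reference unknown edges: ",
         paste(sites$site_id[is.na(idx)], collapse = ", "))
  }
  len <- network$edges$length_km[idx]
  bad <- sites$offset_km < 0 | sites$offset_km > len
  if (any(bad)) {
    stop("offset beyond edge length for site(s): ",
         paste(sites$site_id[bad], collapse = ", "))
  }
  sites
}
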