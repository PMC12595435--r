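#' Generate a connected network topology
#'
#' Builds the structural connectivity \eqn{A_{jk}} used by the oscillator
#' network: a connected, undirected, unweighted graph with a prescribed
#' number of nodes and links. Random graphs are Erdos-Renyi G(n, m) draws,
#' redrawn until connected; small-world graphs are Watts-Strogatz ring
#' lattices (base degree \code{2 * n_links / n_nodes}) rewired with
#' probability \code{rewire_prob}; scale-free graphs use Barabasi-Albert
#' preferential attachment with the per-step edge count chosen so the total
#' edge count comes as close to \code{n_links} as the attachment scheme
#' allows (the attained count is in the returned object).
#'
#' @param kind One of \code{"random"}, \code{"scale_free"},
#'   \code{"small_world"}, \code{"custom"}.
#' @param n_nodes Number of oscillators.
#' @param n_links Target undirected edge count. Must be at least
#'   \code{n_nodes - 1}; for \code{"small_world"}, \code{n_links / n_nodes}
#'   must be a whole number (ring-lattice neighbourhood size).
#' @param seed Integer seed; topologies are deterministic given the seed.
#' @param rewire_prob Watts-Strogatz rewiring probability (small-world only).
#' @param adjacency For \code{kind = "custom"}: a symmetric binary adjacency
#'   matrix with zero diagonal describing a connected graph.
#'
#' @return An object of class \code{sl_topology}: a list with
#'   \code{adjacency} (symmetric 0/1 matrix), \code{n_nodes}, \code{n_links}
#'   (attained count), \code{kind}, and \code{seed}.
#'
#' @examples
#' topo <- generate_topology("random", n_nodes = 50, n_links = 200, seed = 1)
#' glance(topo)
#' @export
generate_topology <- function(kind = c("random", "scale_free", "small_world",
                                       "custom"),
                              n_nodes, n_links = NULL, seed = 1L,
                              rewire_prob = 0.1, adjacency = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(adjacency)) stop("kind = 'custom' requires `adjacency`")
    return(as_sl_topology(adjacency, seed = seed))
  }
  stopifnot(n_nodes >= 2, !is.null(n_links))
  if (n_links < n_nodes - 1)
    stop("infeasible: a connected graph on ", n_nodes, " nodes needs at least ",
         n_nodes - 1, " links")
  if (n_links > n_nodes * (n_nodes - 1) / 2)
    stop("infeasible: more links than node pairs")

  g <- withr::with_seed(seed, switch(kind,
    random = {
      for (try in 1:200) {
        g <- igraph::sample_gnm(n_nodes, n_links)
        if (igraph::is_connected(g)) break
        g <- NULL
      }
      if (is.null(g)) stop("could not draw a connected G(n, m) graph; ",
                           "n_links is too small for n_nodes")
      g
    },
    scale_free = {
      m <- max(1L, round(n_links / n_nodes))
      igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    },
    small_world = {
      nei <- n_links / n_nodes
      if (nei != round(nei))
        stop("small_world needs n_links / n_nodes to be a whole number ",
             "(ring-lattice base degree)")
      for (try in 1:200) {
        g <- igraph::sample_smallworld(1, n_nodes, nei = nei, p = rewire_prob)
        g <- igraph::simplify(g)
        if (igraph::is_connected(g) &&
            igraph::ecount(g) == n_links) break
        g <- NULL
      }
      if (is.null(g)) stop("could not rewire to a connected simple ",
                           "small-world graph; lower rewire_prob")
      g
    }))

  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  out <- as_sl_topology(adj, seed = seed)
  out$kind <- kind
  out
}

as_sl_topology <- function(adjacency, seed = NA_integer_) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency)) || any(diag(adjacency) != 0) ||
      !all(adjacency %in% c(0, 1)))
    stop("adjacency must be symmetric binary with zero diagonal")
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  if (!igraph::is_connected(g)) stop("graph is not connected")
  structure(
    list(adjacency = unname(adjacency),
         n_nodes = nrow(adjacency),
         n_links = sum(adjacency) / 2,
         kind = "custom",
         seed = seed),
    class = "sl_topology")
}

#' @export
print.sl_topology <- function(x, ...) {
  cat(sprintf("<sl_topology> %s graph: %d nodes, %d links (seed %s)\n",
              x$kind, x$n_nodes, x$n_links, x$seed))
  invisible(x)
}

#' @describeIn generate_topology One row per undirected edge
#'   (\code{from}, \code{to}).
#' @param x An \code{sl_topology}.
#' @param ... Unused.
#' @export
tidy.sl_topology <- function(x, ...) {
  idx <- which(upper.tri(x$adjacency) & x$adjacency == 1, arr.ind = TRUE)
  tibble::tibble(from = idx[, 1], to = idx[, 2])
}

#' @describeIn generate_topology One-row summary (nodes, links, degree stats).
#' @export
glance.sl_topology <- function(x, ...) {
  deg <- rowSums(x$adjacency)
  tibble::tibble(kind = x$kind, n_nodes = x$n_nodes, n_links = x$n_links,
                 mean_degree = mean(deg), max_degree = max(deg))
}

# directed edge list (0-based, both directions) for the integrator
topology_edges <- function(topology) {
  idx <- which(topology$adjacency == 1, arr.ind = TRUE)
  list(src = as.integer(idx[, 2] - 1L), dst = as.integer(idx[, 1] - 1L))
}
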