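#' @importFrom igraph graph_from_adjacency_matrix distances mean_distance
#'   betweenness rewire keeping_degseq as_adjacency_matrix components
NULL

as_adjacency <- function(g) {
  if (inherits(g, "binary_graph")) g$adjacency else g
}

as_ig <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Clustering coefficient
#'
#' Nodal clustering is the fraction of a node's neighbor pairs that are
#' themselves connected: t_i / (k_i (k_i - 1) / 2) with t_i the number of
#' triangles through node i and k_i its degree; it is defined as 0 for
#' k_i < 2. The network value is the unweighted mean over all N nodes — a
#' measure of network segregation.
#'
#' @param g a `binary_graph` or 0/1 adjacency matrix.
#' @return list with `nodal` (named per-node values) and `mean`.
#' @export
clustering_coefficient <- function(g) {
  adj <- as_adjacency(g)
  nodal <- nodal_clustering(adj)
  list(nodal = nodal, mean = mean(nodal))
}

# triangles via diag(A^3); A %*% A reused for speed in permutation loops
nodal_clustering <- function(adj) {
  storage.mode(adj) <- "double"
  k <- rowSums(adj)
  a2 <- adj %*% adj
  tri <- rowSums(a2 * adj)        # = diag(A^3), 2 * triangle count per node
  c_i <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  names(c_i) <- rownames(adj)
  c_i
}

mean_clustering <- function(adj) mean(nodal_clustering(adj))

#' Characteristic path length
#'
#' Mean shortest-path (hop) distance between node pairs — the standard
#' measure of network integration. Below the full-connectivity density the
#' graph may fragment and some pairs have no path; two conventions are
#' offered:
#' \describe{
#'   \item{`component`}{(default) average over pairs of nodes in the same
#'     connected component only; unreachable pairs are excluded.}
#'   \item{`harmonic`}{reciprocal of global efficiency: N(N-1) divided by
#'     the sum over ordered pairs of 1/distance, with 1/Inf = 0 for
#'     unreachable pairs.}
#' }
#'
#' @param g a `binary_graph` or 0/1 adjacency matrix.
#' @param mode `"component"` or `"harmonic"`.
#' @return a single number >= 1.
#' @export
characteristic_path_length <- function(g, mode = c("component", "harmonic")) {
  mode <- match.arg(mode)
  adj <- as_adjacency(g)
  if (sum(adj) == 0) stop("characteristic path length undefined: graph has no edges")
  ig <- as_ig(adj)
  if (mode == "component") {
    # same-component ordered-pair average (igraph excludes unreachable pairs)
    igraph::mean_distance(ig, unconnected = TRUE)
  } else {
    d <- igraph::distances(ig)
    off <- d[upper.tri(d)]
    inv <- ifelse(is.finite(off), 1 / off, 0)
    1 / mean(inv)
  }
}

#' Degree-preserving random graph ensemble
#'
#' Generates `size` randomized versions of a graph by Maslov-Sneppen double
#' edge swaps (igraph's `keeping_degseq` rewiring): repeatedly pick two
#' edges (a,b), (c,d) and replace them with (a,d), (c,b) when no self-loop
#' or multi-edge results. Every member has exactly the node count, edge
#' count and degree sequence of the input — the null model against which
#' small-world metrics are normalized.
#'
#' @param g a `binary_graph` or 0/1 adjacency matrix.
#' @param size ensemble size (default 20).
#' @param iterations_per_edge swap attempts per edge (default 10).
#' @param seed integer seed for the ensemble's RNG stream; member m is drawn
#'   under `seed + m` so the ensemble is reproducible and extensible.
#' @return object of class `random_ensemble`: list of `binary_graph`s plus
#'   the generation parameters.
#' @export
generate_random_ensemble <- function(g, size = 20, iterations_per_edge = 10,
                                     seed = 1L) {
  adj <- as_adjacency(g)
  E <- sum(adj) / 2
  if (E < 2) stop("need at least 2 edges to rewire")
  ig <- as_ig(adj)
  niter <- ceiling(iterations_per_edge * E)
  members <- vector("list", size)
  changed <- FALSE
  for (m in seq_len(size)) {
    set.seed(seed + m)
    rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = niter))
    radj <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
    dimnames(radj) <- dimnames(adj)
    if (!changed && !identical(radj == 1, adj == 1)) changed <- TRUE
    members[[m]] <- binary_graph(radj)
  }
  if (!changed && !has_legal_swap(adj)) {
    warning("no legal degree-preserving swap exists; ensemble members are copies of the input")
  }
  structure(list(members = members, size = size,
                 iterations_per_edge = iterations_per_edge, seed = seed),
            class = "random_ensemble")
}

# is there any double edge swap that changes the graph?
has_legal_swap <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  ne <- nrow(idx)
  if (ne < 2) return(FALSE)
  for (p in seq_len(ne - 1L)) {
    a <- idx[p, 1L]; b <- idx[p, 2L]
    for (q in (p + 1L):ne) {
      c <- idx[q, 1L]; d <- idx[q, 2L]
      if (length(unique(c(a, b, c, d))) < 4L) next
      if (adj[a, d] == 0 && adj[c, b] == 0) return(TRUE)
      if (adj[a, c] == 0 && adj[b, d] == 0) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.random_ensemble <- function(x, ...) {
  cat(sprintf("<random_ensemble> %d degree-matched rewired graphs (%g swap attempts/edge)\n",
              x$size, x$iterations_per_edge))
  invisible(x)
}

#' Small-world metrics normalized by a degree-matched random ensemble
#'
#' Computes the clustering coefficient C and characteristic path length L of
#' a graph, their means C_rand and L_rand over a degree-preserving random
#' ensemble, and the ratios gamma = C/C_rand, lambda = L/L_rand and the
#' small-world index sigma = gamma/lambda. A small-world network has
#' gamma clearly above 1 with lambda close to 1, hence sigma > 1.
#'
#' @param g a `binary_graph`.
#' @param ensemble a `random_ensemble` for `g` (see
#'   [generate_random_ensemble()]).
#' @param path_length_mode convention for disconnected graphs, see
#'   [characteristic_path_length()].
#' @return object of class `global_metrics`: list with `clustering`,
#'   `path_length`, `c_rand`, `l_rand`, `gamma`, `lambda`, `sigma`,
#'   `density`, `ensemble_size`.
#' @export
small_worldness <- function(g, ensemble,
                            path_length_mode = c("component", "harmonic")) {
  path_length_mode <- match.arg(path_length_mode)
  stopifnot(inherits(ensemble, "random_ensemble"), ensemble$size >= 1)
  C <- mean_clustering(as_adjacency(g))
  L <- characteristic_path_length(g, path_length_mode)
  c_rand <- mean(vapply(ensemble$members,
                        function(m) mean_clustering(m$adjacency), 0))
  l_rand <- mean(vapply(ensemble$members,
                        function(m) characteristic_path_length(m, path_length_mode), 0))
  if (c_rand == 0) stop("degenerate null: ensemble mean clustering is 0")
  gamma <- C / c_rand
  lambda <- L / l_rand
  structure(list(clustering = C, path_length = L,
                 c_rand = c_rand, l_rand = l_rand,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 density = if (inherits(g, "binary_graph")) g$density else NA_real_,
                 ensemble_size = ensemble$size),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(paste0("<global_metrics> density %.4f\n",
                     "  C = %.4f  L = %.4f  C/C_rand = %.3f  L/L_rand = %.3f  sigma = %.3f",
                     "  (ensemble of %d)\n"),
              x$density, x$clustering, x$path_length,
              x$gamma, x$lambda, x$sigma, x$ensemble_size))
  invisible(x)
}

#' Nodal betweenness centrality and degree
#'
#' Betweenness is the fraction of all shortest paths that pass through a
#' node (Brandes' exact algorithm with even splitting across equal-length
#' shortest paths), normalized by (N-1)(N-2)/2 to lie in `[0, 1]`. Degree is
#' the number of edges incident to the node. Hub flags follow
#' [identify_hubs()].
#'
#' @param g a `binary_graph` or 0/1 adjacency matrix.
#' @return a `nodal_metrics` data frame with columns `roi`, `degree`,
#'   `betweenness`, `is_hub`.
#' @export
betweenness_and_degree <- function(g) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  btw <- igraph::betweenness(as_ig(adj), directed = FALSE, normalized = FALSE)
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  btw <- unname(btw) / norm
  labels <- rownames(adj)
  if (is.null(labels)) labels <- paste0("ROI_", seq_len(n))
  out <- data.frame(roi = labels, degree = as.integer(rowSums(adj)),
                    betweenness = btw, stringsAsFactors = FALSE)
  out$is_hub <- out$roi %in% identify_hubs(out)
  class(out) <- c("nodal_metrics", "data.frame")
  out
}

#' Hub identification by the 2-SD betweenness rule
#'
#' A node is a hub if its betweenness centrality is at least two (population)
#' standard deviations above the network mean betweenness. When the SD is 0
#' (all nodes equal) there is no variability to exceed and no node is a hub.
#'
#' @param nodal a `nodal_metrics` data frame, or a named numeric vector of
#'   betweenness values.
#' @param n_sd hub threshold in SDs above the mean (default 2).
#' @return character vector of hub ROI labels.
#' @export
identify_hubs <- function(nodal, n_sd = 2) {
  if (is.data.frame(nodal)) {
    b <- stats::setNames(nodal$betweenness, nodal$roi)
  } else {
    b <- nodal
  }
  n <- length(b)
  sd_pop <- sqrt(mean((b - mean(b))^2))
  if (sd_pop == 0) return(character(0))
  names(b)[b >= mean(b) + n_sd * sd_pop]
}
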