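#' Association matrix of inter-regional correlations
#'
#' For one group, the structural covariance network's weighted backbone: an
#' N x N matrix R whose entry r_ij is the Pearson correlation, across
#' subjects, between the (residual) volumes of regions i and j. The diagonal
#' is set to zero by convention.
#'
#' @param residuals a [volume_table] (typically from [regress_confounds()]).
#' @return an `association_matrix`: numeric N x N matrix with ROI dimnames,
#'   zero diagonal, and attribute `n_subjects`.
#' @export
build_association_matrix <- function(residuals) {
  stopifnot(inherits(residuals, "volume_table"))
  Y <- volume_matrix(residuals)
  if (nrow(Y) < 3L) stop("need at least 3 subjects to correlate; have ", nrow(Y))
  sds <- apply(Y, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI column(s): ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(Y)
  diag(R) <- 0
  structure(R, class = c("association_matrix", "matrix"),
            n_subjects = nrow(Y))
}

#' @export
print.association_matrix <- function(x, ...) {
  r <- upper_triangle(x)
  cat(sprintf("<association_matrix> %d ROIs, %d subjects; off-diagonal r: min %.3f, median %.3f, max %.3f\n",
              nrow(x), attr(x, "n_subjects"), min(r), stats::median(r), max(r)))
  invisible(x)
}

#' Upper-triangle correlation values
#'
#' Returns the N(N-1)/2 above-diagonal entries of a symmetric matrix in
#' row-major order (row 1 left to right, then row 2, ...). This is the value
#' list used for the between-group correlation-strength comparison.
#'
#' @param assoc an `association_matrix` (or any symmetric matrix).
#' @export
association_summary <- function(assoc) {
  upper_triangle(assoc)
}

upper_triangle <- function(m) {
  t(m)[lower.tri(m)]  # transpose trick: row-major order of the upper triangle
}

# per-N cache of upper-triangle linear and (i, j) indices; the permutation
# loops call ranked_edges() tens of thousands of times on same-sized matrices
.ut_cache <- new.env(parent = emptyenv())

ut_index <- function(n) {
  key <- as.character(n)
  hit <- .ut_cache[[key]]
  if (!is.null(hit)) return(hit)
  ut <- which(upper.tri(matrix(0, n, n)))
  idx <- arrayInd(ut, c(n, n))
  val <- list(ut = ut, i = idx[, 1L], j = idx[, 2L])
  assign(key, val, envir = .ut_cache)
  val
}

# Off-diagonal upper-triangle edges ordered by decreasing r, ties broken by
# (row, col) lexicographic order. Returns a data-frame-free list for speed.
ranked_edges <- function(assoc) {
  n <- nrow(assoc)
  ix <- ut_index(n)
  r <- assoc[ix$ut]
  ord <- order(-r, ix$i, ix$j)
  list(i = ix$i[ord], j = ix$j[ord], r = r[ord], n = n)
}

#' Binarize an association matrix at a target network density
#'
#' Keeps the E = round(density * N(N-1)/2) largest off-diagonal correlations
#' (signed values, not absolute) as edges of an undirected, unweighted graph;
#' equivalently, thresholds r_ij at the E-th largest value. Ties at the
#' cutoff are broken deterministically by (row, column) index order. The
#' realized density E / (N(N-1)/2) is reported on the result and may differ
#' from the request by at most one edge's worth.
#'
#' @param assoc an `association_matrix`.
#' @param density target density in (0, 1].
#' @return a `binary_graph`: list with `adjacency` (0/1 symmetric matrix,
#'   zero diagonal), `roi_labels`, `edge_count`, `density` (realized) and
#'   `requested_density`.
#' @export
threshold_at_density <- function(assoc, density) {
  stopifnot(is.matrix(assoc), nrow(assoc) == ncol(assoc))
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]; got ", density)
  n <- nrow(assoc)
  m <- n * (n - 1L) / 2L
  E <- round(density * m)
  if (E < 1L) stop("density ", density, " yields zero edges for N = ", n)
  edges <- ranked_edges(assoc)
  if (edges$r[E] <= 0) {
    warning("correlation cutoff at density ", density,
            " is non-positive (r = ", signif(edges$r[E], 3),
            "); negative correlations enter the graph")
  }
  adj <- matrix(0L, n, n, dimnames = dimnames(assoc))
  sel_i <- edges$i[seq_len(E)]
  sel_j <- edges$j[seq_len(E)]
  adj[cbind(sel_i, sel_j)] <- 1L
  adj[cbind(sel_j, sel_i)] <- 1L
  new_binary_graph(adj, E, requested_density = density)
}

# unvalidated constructor for adjacency built in-package (hot loops)
new_binary_graph <- function(adjacency, edge_count, requested_density = NA_real_) {
  n <- nrow(adjacency)
  labels <- rownames(adjacency)
  if (is.null(labels)) labels <- paste0("ROI_", seq_len(n))
  structure(list(adjacency = adjacency, roi_labels = labels,
                 edge_count = as.integer(edge_count),
                 density = edge_count / (n * (n - 1) / 2),
                 requested_density = requested_density),
            class = "binary_graph")
}

#' Construct a `binary_graph` from a 0/1 adjacency matrix
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @param requested_density optional density that was asked for, if the graph
#'   came from [threshold_at_density()].
#' @export
binary_graph <- function(adjacency, requested_density = NA_real_) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be 0/1")
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) stop("adjacency must be symmetric")
  new_binary_graph(adjacency, sum(adjacency) / 2, requested_density)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges, density %.4f\n",
              length(x$roi_labels), x$edge_count, x$density))
  invisible(x)
}

#' Minimum density at which every group's network is fully connected
#'
#' Scans the grid of attainable densities k / (N(N-1)/2) and returns the
#' smallest one at which thresholding each supplied association matrix gives
#' a single connected component. Per matrix this is a percolation problem:
#' edges are added in decreasing-correlation order (the same deterministic
#' order used by [threshold_at_density()]) under a union-find structure until
#' the graph first connects; the answer is the maximum over matrices of that
#' percolation density.
#'
#' @param assocs one `association_matrix` or a list of them (all same N).
#' @return the minimum full-connectivity density (a multiple of 1/(N(N-1)/2)).
#' @export
min_full_connectivity_density <- function(assocs) {
  if (inherits(assocs, "association_matrix") ||
      (is.matrix(assocs) && !is.list(assocs))) {
    assocs <- list(assocs)
  }
  stopifnot(length(assocs) >= 1L)
  n <- nrow(assocs[[1L]])
  stopifnot(all(vapply(assocs, nrow, 0L) == n))
  m <- n * (n - 1L) / 2L
  k_star <- vapply(assocs, function(a) percolation_edge_count(ranked_edges(a)), 0L)
  max(k_star) / m
}

# smallest k such that the top-k edges form one connected component
percolation_edge_count <- function(edges) {
  n <- edges$n
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  components <- n
  for (k in seq_along(edges$i)) {
    ri <- find(edges$i[k]); rj <- find(edges$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      components <- components - 1L
      if (components == 1L) return(k)
    }
  }
  stop("graph never connects; association matrix degenerate")  # unreachable for finite r
}
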