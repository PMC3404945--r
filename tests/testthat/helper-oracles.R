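# Brute-force reference implementations, independent of the package's code
# paths (no igraph, no shared helpers). Used as oracles on small graphs.

# all-pairs hop distances by Floyd-Warshall
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) links <- links + adj[nb[a], nb[b]]
    }
    links / (k * (k - 1) / 2)
  })
}

bf_path_length <- function(adj, mode = c("component", "harmonic")) {
  mode <- match.arg(mode)
  d <- bf_distances(adj)
  off <- d[upper.tri(d)]
  if (mode == "component") mean(off[is.finite(off)])
  else 1 / mean(ifelse(is.finite(off), 1 / off, 0))
}

# shortest-path counts: the number of geodesics from s to t equals the
# (s, t) entry of A^d(s,t) (walks of minimal length cannot revisit nodes)
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  maxd <- max(d[is.finite(d)])
  pow <- vector("list", max(1, maxd))
  pow[[1]] <- adj
  if (maxd >= 2) for (k in 2:maxd) pow[[k]] <- pow[[k - 1]] %*% adj
  nsp <- function(a, b) {
    if (a == b) return(1)
    if (!is.finite(d[a, b])) return(0)
    pow[[d[a, b]]][a, b]
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          b[v] <- b[v] + nsp(s, v) * nsp(v, t) / nsp(s, t)
        }
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

bf_hubs <- function(betweenness, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ROI_", seq_along(betweenness))
  sd_pop <- sqrt(mean((betweenness - mean(betweenness))^2))
  if (sd_pop == 0) return(character(0))
  labels[betweenness >= mean(betweenness) + 2 * sd_pop]
}

bf_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] == 1 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# linear scan over k: smallest density k/M whose top-k graph is connected,
# for every matrix; ties broken by (row, col) order as documented
bf_min_density <- function(assocs) {
  if (!is.list(assocs)) assocs <- list(assocs)
  n <- nrow(assocs[[1]])
  m <- n * (n - 1) / 2
  per_matrix <- sapply(assocs, function(R) {
    idx <- which(upper.tri(R), arr.ind = TRUE)
    ord <- order(-R[idx], idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    for (k in (n - 1):m) {
      adj <- matrix(0, n, n)
      sel <- idx[seq_len(k), , drop = FALSE]
      adj[sel] <- 1
      adj[sel[, 2:1, drop = FALSE]] <- 1
      if (bf_connected(adj)) return(k)
    }
    m
  })
  max(per_matrix) / m
}

# random connected-ish G(n, p) adjacency with a given seed
random_adj <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

# adjacency from an explicit edge list on n nodes
adj_from_edges <- function(n, edges, labels = NULL) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  if (!is.null(labels)) dimnames(adj) <- list(labels, labels)
  adj
}

# quick residual table from a volumes matrix, for netbuild/inference tests
table_from_matrix <- function(vols, group = "A") {
  n <- nrow(vols)
  if (is.null(colnames(vols))) colnames(vols) <- paste0("ROI_", seq_len(ncol(vols)))
  df <- data.frame(subject_id = sprintf("%s%02d", group, seq_len(n)),
                   group = group, age = seq(40, 70, length.out = n),
                   tbv = 1200 + 40 * sin(seq_len(n)),  # not collinear with age
                   stringsAsFactors = FALSE)
  as_volume_table(cbind(df, as.data.frame(vols)))
}
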