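triangle <- adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
star6 <- adj_from_edges(6, lapply(2:6, function(j) c(1, j)))
path4 <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)))

test_that("clustering coefficient: closed-form cases and brute force", {
  expect_equal(clustering_coefficient(triangle)$nodal, rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(clustering_coefficient(triangle)$mean, 1)
  expect_equal(clustering_coefficient(star6)$mean, 0)
  g5 <- adj_from_edges(5, list(c(1, 2), c(2, 3), c(3, 1), c(3, 4), c(4, 5)),
                       labels = LETTERS[1:5])
  cc <- clustering_coefficient(g5)
  expect_equal(unname(cc$nodal), bf_clustering(g5), tolerance = 1e-12)
  expect_named(cc$nodal, LETTERS[1:5])
})

test_that("characteristic path length: closed-form cases and conventions", {
  for (n in c(4, 7)) {
    K <- 1 - diag(n)
    expect_equal(characteristic_path_length(K), 1)
  }
  p3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(characteristic_path_length(p3), 4 / 3)
  two_triangles <- adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                          c(4, 5), c(5, 6), c(4, 6)))
  expect_equal(characteristic_path_length(two_triangles, "component"), 1)
  # harmonic convention counts unreachable pairs as infinitely long
  expect_equal(characteristic_path_length(two_triangles, "harmonic"),
               bf_path_length(two_triangles, "harmonic"))
  expect_gt(characteristic_path_length(two_triangles, "harmonic"), 1)
  expect_error(characteristic_path_length(matrix(0L, 4, 4)), "no edges")
})

test_that("path length never increases as edges are added", {
  set.seed(55)
  adj <- adj_from_edges(8, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                c(5, 6), c(6, 7), c(7, 8)))
  prev <- characteristic_path_length(adj)
  absent <- which(upper.tri(adj) & adj == 0)
  for (e in sample(absent, 12)) {
    ij <- arrayInd(e, dim(adj))
    adj[ij[1], ij[2]] <- 1L; adj[ij[2], ij[1]] <- 1L
    cur <- characteristic_path_length(adj)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("betweenness and degree: closed-form cases", {
  nm <- betweenness_and_degree(star6)
  expect_equal(nm$betweenness, c(1, rep(0, 5)))
  expect_equal(nm$degree, c(5L, rep(1L, 5)))
  expect_equal(betweenness_and_degree(1 - diag(6))$betweenness, rep(0, 6))
  nm4 <- betweenness_and_degree(path4)
  expect_equal(nm4$betweenness, c(0, 2 / 3, 2 / 3, 0))
  expect_equal(sum(nm4$degree), 2 * 3)
})

test_that("all metrics match brute force on random small graphs", {
  for (case in 1:60) {
    set.seed(3000 + case)
    n <- sample(4:7, 1)
    adj <- random_adj(n, p = runif(1, 0.3, 0.8), seed = 3000 + case)
    if (sum(adj) == 0) next
    expect_equal(unname(clustering_coefficient(adj)$nodal), bf_clustering(adj),
                 tolerance = 1e-9)
    expect_equal(characteristic_path_length(adj), bf_path_length(adj),
                 tolerance = 1e-9)
    nm <- betweenness_and_degree(adj)
    expect_equal(nm$betweenness, bf_betweenness(adj), tolerance = 1e-9)
    expect_identical(nm$degree, as.integer(rowSums(adj)))
    expect_identical(sort(identify_hubs(nm)), sort(bf_hubs(nm$betweenness)))
  }
})

test_that("rewired ensembles preserve the degree sequence exactly", {
  set.seed(91)
  adj <- random_adj(20, p = 0.3, seed = 91)
  ens <- generate_random_ensemble(adj, size = 8, seed = 13)
  for (m in ens$members) {
    expect_identical(rowSums(m$adjacency), rowSums(adj))
    expect_equal(m$edge_count, sum(adj) / 2)
  }
  # reproducible and extensible seed stream
  ens2 <- generate_random_ensemble(adj, size = 8, seed = 13)
  expect_identical(lapply(ens$members, `[[`, "adjacency"),
                   lapply(ens2$members, `[[`, "adjacency"))
})

test_that("graphs with no legal swap come back unchanged with a warning", {
  expect_warning(ens <- generate_random_ensemble(triangle, size = 3, seed = 1),
                 "no legal")
  for (m in ens$members) expect_identical(m$adjacency == 1, triangle == 1)
  expect_error(generate_random_ensemble(adj_from_edges(3, list(c(1, 2)))),
               "at least 2 edges")
})

test_that("rewiring a ring lattice destroys clustering", {
  ring <- function(n, k) {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n)) for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
    adj
  }
  lat <- ring(20, 4)
  c0 <- clustering_coefficient(lat)$mean
  ens <- generate_random_ensemble(lat, size = 15, seed = 29)
  c_rand <- mean(sapply(ens$members, function(m) clustering_coefficient(m)$mean))
  expect_lt(c_rand, c0)
})

test_that("small-worldness against an ensemble of copies is exactly 1", {
  set.seed(7)
  adj <- random_adj(12, p = 0.4, seed = 7)
  ens <- structure(list(members = replicate(5, binary_graph(adj),
                                            simplify = FALSE),
                        size = 5, iterations_per_edge = 0, seed = 0),
                   class = "random_ensemble")
  gm <- small_worldness(binary_graph(adj), ens)
  expect_equal(gm$gamma, 1)
  expect_equal(gm$lambda, 1)
  expect_equal(gm$sigma, 1)
  expect_equal(gm$sigma, gm$gamma / gm$lambda)
})

test_that("a star graph's null ensemble is degenerate for clustering", {
  ens <- suppressWarnings(generate_random_ensemble(star6, size = 3, seed = 2))
  expect_error(small_worldness(binary_graph(star6), ens), "degenerate")
})

test_that("hub rule: degenerate SD means no hubs; strong centers are found", {
  expect_identical(identify_hubs(stats::setNames(rep(0.3, 8), letters[1:8])),
                   character(0))
  star10 <- adj_from_edges(10, lapply(2:10, function(j) c(1, j)),
                           labels = paste0("N", 1:10))
  expect_identical(identify_hubs(betweenness_and_degree(star10)), "N1")
  # barbell: two stars joined by a bridge between their centers
  barbell <- adj_from_edges(10, c(lapply(2:5, function(j) c(1, j)),
                                  lapply(7:10, function(j) c(6, j)),
                                  list(c(1, 6))),
                            labels = paste0("N", 1:10))
  nm <- betweenness_and_degree(barbell)
  expect_identical(sort(identify_hubs(nm)), c("N1", "N6"))
  expect_identical(sort(bf_hubs(bf_betweenness(barbell), paste0("N", 1:10))),
                   c("N1", "N6"))
})
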