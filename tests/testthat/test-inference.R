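test_that("Fisher r-to-z: closed form, symmetry, domain", {
  expect_equal(fisher_r_to_z(0), 0)
  expect_equal(fisher_r_to_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_r_to_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.1)
  expect_equal(fisher_r_to_z(-r), -fisher_r_to_z(r))
  expect_error(fisher_r_to_z(1), ">= 1")
  expect_error(fisher_r_to_z(-1.2), ">= 1")
})

rand_assoc <- function(n, seed) {
  set.seed(seed)
  R <- stats::cor(matrix(rnorm(30 * n), 30, n))
  diag(R) <- 0
  dimnames(R) <- list(paste0("ROI_", 1:n), paste0("ROI_", 1:n))
  structure(R, class = c("association_matrix", "matrix"), n_subjects = 30L)
}

test_that("strength comparison: identity, antisymmetry, textbook oracle", {
  A <- rand_assoc(8, 1)
  expect_equal(compare_strength(A, A)$t_statistic, 0)
  expect_equal(compare_strength(A, A)$p_value, 1)
  B <- rand_assoc(8, 2)
  ab <- compare_strength(A, B)
  ba <- compare_strength(B, A)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$df, 2 * 28 - 2)
  # oracle: stats::t.test with pooled variance on the z values
  A4 <- rand_assoc(4, 3); B4 <- rand_assoc(4, 4)
  got <- compare_strength(A4, B4)
  ora <- stats::t.test(atanh(association_summary(A4)),
                       atanh(association_summary(B4)), var.equal = TRUE)
  expect_equal(got$t_statistic, unname(ora$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ora$p.value, tolerance = 1e-12)
  expect_equal(got$n_values, 6L)
})

test_that("|r| = 1 in an association matrix is reported with the ROI pair", {
  A <- rand_assoc(3, 5)
  A[1, 2] <- A[2, 1] <- 1  # exact degeneracy
  B <- rand_assoc(3, 6)
  expect_error(compare_strength(A, B), "ROI_1 and ROI_2")
})

test_that("permutation p and CI are mutually consistent by construction", {
  set.seed(808)
  for (R in c(100, 200, 999, 1000)) {
    null <- rnorm(R) + rexp(R) - 1  # deliberately asymmetric null
    for (obs in c(stats::quantile(null, c(0.01, 0.03, 0.5, 0.97, 0.99)),
                  min(null) - 1, max(null) + 1, sample(null, 5))) {
      s <- covnet:::perm_summary(obs, null)
      expect_gte(s$p, 1 / (R + 1))
      expect_lte(s$ci_low, s$ci_high)
      expect_identical(s$p < 0.05, obs < s$ci_low || obs > s$ci_high)
    }
  }
})

null_pair <- function(seed, n = 20, n_rois = 12) {
  spec <- cohort_spec(n_subjects_per_group = n, n_rois = n_rois, n_modules = 3,
                      r_within_A = 0.4, r_within_B = 0.4, r_between = 0.1,
                      seed = seed)
  coh <- generate_cohort(spec)
  list(a = regress_confounds(coh$A), b = regress_confounds(coh$B))
}

test_that("permutation test: determinism, antisymmetry, add-one floor", {
  rp <- null_pair(60)
  run <- function(a, b) permutation_test(a, b, measures = "clustering",
                                         densities = c(0.3, 0.5),
                                         repetitions = 100, seed = 5)
  r1 <- run(rp$a, rp$b)
  r2 <- run(rp$a, rp$b)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "null_diffs"), attr(r2, "null_diffs"))
  r3 <- run(rp$b, rp$a)
  expect_equal(r3$observed_diff, -r1$observed_diff)
  expect_true(all(r1$p >= 1 / 101))
  expect_true(all(r1$ok))
  # CI/p consistency on every emitted row
  expect_identical(r1$p < 0.05,
                   r1$observed_diff < r1$ci_low | r1$observed_diff > r1$ci_high)
})

test_that("identical groups give an observed difference of zero and p near 1", {
  rp <- null_pair(61)
  same <- permutation_test(rp$a, rp$a, measures = "clustering",
                           densities = 0.4, repetitions = 100, seed = 9)
  expect_equal(same$observed_diff, 0)
  expect_gte(same$p, 0.5)
})

test_that("two independent null draws are exchangeable (KS spot check)", {
  rp <- null_pair(62, n = 25)
  d1 <- permutation_test(rp$a, rp$b, measures = "clustering", densities = 0.4,
                         repetitions = 200, seed = 100)
  d2 <- permutation_test(rp$a, rp$b, measures = "clustering", densities = 0.4,
                         repetitions = 200, seed = 300200)
  n1 <- attr(d1, "null_diffs")$clustering[, 1]
  n2 <- attr(d2, "null_diffs")$clustering[, 1]
  expect_gt(suppressWarnings(stats::ks.test(n1, n2)$p.value), 0.01)
})

test_that("undefined measures at a density are flagged, not dropped", {
  rp <- null_pair(63, n_rois = 8)
  # density so low that E = 0 for an 8-ROI graph: 0.01 * 28 rounds to 0
  res <- permutation_test(rp$a, rp$b, measures = "clustering",
                          densities = c(0.01, 0.5), repetitions = 100, seed = 2)
  expect_equal(nrow(res), 2)
  expect_false(res$ok[1])
  expect_true(is.na(res$p[1]))
  expect_true(res$ok[2])
})

test_that("ensemble-normalized measures flow through the permutation machinery", {
  rp <- null_pair(64, n = 18, n_rois = 10)
  res <- permutation_test(rp$a, rp$b, measures = c("gamma", "lambda", "sigma"),
                          densities = 0.35, repetitions = 100, seed = 4,
                          ensemble_size = 3)
  expect_equal(nrow(res), 3)
  expect_true(all(res$ok))
  sig <- res[res$measure == "sigma", ]
  gam <- res[res$measure == "gamma", ]
  lam <- res[res$measure == "lambda", ]
  expect_true(all(is.finite(c(sig$p, gam$p, lam$p))))
})

test_that("nodal comparison: antisymmetry, determinism, connectivity guard", {
  rp <- null_pair(65, n = 25)
  R <- list(build_association_matrix(rp$a), build_association_matrix(rp$b))
  dmin <- min_full_connectivity_density(R)
  n1 <- nodal_comparison(rp$a, rp$b, density = dmin, repetitions = 100, seed = 11,
                         ensemble_size = 3)
  n2 <- nodal_comparison(rp$a, rp$b, density = dmin, repetitions = 100, seed = 11,
                         ensemble_size = 3)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  n3 <- nodal_comparison(rp$b, rp$a, density = dmin, repetitions = 100, seed = 11,
                         ensemble_size = 3)
  expect_equal(n3$observed_diff, -n1$observed_diff)
  expect_equal(nrow(n1), 2 * 12)  # betweenness + degree per ROI
  expect_identical(n1$p < 0.05,
                   n1$observed_diff < n1$ci_low | n1$observed_diff > n1$ci_high)
  # a density below the percolation point must be refused
  lowest <- 11 / (12 * 11 / 2)  # spanning-tree density; almost surely disconnected
  if (lowest < dmin) {
    expect_error(nodal_comparison(rp$a, rp$b, density = lowest,
                                  repetitions = 100, seed = 1), "disconnected")
  }
})

test_that("a planted high-correlation ROI is recovered as the top degree difference", {
  hits <- 0
  for (run in 1:10) {
    set.seed(7000 + run)
    n <- 30; n_rois <- 12
    # group A: ROI_1 strongly coupled to every other ROI; group B: independent
    make <- function(spiked) {
      base <- matrix(rnorm(n * n_rois), n, n_rois)
      if (spiked) base[, -1] <- base[, -1] + 1.2 * base[, 1]
      colnames(base) <- paste0("ROI_", seq_len(n_rois))
      table_from_matrix(base)
    }
    ta <- make(TRUE); tb <- make(FALSE)
    res <- nodal_comparison(regress_confounds(ta), regress_confounds(tb),
                            density = 0.5, repetitions = 100,
                            seed = run, ensemble_size = 2)
    deg <- res[res$measure == "degree", ]
    if (deg$roi[which.max(deg$observed_diff)] == "ROI_1") hits <- hits + 1
  }
  expect_gte(hits, 8)
})
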