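#' Fisher r-to-z transform
#'
#' z = arctanh(r) = 0.5 log((1+r)/(1-r)); variance-stabilizing for Pearson
#' correlations, applied before comparing mean correlation strength.
#'
#' @param r correlation value(s), each with |r| < 1.
#' @export
fisher_r_to_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("Fisher z is infinite at |r| >= 1; got r = ",
         paste(r[abs(r) >= 1], collapse = ", "))
  }
  atanh(r)
}

#' Compare overall correlation strength between two groups
#'
#' Transforms every above-diagonal correlation of each group's association
#' matrix with Fisher's r-to-z and applies a pooled-variance two-sample
#' t-test to the two sets of z values. A positive t means group A's mean
#' inter-regional correlation exceeds group B's.
#'
#' @param assoc_a,assoc_b the two groups' `association_matrix` objects
#'   (same N).
#' @return object of class `strength_comparison`: `t_statistic`, `p_value`,
#'   `df`, `mean_z_A`, `mean_z_B`, `n_values`.
#' @export
compare_strength <- function(assoc_a, assoc_b) {
  stopifnot(nrow(assoc_a) == nrow(assoc_b))
  za <- fisher_z_triangle(assoc_a, "A")
  zb <- fisher_z_triangle(assoc_b, "B")
  n <- length(za)
  sp2 <- ((n - 1) * stats::var(za) + (n - 1) * stats::var(zb)) / (2 * n - 2)
  t_stat <- (mean(za) - mean(zb)) / sqrt(sp2 * (2 / n))
  df <- 2 * n - 2
  structure(list(t_statistic = t_stat,
                 p_value = 2 * stats::pt(-abs(t_stat), df),
                 df = df, mean_z_A = mean(za), mean_z_B = mean(zb),
                 n_values = n),
            class = "strength_comparison")
}

fisher_z_triangle <- function(assoc, which_group) {
  r <- association_summary(assoc)
  if (any(abs(r) >= 1)) {
    n <- nrow(assoc)
    ut <- which(upper.tri(assoc), arr.ind = TRUE)
    ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
    bad <- which(abs(r) >= 1)[1L]
    labels <- rownames(assoc)
    if (is.null(labels)) labels <- paste0("ROI_", seq_len(n))
    stop("group ", which_group, ": |r| = 1 between ",
         labels[ut[bad, 1L]], " and ", labels[ut[bad, 2L]],
         "; Fisher z undefined")
  }
  fisher_r_to_z(r)
}

#' @export
print.strength_comparison <- function(x, ...) {
  cat(sprintf("<strength_comparison> mean z: A %.4f vs B %.4f; t(%d) = %.2f, p = %.3g\n",
              x$mean_z_A, x$mean_z_B, x$df, x$t_statistic, x$p_value))
  invisible(x)
}

# --- permutation machinery -------------------------------------------------

# Two-tailed percentile p with add-one correction, and the 95% null interval
# expressed as the order statistics that make "p < alpha <=> observed outside
# [ci_low, ci_high]" exact. With R sorted null values d_(1..R) and
# K = ceiling((alpha/2) (R+1)) - 2 (the largest extreme-tail count still
# significant), the interval is [d_(K+1), d_(R-K)].
perm_summary <- function(observed, null, alpha = 0.05) {
  R <- length(null)
  lower <- (1 + sum(null <= observed)) / (R + 1)
  upper <- (1 + sum(null >= observed)) / (R + 1)
  p <- min(1, 2 * min(lower, upper))
  d <- sort(null)
  K <- ceiling((alpha / 2) * (R + 1)) - 2
  K <- max(0L, min(as.integer(K), floor((R - 1) / 2)))
  list(p = p, ci_low = d[K + 1L], ci_high = d[R - K])
}

.global_measures <- c("clustering", "path_length", "gamma", "lambda", "sigma")

# fast evaluation of global measures on an adjacency matrix; ensemble-based
# measures (gamma/lambda/sigma) draw a fresh degree-matched ensemble
measure_values <- function(adj, measures, path_length_mode,
                           ensemble_size, iterations_per_edge, seed) {
  out <- stats::setNames(rep(NA_real_, length(measures)), measures)
  if ("clustering" %in% measures) out["clustering"] <- mean_clustering(adj)
  need_l <- any(c("path_length", "lambda", "sigma") %in% measures)
  if (need_l) L <- characteristic_path_length(adj, path_length_mode)
  if ("path_length" %in% measures) out["path_length"] <- L
  if (any(c("gamma", "lambda", "sigma") %in% measures)) {
    ens <- generate_random_ensemble(adj, size = ensemble_size,
                                    iterations_per_edge = iterations_per_edge,
                                    seed = seed)
    gm <- small_worldness(binary_graph(adj), ens, path_length_mode)
    if ("gamma" %in% measures) out["gamma"] <- gm$gamma
    if ("lambda" %in% measures) out["lambda"] <- gm$lambda
    if ("sigma" %in% measures) out["sigma"] <- gm$sigma
  }
  out
}

#' Permutation test of between-group differences in global network measures
#'
#' Builds the null distribution of the group difference (group A minus
#' group B) by repeatedly reassigning subjects' residual volume rows to two
#' relabeled groups of the original sizes, rebuilding each relabeled group's
#' association matrix, thresholding at every density of the grid, and
#' recomputing the measure. Residuals are computed once, before permutation.
#' The two-tailed p-value is the observed difference's percentile position
#' in the null distribution (add-one corrected, so p >= 1/(repetitions+1)),
#' and the 95% null interval is consistent with it: p < 0.05 exactly when
#' the observed difference falls outside the interval.
#'
#' Ensemble-normalized measures (`gamma`, `lambda`, `sigma`) draw a fresh
#' degree-matched rewired ensemble for every permutation network, under a
#' deterministic per-repetition seed stream (`seed + repetition`).
#'
#' @param residuals_a,residuals_b residual [volume_table]s of the two groups
#'   (identical ROI labels and order).
#' @param measures subset of `"clustering"`, `"path_length"`, `"gamma"`,
#'   `"lambda"`, `"sigma"`.
#' @param densities numeric vector of network densities (strictly
#'   increasing, in (0,1]).
#' @param repetitions number of label permutations (>= 100; the classical
#'   choice is 1000).
#' @param seed master seed; repetition m uses `seed + m`.
#' @param ensemble_size,iterations_per_edge null-ensemble parameters for
#'   gamma/lambda/sigma.
#' @param path_length_mode see [characteristic_path_length()].
#' @return data frame of class `permutation_result` with one row per
#'   measure x density: `measure`, `density`, `observed_diff`, `p`,
#'   `ci_low`, `ci_high`, `ok` (FALSE when the measure was undefined at that
#'   density for some permutation), plus attributes `null_diffs` (named list
#'   of numeric matrices, repetitions x densities), `repetitions`, `seed`.
#' @export
permutation_test <- function(residuals_a, residuals_b,
                             measures = "clustering",
                             densities,
                             repetitions = 1000L,
                             seed = 1L,
                             ensemble_size = 20L,
                             iterations_per_edge = 10L,
                             path_length_mode = c("component", "harmonic")) {
  path_length_mode <- match.arg(path_length_mode)
  stopifnot(identical(roi_labels(residuals_a), roi_labels(residuals_b)),
            repetitions >= 100L, all(diff(densities) > 0),
            all(densities > 0), all(densities <= 1))
  measures <- match.arg(measures, .global_measures, several.ok = TRUE)

  Ya <- volume_matrix(residuals_a)
  Yb <- volume_matrix(residuals_b)
  na <- nrow(Ya)
  pooled <- rbind(Ya, Yb)
  n_tot <- nrow(pooled)

  eval_groups <- function(ma, mb, rep_seed) {
    Ra <- stats::cor(ma); diag(Ra) <- 0
    Rb <- stats::cor(mb); diag(Rb) <- 0
    vapply(densities, function(d) {
      va <- try_measures(Ra, d, measures, path_length_mode,
                         ensemble_size, iterations_per_edge, rep_seed)
      vb <- try_measures(Rb, d, measures, path_length_mode,
                         ensemble_size, iterations_per_edge, rep_seed + 500000L)
      va - vb
    }, numeric(length(measures)))
  }

  observed <- eval_groups(Ya, Yb, seed)  # measures x densities
  if (length(measures) == 1L) observed <- matrix(observed, nrow = 1L)

  null_arr <- array(NA_real_,
                    c(repetitions, length(measures), length(densities)))
  for (m in seq_len(repetitions)) {
    set.seed(seed + m)
    idx <- sample.int(n_tot)
    nd <- eval_groups(pooled[idx[seq_len(na)], , drop = FALSE],
                      pooled[idx[(na + 1L):n_tot], , drop = FALSE],
                      seed + m)
    if (length(measures) == 1L) nd <- matrix(nd, nrow = 1L)
    null_arr[m, , ] <- nd
  }

  rows <- list(); nulls <- list()
  for (mi in seq_along(measures)) {
    nm <- matrix(null_arr[, mi, ], nrow = repetitions,
                 dimnames = list(NULL, format(densities)))
    nulls[[measures[mi]]] <- nm
    for (di in seq_along(densities)) {
      obs <- observed[mi, di]
      nd <- nm[, di]
      ok <- is.finite(obs) && all(is.finite(nd))
      if (ok) {
        s <- perm_summary(obs, nd)
      } else {
        s <- list(p = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        measure = measures[mi], density = densities[di],
        observed_diff = obs, p = s$p,
        ci_low = s$ci_low, ci_high = s$ci_high, ok = ok,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "null_diffs") <- nulls
  attr(out, "repetitions") <- as.integer(repetitions)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("permutation_result", "data.frame")
  out
}

# measure evaluation that flags undefined results instead of aborting
try_measures <- function(R, density, measures, path_length_mode,
                         ensemble_size, iterations_per_edge, seed) {
  tryCatch({
    g <- suppressWarnings(threshold_at_density(R, density))
    measure_values(g$adjacency, measures, path_length_mode,
                   ensemble_size, iterations_per_edge, seed)
  }, error = function(e) {
    stats::setNames(rep(NA_real_, length(measures)), measures)
  })
}

#' Permutation test of nodal betweenness and degree at one density
#'
#' Applies the same label-permutation machinery per node: at the chosen
#' density (typically the minimum full-connectivity density), each
#' permutation rebuilds both relabeled groups' graphs and records the
#' per-ROI difference (A minus B) in betweenness centrality and degree.
#' Each ROI gets its own two-tailed percentile p and 95% null interval.
#'
#' As a second, distinctly labeled reference, the mean nodal values over a
#' degree-matched rewired ensemble of each *observed* group's graph are
#' reported (`rand_mean_a`, `rand_mean_b`): the permutation null answers
#' "could this difference arise from group labels alone", the rewired null
#' answers "how would this node behave in a random graph of the same degree
#' sequence".
#'
#' @inheritParams permutation_test
#' @param density a single density; must leave both observed graphs
#'   connected.
#' @return data frame of class `nodal_permutation_result`: one row per
#'   ROI x measure (`betweenness`, `degree`) with `observed_diff`, `p`,
#'   `ci_low`, `ci_high`, `rand_mean_a`, `rand_mean_b`.
#' @export
nodal_comparison <- function(residuals_a, residuals_b, density,
                             repetitions = 1000L, seed = 1L,
                             ensemble_size = 20L, iterations_per_edge = 10L) {
  stopifnot(identical(roi_labels(residuals_a), roi_labels(residuals_b)),
            length(density) == 1L, repetitions >= 100L)
  Ya <- volume_matrix(residuals_a)
  Yb <- volume_matrix(residuals_b)
  na <- nrow(Ya)
  pooled <- rbind(Ya, Yb)
  n_tot <- nrow(pooled)
  labels <- roi_labels(residuals_a)
  n_roi <- length(labels)

  nodal_pair <- function(ma, mb) {
    Ra <- stats::cor(ma); diag(Ra) <- 0
    Rb <- stats::cor(mb); diag(Rb) <- 0
    ga <- suppressWarnings(threshold_at_density(Ra, density))
    gb <- suppressWarnings(threshold_at_density(Rb, density))
    list(a = betweenness_and_degree(ga), b = betweenness_and_degree(gb),
         ga = ga, gb = gb)
  }

  obs <- nodal_pair(Ya, Yb)
  if (igraph::components(as_ig(obs$ga$adjacency))$no > 1L ||
      igraph::components(as_ig(obs$gb$adjacency))$no > 1L) {
    stop("density ", density, " leaves an observed group's graph disconnected; ",
         "use min_full_connectivity_density()")
  }

  null_btw <- matrix(NA_real_, repetitions, n_roi)
  null_deg <- matrix(NA_real_, repetitions, n_roi)
  for (m in seq_len(repetitions)) {
    set.seed(seed + m)
    idx <- sample.int(n_tot)
    np <- nodal_pair(pooled[idx[seq_len(na)], , drop = FALSE],
                     pooled[idx[(na + 1L):n_tot], , drop = FALSE])
    null_btw[m, ] <- np$a$betweenness - np$b$betweenness
    null_deg[m, ] <- np$a$degree - np$b$degree
  }

  # rewired-ensemble reference for the observed graphs
  rand_ref <- function(g, offs) {
    ens <- generate_random_ensemble(g, size = ensemble_size,
                                    iterations_per_edge = iterations_per_edge,
                                    seed = seed + offs)
    vals <- vapply(ens$members, function(m) {
      nm <- betweenness_and_degree(m)
      c(nm$betweenness, nm$degree)
    }, numeric(2L * n_roi))
    rm <- rowMeans(vals)
    list(btw = rm[seq_len(n_roi)], deg = rm[n_roi + seq_len(n_roi)])
  }
  ra <- rand_ref(obs$ga, 1000000L)
  rb <- rand_ref(obs$gb, 2000000L)

  build_rows <- function(measure, obs_diff, null_mat, rand_a, rand_b) {
    out <- lapply(seq_len(n_roi), function(i) {
      s <- perm_summary(obs_diff[i], null_mat[, i])
      data.frame(measure = measure, roi = labels[i],
                 observed_diff = obs_diff[i], p = s$p,
                 ci_low = s$ci_low, ci_high = s$ci_high,
                 rand_mean_a = rand_a[i], rand_mean_b = rand_b[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  out <- rbind(
    build_rows("betweenness", obs$a$betweenness - obs$b$betweenness,
               null_btw, ra$btw, rb$btw),
    build_rows("degree", as.numeric(obs$a$degree - obs$b$degree),
               null_deg, ra$deg, rb$deg))
  attr(out, "density") <- density
  attr(out, "repetitions") <- as.integer(repetitions)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("nodal_permutation_result", "data.frame")
  out
}
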