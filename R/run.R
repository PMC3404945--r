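#' Run configuration for the full analysis
#'
#' Collects every tunable of the end-to-end pipeline. `densities` defaults
#' to the grid 0.05-0.50 in steps of 0.01; `repetitions` defaults to the
#' classical 1000 label permutations; the rewired null ensemble has 20
#' members with 10 swap attempts per edge. Any field can be overridden; a
#' config can also be read from a JSON file with [read_run_config()].
#'
#' @param group_a,group_b paths to the two groups' volume CSVs.
#' @param covariates nuisance covariates to regress out.
#' @param densities density grid for the sweep (strictly increasing).
#' @param repetitions permutations for every test (>= 100).
#' @param ensemble_size,iterations_per_edge rewired-null parameters.
#' @param path_length_mode `"component"` or `"harmonic"`.
#' @param pooled_confound_fit fit confound regressions on the pooled groups
#'   instead of per group (default `FALSE`).
#' @param measures global measures for the density sweep.
#' @param seed master seed for all randomness in the run.
#' @param out_dir output directory (created if absent).
#' @return a `run_config` list.
#' @export
run_config <- function(group_a, group_b,
                       covariates = c("age", "tbv"),
                       densities = seq(0.05, 0.50, by = 0.01),
                       repetitions = 1000L,
                       ensemble_size = 20L,
                       iterations_per_edge = 10L,
                       path_length_mode = "component",
                       pooled_confound_fit = FALSE,
                       measures = c("clustering", "path_length", "gamma",
                                    "lambda", "sigma"),
                       seed = 1L,
                       out_dir = "covnet_results") {
  cfg <- list(group_a = group_a, group_b = group_b, covariates = covariates,
              densities = densities, repetitions = as.integer(repetitions),
              ensemble_size = as.integer(ensemble_size),
              iterations_per_edge = as.integer(iterations_per_edge),
              path_length_mode = path_length_mode,
              pooled_confound_fit = isTRUE(pooled_confound_fit),
              measures = measures, seed = as.integer(seed),
              out_dir = out_dir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  for (f in c("group_a", "group_b")) {
    if (!file.exists(cfg[[f]])) stop("config: file not found: ", cfg[[f]])
  }
  if (cfg$repetitions < 100L) stop("config: repetitions must be >= 100")
  d <- cfg$densities
  if (any(d <= 0) || any(d > 1) || any(diff(d) <= 0)) {
    stop("config: densities must be strictly increasing in (0, 1]")
  }
  if (!cfg$path_length_mode %in% c("component", "harmonic")) {
    stop("config: unknown path_length_mode '", cfg$path_length_mode, "'")
  }
  bad <- setdiff(cfg$measures, .global_measures)
  if (length(bad)) stop("config: unknown measure(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' @rdname run_config
#' @param path JSON file holding any subset of the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("config: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Run the full structural covariance network analysis
#'
#' Executes the whole pipeline on two groups' volume tables:
#' confound regression; per-group association matrices; Fisher r-to-z
#' correlation-strength comparison; minimum full-connectivity density;
#' global small-world metrics for both groups at that density; permutation
#' comparison of the global measures across the density grid; per-ROI
#' betweenness/degree permutation comparison and hub identification at the
#' minimum density. All tables are written as CSV, summary objects as JSON,
#' and a run report (config, seeds, package version) makes the run exactly
#' reproducible. Timings go to `run.log` only, so result files are
#' byte-identical across reruns with the same config and seed.
#'
#' @param config a `run_config`.
#' @return the run report (list), invisibly; all artifacts under
#'   `config$out_dir`.
#' @export
run_full_analysis <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    say("stage ", name, " start")
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say("stage ", name, " done")
    r
  }
  out <- function(...) file.path(config$out_dir, paste0(...))

  tabs <- stage("read", list(a = read_volume_table(config$group_a, config$covariates),
                             b = read_volume_table(config$group_b, config$covariates)))
  stopifnot(identical(roi_labels(tabs$a), roi_labels(tabs$b)))

  resid <- stage("preprocess", {
    if (config$pooled_confound_fit) {
      rr <- regress_confounds_pooled(tabs$a, tabs$b, config$covariates)
      list(a = rr[[1]], b = rr[[2]])
    } else {
      list(a = regress_confounds(tabs$a, config$covariates),
           b = regress_confounds(tabs$b, config$covariates))
    }
  })
  write_volume_table(resid$a, out("residuals_a.csv"))
  write_volume_table(resid$b, out("residuals_b.csv"))

  assoc <- stage("associate", list(a = build_association_matrix(resid$a),
                                   b = build_association_matrix(resid$b)))
  write_matrix_csv(assoc$a, out("association_a.csv"))
  write_matrix_csv(assoc$b, out("association_b.csv"))

  strength <- stage("strength", compare_strength(assoc$a, assoc$b))

  d_min <- stage("min_density", min_full_connectivity_density(list(assoc$a, assoc$b)))
  say("minimum full-connectivity density: ", format(d_min))

  graphs <- stage("threshold", list(a = threshold_at_density(assoc$a, d_min),
                                    b = threshold_at_density(assoc$b, d_min)))
  for (g in c("a", "b")) {
    write_matrix_csv(graphs[[g]]$adjacency, out("adjacency_", g, "_mindensity.csv"))
    write_edge_list(graphs[[g]], out("edges_", g, "_mindensity.txt"))
  }

  globals <- stage("global_metrics", {
    lapply(stats::setNames(c("a", "b"), c("a", "b")), function(g) {
      ens <- generate_random_ensemble(
        graphs[[g]], size = config$ensemble_size,
        iterations_per_edge = config$iterations_per_edge,
        seed = config$seed + if (g == "a") 3000000L else 4000000L)
      small_worldness(graphs[[g]], ens, config$path_length_mode)
    })
  })

  sweep <- stage("density_sweep", permutation_test(
    resid$a, resid$b, measures = config$measures,
    densities = config$densities, repetitions = config$repetitions,
    seed = config$seed, ensemble_size = config$ensemble_size,
    iterations_per_edge = config$iterations_per_edge,
    path_length_mode = config$path_length_mode))
  utils::write.csv(as.data.frame(sweep), out("global_comparison.csv"),
                   row.names = FALSE, quote = FALSE)

  nodal <- stage("nodal", nodal_comparison(
    resid$a, resid$b, density = d_min,
    repetitions = config$repetitions, seed = config$seed,
    ensemble_size = config$ensemble_size,
    iterations_per_edge = config$iterations_per_edge))
  utils::write.csv(as.data.frame(nodal), out("nodal_comparison.csv"),
                   row.names = FALSE, quote = FALSE)

  hubs <- stage("hubs", {
    nm <- lapply(graphs, betweenness_and_degree)
    for (g in c("a", "b")) {
      utils::write.csv(as.data.frame(nm[[g]]), out("nodal_metrics_", g, ".csv"),
                       row.names = FALSE, quote = FALSE)
    }
    lapply(nm, identify_hubs)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("covnet")),
    config = unclass(config),
    groups = list(a = group_label(tabs$a), b = group_label(tabs$b)),
    n_subjects = list(a = nrow(tabs$a), b = nrow(tabs$b)),
    n_rois = length(roi_labels(tabs$a)),
    min_full_connectivity_density = d_min,
    strength_comparison = unclass(strength),
    global_metrics_at_min_density = lapply(globals, unclass),
    hubs = hubs)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say(sprintf("total elapsed: %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, out("run.log"))
  invisible(report)
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(roi = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_edge_list <- function(g, path) {
  adj <- g$adjacency
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- sprintf("%s\t%s\t1", g$roi_labels[idx[, 1L]], g$roi_labels[idx[, 2L]])
  writeLines(lines, path)
}
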