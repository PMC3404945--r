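#' Regress nuisance covariates out of every ROI
#'
#' Fits, for each ROI column, an ordinary least-squares regression of volume
#' on an intercept plus the named covariates, and substitutes the residuals
#' for the raw values. This is the standard adjustment step before building
#' a structural covariance network: the association matrix is computed from
#' residual volumes so that shared age and head-size effects do not inflate
#' inter-regional correlations.
#'
#' The fit can be done within one group's table (the default pipeline runs it
#' per group) or on a pooled table via [regress_confounds_pooled()]; see the
#' methods vignette for why the permutation test always uses residuals
#' computed once, before any relabeling.
#'
#' @param table a [volume_table].
#' @param covariate_names covariate columns to remove (default `age`, `tbv`).
#' @return a `volume_table` whose ROI columns hold residuals (mean zero,
#'   orthogonal to each covariate), flagged with attribute
#'   `residualized = TRUE`.
#' @export
regress_confounds <- function(table, covariate_names = c("age", "tbv")) {
  stopifnot(inherits(table, "volume_table"))
  missing_cov <- setdiff(covariate_names, names(table))
  if (length(missing_cov) > 0L) {
    stop("covariate(s) not in table: ", paste(missing_cov, collapse = ", "))
  }
  n <- nrow(table)
  p <- length(covariate_names) + 1L  # + intercept
  if (n < p + 1L) {
    stop("need at least ", p + 1L, " subjects to fit ", p,
         " regression parameters; have ", n)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(table[, covariate_names, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design: covariate(s) collinear with the rest: ",
         paste(dropped, collapse = ", "))
  }
  Y <- volume_matrix(table)
  res <- qr.resid(qx, Y)
  out <- as.data.frame(table)
  out[, colnames(res)] <- res
  out <- as_volume_table(out, covariates = attr(table, "covariates"))
  attr(out, "residualized") <- TRUE
  out
}

#' @rdname regress_confounds
#'
#' @details `regress_confounds_pooled()` stacks the two groups, fits the
#'   per-ROI regressions once on the pooled design, and returns the split
#'   residual tables. Pooled fitting keeps a single set of regression
#'   coefficients across groups, which some studies prefer; the per-group
#'   default mirrors building each group's network from its own table.
#'
#' @param table_a,table_b the two groups' [volume_table]s (identical ROI
#'   labels, identical order).
#' @export
regress_confounds_pooled <- function(table_a, table_b,
                                     covariate_names = c("age", "tbv")) {
  stopifnot(identical(roi_labels(table_a), roi_labels(table_b)))
  pooled <- rbind(as.data.frame(table_a), as.data.frame(table_b))
  pooled$group <- "pooled"
  pooled <- as_volume_table(pooled, covariates = attr(table_a, "covariates"))
  res <- regress_confounds(pooled, covariate_names)
  na <- nrow(table_a)
  split_one <- function(rows, template) {
    out <- as.data.frame(res)[rows, , drop = FALSE]
    out$group <- group_label(template)
    rownames(out) <- NULL
    out <- as_volume_table(out, covariates = attr(template, "covariates"))
    attr(out, "residualized") <- TRUE
    out
  }
  list(split_one(seq_len(na), table_a),
       split_one(na + seq_len(nrow(table_b)), table_b))
}
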