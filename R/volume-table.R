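#' Subject-by-ROI volume tables
#'
#' A `volume_table` is a plain data frame with one row per subject and columns
#' `subject_id`, `group`, one column per covariate (by default `age` and
#' `tbv`, the total brain volume), followed by one numeric column per region
#' of interest (ROI). It is the container for both raw gray-matter volumes
#' and, after [regress_confounds()], their confound-adjusted residuals.
#'
#' @param df data frame with the columns described above.
#' @param covariates character vector naming the covariate columns.
#' @name volume_table
NULL

.vt_reserved <- function(covariates) c("subject_id", "group", covariates)

#' @describeIn volume_table validate a data frame and stamp the class.
#' @export
as_volume_table <- function(df, covariates = c("age", "tbv")) {
  stopifnot(is.data.frame(df))
  need <- .vt_reserved(covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("volume table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  rois <- setdiff(names(df), need)
  if (length(rois) < 2L) stop("volume table needs at least 2 ROI columns")
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicate subject_id: ", paste(dup, collapse = ", "))
  }
  num_cols <- c(covariates, rois)
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop("column '", cn, "' is not numeric")
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      stop("non-finite value in column '", cn, "', row ", bad,
           " (subject ", df$subject_id[bad], ")")
    }
  }
  if (length(unique(df$group)) != 1L) {
    stop("a volume table holds exactly one group; found: ",
         paste(unique(df$group), collapse = ", "))
  }
  structure(df, class = c("volume_table", "data.frame"),
            covariates = covariates)
}

#' @describeIn volume_table ROI label vector, in column order.
#' @param x a `volume_table`.
#' @export
roi_labels <- function(x) {
  setdiff(names(x), .vt_reserved(attr(x, "covariates")))
}

#' @describeIn volume_table numeric subjects-by-ROI matrix (rownames =
#'   subject ids).
#' @export
volume_matrix <- function(x) {
  m <- as.matrix(x[, roi_labels(x), drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

#' @describeIn volume_table group label (scalar).
#' @export
group_label <- function(x) unique(x$group)

#' @export
print.volume_table <- function(x, ...) {
  cat(sprintf("<volume_table> group '%s': %d subjects x %d ROIs (covariates: %s)\n",
              group_label(x), nrow(x), length(roi_labels(x)),
              paste(attr(x, "covariates"), collapse = ", ")))
  invisible(x)
}

#' Read / write volume tables as CSV
#'
#' The on-disk dialect is a plain CSV with a header row: `subject_id`,
#' `group`, the covariate columns, then one column per ROI label. Reading
#' validates the table (no missing or non-numeric cells, unique subject ids)
#' and preserves ROI column order from the file.
#'
#' @param path file path.
#' @param covariates covariate column names expected in the file.
#' @return `read_volume_table()` returns a [volume_table];
#'   `write_volume_table()` returns `path` invisibly.
#' @export
read_volume_table <- function(path, covariates = c("age", "tbv")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_volume_table(df, covariates = covariates)
}

#' @rdname read_volume_table
#' @param x a `volume_table`.
#' @export
write_volume_table <- function(x, path) {
  stopifnot(inherits(x, "volume_table"))
  df <- as.data.frame(x)
  # %.17g keeps doubles bit-exact across a write/read round trip
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled AAL-90 region labels
#'
#' Returns the 90 cortical and subcortical region labels (45 bilateral
#' abbreviations, `_L`/`_R` suffixed) conventionally used for whole-brain
#' gray-matter parcellation with the AAL atlas, cerebellum excluded.
#'
#' @return character vector of length 90.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "covnet",
                      mustWork = TRUE)
  readLines(path)
}
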