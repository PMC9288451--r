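#' Construct an expression matrix container
#'
#' A light wrapper around a numeric features x samples matrix that records
#' what the values are (`counts` or `log_cpm`) and which feature class they
#' measure (`mrna` or `mirna`). All pipeline steps accept and return this
#' container so that scale mix-ups (e.g. testing on raw counts) are caught
#' early.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   non-empty unique dimnames.
#' @param kind `"mrna"` or `"mirna"`.
#' @param scale `"counts"` (non-negative) or `"log_cpm"`.
#' @return An object of class `fc_expression_matrix`.
#' @export
expression_matrix <- function(values, kind = c("mrna", "mirna"),
                              scale = c("counts", "log_cpm")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    fc_stop("fc_non_numeric", "expression values must form a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    fc_stop("fc_missing_ids", "expression matrix needs feature and sample names")
  }
  if (anyDuplicated(rownames(values))) {
    fc_stop("fc_duplicate_id", "duplicate feature ids: %s",
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    fc_stop("fc_duplicate_id", "duplicate sample ids: %s",
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    fc_stop("fc_non_numeric", "expression values must be finite")
  }
  if (scale == "counts" && any(values < 0)) {
    fc_stop("fc_negative_count", "negative count in expression matrix")
  }
  structure(list(values = values, kind = kind, scale = scale),
            class = "fc_expression_matrix")
}

#' @export
print.fc_expression_matrix <- function(x, ...) {
  cat(sprintf("<fc_expression_matrix> %s, %s: %d features x %d samples\n",
              x$kind, x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.fc_expression_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# Subset an expression matrix by feature and/or sample ids, keeping metadata.
em_subset <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, kind = x$kind, scale = x$scale)
}
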