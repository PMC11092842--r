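# Feature transform contract: the six right-skewed count features are
# log-transformed (ln(1+x), safe at zero counts), then every feature is
# min-max scaled with statistics fitted on training rows only. At predict
# time values outside the training range are clamped to [0, 1]; a column
# constant in training maps to 0.

#' Names of the log-transformed features
#'
#' The six right-skewed count features that receive a `log1p` transform
#' before min-max scaling: overlapping gene, exon, promoter, disease and
#' pathogenic-SNV counts, and bp length.
#' @return character vector of six feature names.
#' @export
log_features <- function() {
  c("gene_count", "disease_count", "exon_count", "promoter_count",
    "pathogenic_snv_count", "bp_length")
}

#' Fit the feature transformer on training data
#'
#' @param x training feature matrix or data frame (numeric columns; an
#'   `id` column, if present, is ignored).
#' @param log_cols columns to log1p-transform before scaling.
#' @return an object of class `feature_transformer` holding the per-column
#'   post-log minima and maxima.
#' @export
fit_transformer <- function(x, log_cols = log_features()) {
  x <- .feature_numeric(x)
  log_cols <- intersect(log_cols, colnames(x))
  for (cc in log_cols) x[[cc]] <- log1p(x[[cc]])
  mins <- vapply(x, min, 0)
  maxs <- vapply(x, max, 0)
  obj <- list(log_cols = log_cols, features = colnames(x),
              min = mins, max = maxs)
  class(obj) <- "feature_transformer"
  obj
}

#' Apply a fitted transformer
#'
#' @param transformer a `feature_transformer` from [fit_transformer()].
#' @param x feature matrix/data frame with the training columns.
#' @return data frame of transformed features, all values in \[0, 1\].
#' @export
apply_transformer <- function(transformer, x) {
  if (!inherits(transformer, "feature_transformer"))
    stop("transformer is not fitted (expected a 'feature_transformer')")
  ids <- if (is.data.frame(x) && "id" %in% colnames(x)) x$id else NULL
  x <- .feature_numeric(x)
  miss <- setdiff(transformer$features, colnames(x))
  if (length(miss))
    stop("feature column(s) missing: ", paste(miss, collapse = ", "))
  x <- x[, transformer$features, drop = FALSE]
  for (cc in transformer$log_cols) x[[cc]] <- log1p(x[[cc]])
  for (cc in transformer$features) {
    rng <- transformer$max[[cc]] - transformer$min[[cc]]
    x[[cc]] <- if (rng == 0) rep(0, nrow(x)) else
      pmin(1, pmax(0, (x[[cc]] - transformer$min[[cc]]) / rng))
  }
  if (!is.null(ids)) rownames(x) <- NULL
  x
}

#' @export
print.feature_transformer <- function(x, ...) {
  cat("feature_transformer:", length(x$features), "features;",
      length(x$log_cols), "log1p-transformed\n")
  invisible(x)
}

.feature_numeric <- function(x) {
  x <- as.data.frame(x)
  x$id <- NULL
  nonnum <- names(x)[!vapply(x, is.numeric, TRUE)]
  if (length(nonnum))
    stop("non-numeric feature column(s): ", paste(nonnum, collapse = ", "))
  x
}
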