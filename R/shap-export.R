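# Static exports of Shapley attributions: a beeswarm plot per class and a
# per-variant force plot, each as a portable image (PNG or SVG by file
# extension) with a machine-readable TSV written beside it so downstream
# checks never parse pixels. Features are ranked by mean |attribution|.

.attr_ranking <- function(attr, class) {
  phi <- attr$phi[[class]]
  imp <- colMeans(abs(phi))
  ord <- order(-imp, colnames(phi))  # deterministic: ties by name
  data.frame(feature = colnames(phi)[ord], rank = seq_along(ord),
             mean_abs_shap = imp[ord], stringsAsFactors = FALSE)
}

.open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height, res = 110),
         svg = grDevices::svg(path, width = width / 110, height = height / 110),
         stop("unsupported image format '", ext, "' (use .png or .svg)"))
}

#' Export a SHAP beeswarm plot
#'
#' One row per feature (ranked by mean absolute attribution, most
#' influential on top), one jittered point per observation, colored by the
#' observation's feature value. A TSV twin holds every plotted value.
#'
#' @param attr an `attribution_matrix` from [attribute()].
#' @param class which class's attributions to plot.
#' @param path image file (.png or .svg); the TSV twin is written to
#'   `paste0(path, ".tsv")` unless `tsv_path` is given.
#' @param tsv_path optional TSV path.
#' @param max_features rows shown in the plot (TSV always holds all).
#' @return invisible list with `image` and `tsv` paths.
#' @export
export_beeswarm <- function(attr, class, path, tsv_path = NULL,
                            max_features = 15) {
  stopifnot(inherits(attr, "attribution_matrix"), class %in% attr$classes)
  if (is.null(tsv_path)) tsv_path <- paste0(path, ".tsv")
  rk <- .attr_ranking(attr, class)
  phi <- attr$phi[[class]]
  ids <- if (is.null(attr$ids)) as.character(seq_len(nrow(phi))) else attr$ids

  tsv <- do.call(rbind, lapply(seq_len(nrow(rk)), function(i) {
    f <- rk$feature[i]
    data.frame(feature = f, rank = rk$rank[i],
               mean_abs_shap = rk$mean_abs_shap[i], cnv_id = ids,
               shap_value = phi[, f], feature_value = attr$X[, f],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(format(tsv, digits = 10, trim = TRUE, scientific = FALSE),
                     tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)

  show <- utils::head(rk$feature, max_features)
  .open_device(path, 900, 110 + 42 * length(show))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 12, 2, 1))
  xlim <- range(phi[, show, drop = FALSE], 0)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, length(show) + 0.5),
                 yaxt = "n", xlab = "Shapley value (impact on class score)",
                 ylab = "", main = paste0("Feature attributions: ", class))
  graphics::axis(2, at = rev(seq_along(show)), labels = show, las = 1,
                 cex.axis = 0.8)
  graphics::abline(v = 0, col = "grey60")
  set.seed(1)  # jitter only; data content lives in the TSV
  for (i in seq_along(show)) {
    f <- show[i]
    v <- attr$X[, f]
    rngv <- range(v)
    col_w <- if (diff(rngv) == 0) rep(0.5, length(v)) else
      (v - rngv[1]) / diff(rngv)
    cols <- grDevices::rgb(col_w, 0.2, 1 - col_w, alpha = 0.75)
    graphics::points(phi[, f],
                     rep(length(show) - i + 1, nrow(phi)) +
                       stats::runif(nrow(phi), -0.25, 0.25),
                     pch = 16, cex = 0.6, col = cols)
  }
  invisible(list(image = path, tsv = tsv_path))
}

#' Export a SHAP force plot for one CNV
#'
#' Waterfall-style horizontal bars from the class base value to the
#' model's output for one observation, one bar per feature, ranked by
#' absolute attribution. A TSV twin holds the plotted values.
#'
#' @inheritParams export_beeswarm
#' @param cnv_id the observation to explain (an `id` from the attributed
#'   set, or a row number when the set carries no ids).
#' @return invisible list with `image` and `tsv` paths.
#' @export
export_force <- function(attr, cnv_id, class, path, tsv_path = NULL,
                         max_features = 12) {
  stopifnot(inherits(attr, "attribution_matrix"), class %in% attr$classes)
  ids <- if (is.null(attr$ids)) as.character(seq_len(nrow(attr$X))) else attr$ids
  row <- match(as.character(cnv_id), ids)
  if (is.na(row)) stop("unknown cnv_id: ", cnv_id)
  if (is.null(tsv_path)) tsv_path <- paste0(path, ".tsv")

  phi <- attr$phi[[class]][row, ]
  ord <- order(-abs(phi), names(phi))
  tsv <- data.frame(cnv_id = as.character(cnv_id), class = class,
                    base_value = attr$base[[class]],
                    output = attr$base[[class]] + sum(phi),
                    feature = names(phi)[ord], shap_value = phi[ord],
                    feature_value = attr$X[row, ord],
                    stringsAsFactors = FALSE)
  utils::write.table(format(tsv, digits = 10, trim = TRUE, scientific = FALSE),
                     tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)

  show <- utils::head(ord, max_features)
  .open_device(path, 900, 140 + 34 * length(show))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 12, 3, 1))
  vals <- phi[show]
  cum <- attr$base[[class]] + c(0, cumsum(vals))
  graphics::plot(NA, xlim = range(cum), ylim = c(0.5, length(show) + 0.5),
                 yaxt = "n", xlab = paste0("class score (base -> output), ",
                                           "base = ", signif(attr$base[[class]], 4)),
                 ylab = "",
                 main = sprintf("Force plot: %s (%s)", cnv_id, class))
  graphics::axis(2, at = rev(seq_along(show)),
                 labels = names(phi)[show], las = 1, cex.axis = 0.8)
  for (i in seq_along(show)) {
    graphics::segments(cum[i], length(show) - i + 1, cum[i + 1],
                       length(show) - i + 1, lwd = 8,
                       col = if (vals[i] >= 0) "#d73027" else "#4575b4")
  }
  graphics::abline(v = attr$base[[class]], lty = 2, col = "grey50")
  invisible(list(image = path, tsv = tsv_path))
}
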