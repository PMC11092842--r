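# Per-CNV-type model training: cross-validated architecture ranking over a
# roster, randomized hyperparameter search, one-vs-rest isotonic
# calibration, and three-class probabilistic prediction with an argmax
# label (ties broken pathogenic > VUS > benign, the clinically
# conservative direction). Deletion and duplication models are trained
# independently; the caller routes CNVs by type.

.class_levels <- function() factor(character(), levels = significance_classes())

.as_class_factor <- function(y) {
  y <- factor(as.character(y), levels = significance_classes())
  if (anyNA(y)) stop("labels must be benign / VUS / pathogenic")
  droplevels(y, exclude = NULL)
}

#' Stratified cross-validation folds
#'
#' Assigns each example to one of `k` folds, shuffling within class so
#' every fold carries all classes.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment per example.
#' @export
stratified_folds <- function(y, k = 5, seed = 1) {
  y <- as.factor(y)
  tab <- table(y)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
         " example(s), fewer than k = ", k, " folds; use a smaller k")
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Argmax labels with deterministic priority tie-break.
.argmax_label <- function(probs) {
  classes <- colnames(probs)
  priority <- c(pathogenic = 3, VUS = 2, benign = 1)[classes]
  apply(probs, 1, function(p) {
    best <- which(p == max(p))
    classes[best[order(-priority[best])[1]]]
  })
}

# Mean cross-validated macro F1 of one architecture/hyperparameter setting.
.cv_macro_f1 <- function(arch, params, x, y, folds, seed) {
  scores <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- tryCatch(arch$fit(x[tr, , drop = FALSE], y[tr], params,
                             seed = seed + f),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    p <- tryCatch(arch$prob(fit, x[!tr, , drop = FALSE], levels(y)),
                  error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    multiclass_summary(.argmax_label(p), y[!tr])$macro_f1
  }, 0)
  if (all(is.na(scores))) -Inf else mean(scores, na.rm = TRUE)
}

#' Rank candidate architectures by cross-validated macro F1
#'
#' Runs stratified k-fold cross-validation for every roster entry at its
#' default hyperparameters and ranks by mean multi-class (macro) F1.
#' Deterministic for a fixed seed; ties resolve in roster order.
#'
#' @param x feature matrix (already transformed).
#' @param y labels over benign / VUS / pathogenic.
#' @param roster architecture list, see [default_roster()].
#' @param k folds (default 5).
#' @param seed RNG seed.
#' @return data frame with `architecture`, `mean_macro_f1`, sorted best
#'   first.
#' @export
select_architecture <- function(x, y, roster = default_roster(), k = 5,
                                seed = 1) {
  if (!length(roster)) stop("roster must be non-empty")
  y <- .as_class_factor(y)
  folds <- stratified_folds(y, k, seed)
  f1 <- vapply(roster, function(arch)
    .cv_macro_f1(arch, arch$defaults, x, y, folds, seed), 0)
  out <- data.frame(architecture = names(roster), mean_macro_f1 = f1,
                    stringsAsFactors = FALSE)
  out[order(-out$mean_macro_f1), , drop = FALSE]
}

#' Randomized hyperparameter search for one architecture
#'
#' Draws `n_draws` hyperparameter sets from the architecture's space and
#' scores each by stratified k-fold macro F1; best draw wins, ties broken
#' by draw order. An architecture with an empty space returns its defaults
#' with a note.
#'
#' @inheritParams select_architecture
#' @param arch one roster entry.
#' @param n_draws number of random draws.
#' @return list with `params`, `score`, `draws` (per-draw score table) and
#'   `note`.
#' @export
tune_hyperparameters <- function(x, y, arch, n_draws = 50, k = 5, seed = 1) {
  y <- .as_class_factor(y)
  if (is.null(arch$space) || !length(arch$space))
    return(list(params = arch$defaults, score = NA_real_, draws = NULL,
                note = "empty hyperparameter space; defaults returned"))
  folds <- stratified_folds(y, k, seed)
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) sample_hyperparameters(arch$space))
  scores <- vapply(draws, function(p) .cv_macro_f1(arch, p, x, y, folds, seed), 0)
  best <- which.max(scores)  # first max wins: tie-break by draw order
  list(params = draws[[best]], score = scores[best],
       draws = data.frame(draw = seq_len(n_draws), macro_f1 = scores),
       note = NULL)
}

#' Fit and isotonically calibrate the final model
#'
#' Produces out-of-fold raw class probabilities via stratified k-fold
#' refits, fits one isotonic regression per class (one-vs-rest) on them,
#' refits the estimator on all rows, and returns the calibrated ensemble.
#'
#' @inheritParams tune_hyperparameters
#' @param params hyperparameters for the final fit.
#' @return list with `fit`, `calibrators`, `oof_probs`, `folds`.
#' @export
calibrate_and_fit <- function(x, y, arch, params, k = 5, seed = 1) {
  y <- .as_class_factor(y)
  folds <- stratified_folds(y, k, seed)
  classes <- levels(y)
  oof <- matrix(NA_real_, nrow(x), length(classes),
                dimnames = list(NULL, classes))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < length(classes))
      stop("a training fold lost a class; cannot calibrate")
    fit_f <- arch$fit(x[tr, , drop = FALSE], y[tr], params, seed = seed + f)
    oof[!tr, ] <- arch$prob(fit_f, x[!tr, , drop = FALSE], classes)
  }
  calibrators <- fit_calibrators(oof, y, classes)
  final <- arch$fit(x, y, params, seed = seed)
  list(fit = final, calibrators = calibrators, oof_probs = oof, folds = folds)
}

#' Train a calibrated multi-class CNV significance classifier
#'
#' The package's central fitting function. Given a raw feature matrix and
#' three-class labels for one CNV type, it (1) fits the log/min-max
#' feature transformer on the training rows, (2) ranks the architecture
#' roster by stratified k-fold macro F1, (3) runs a randomized
#' hyperparameter search on the winning architecture, (4) fits one
#' isotonic calibrator per class on out-of-fold probabilities and refits
#' the estimator on all rows. Everything is deterministic for a fixed
#' seed.
#'
#' @param x raw (untransformed) feature data frame from
#'   [extract_features()]; an `id` column is ignored.
#' @param y labels over benign / VUS / pathogenic.
#' @param cnv_type `"DEL"` or `"DUP"`; recorded and enforced at predict
#'   time.
#' @param roster candidate architectures, see [default_roster()].
#' @param folds cross-validation folds (default 5).
#' @param n_draws randomized hyperparameter draws (default 50).
#' @param seed RNG seed.
#' @param transform fit and apply the feature transformer (default TRUE;
#'   set FALSE if `x` is already transformed).
#' @return an object of class `cnv_classifier`.
#' @seealso [predict.cnv_classifier()], [attribute()]
#' @export
cnv_classifier <- function(x, y, cnv_type = c("DEL", "DUP"),
                           roster = default_roster(), folds = 5,
                           n_draws = 50, seed = 1, transform = TRUE) {
  cnv_type <- match.arg(cnv_type)
  y <- .as_class_factor(y)
  transformer <- NULL
  if (transform) {
    transformer <- fit_transformer(x)
    xt <- as.matrix(apply_transformer(transformer, x))
  } else xt <- as.matrix(.feature_numeric(x))

  ranking <- select_architecture(xt, y, roster, k = folds, seed = seed)
  arch <- roster[[ranking$architecture[1]]]
  tuned <- tune_hyperparameters(xt, y, arch, n_draws = n_draws, k = folds,
                                seed = seed)
  cal <- calibrate_and_fit(xt, y, arch, tuned$params, k = folds, seed = seed)

  obj <- list(cnv_type = cnv_type, architecture = arch$id,
              hyperparameters = tuned$params, transformer = transformer,
              fit = cal$fit, calibrators = cal$calibrators,
              arch_adapter = arch, class_levels = levels(y), seed = seed,
              folds = folds, n_draws = n_draws,
              cv_summary = list(architecture_ranking = ranking,
                                tuning_score = tuned$score,
                                tuning_note = tuned$note),
              feature_names = colnames(xt), n = nrow(xt),
              train_x = xt,   # kept for cover reconstruction in attribute()
              class_counts = as.list(table(y)))
  class(obj) <- "cnv_classifier"
  obj
}

#' Predict CNV clinical significance
#'
#' Returns calibrated probabilities of benign, uncertain and pathogenic
#' significance plus the argmax label (ties broken
#' pathogenic > VUS > benign).
#'
#' @param object a `cnv_classifier`.
#' @param newdata either a raw feature data frame (as from
#'   [extract_features()]) or a `cnv_set` (then `bundle` is required and
#'   features are extracted first).
#' @param bundle an `annotation_bundle`, when `newdata` is a `cnv_set`.
#' @param calibrated return calibrated (default) or raw probabilities.
#' @param ... unused.
#' @return data frame with `id` (if available), `pr_benign`, `pr_vus`,
#'   `pr_pathogenic`, `label`.
#' @export
predict.cnv_classifier <- function(object, newdata, bundle = NULL,
                                   calibrated = TRUE, ...) {
  ids <- NULL
  if (inherits(newdata, "cnv_set")) {
    if (is.null(bundle))
      stop("an annotation bundle is required to featurize a cnv_set")
    if (any(newdata$type != object$cnv_type))
      stop("CNV type mismatch: model is for ", object$cnv_type,
           "; route DEL/DUP records to their own models")
    newdata <- extract_features(newdata, bundle)
  }
  if (is.data.frame(newdata) && "id" %in% colnames(newdata))
    ids <- newdata$id
  if (nrow(newdata) == 0) {
    out <- data.frame(id = character(), pr_benign = numeric(),
                      pr_vus = numeric(), pr_pathogenic = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    return(out)
  }
  xt <- if (!is.null(object$transformer))
    as.matrix(apply_transformer(object$transformer, newdata))
  else as.matrix(.feature_numeric(newdata))
  raw <- object$arch_adapter$prob(object$fit, xt, object$class_levels)
  probs <- if (calibrated) apply_calibrators(object$calibrators, raw) else raw
  out <- data.frame(pr_benign = probs[, "benign"],
                    pr_vus = probs[, "VUS"],
                    pr_pathogenic = probs[, "pathogenic"],
                    label = .argmax_label(probs),
                    stringsAsFactors = FALSE)
  if (!is.null(ids)) out <- cbind(data.frame(id = ids,
                                             stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' @export
print.cnv_classifier <- function(x, ...) {
  cat(sprintf("cnv_classifier (%s): %s architecture, %d training CNVs\n",
              x$cnv_type, x$architecture, x$n))
  cat("  classes:", paste(sprintf("%s=%d", names(x$class_counts),
                                  unlist(x$class_counts)), collapse = " "), "\n")
  cat(sprintf("  CV macro F1 (architecture selection): %.4f\n",
              x$cv_summary$architecture_ranking$mean_macro_f1[1]))
  if (!is.na(x$cv_summary$tuning_score))
    cat(sprintf("  CV macro F1 (tuned): %.4f\n", x$cv_summary$tuning_score))
  invisible(x)
}

#' @export
summary.cnv_classifier <- function(object, ...) {
  cat("Architecture ranking (stratified ", object$folds, "-fold CV):\n",
      sep = "")
  print(object$cv_summary$architecture_ranking, row.names = FALSE)
  cat("\nSelected hyperparameters (", object$n_draws, " random draws):\n",
      sep = "")
  utils::str(object$hyperparameters, give.attr = FALSE)
  invisible(object)
}

#' @export
plot.cnv_classifier <- function(x, ...) {
  r <- x$cv_summary$architecture_ranking
  graphics::dotchart(rev(r$mean_macro_f1), labels = rev(r$architecture),
                     xlab = "CV macro F1",
                     main = sprintf("Architecture selection (%s)", x$cnv_type))
  invisible(x)
}
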