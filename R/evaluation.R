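# Benchmarking protocol: per-class one-vs-rest PR/ROC curves and AUCs,
# complement scores for binary comparators, multi-class macro F1 and
# accuracy, and confusion matrices (raw and row-normalized). ROC AUC uses
# the trapezoid rule (equal to Mann-Whitney pair counting with ties at
# half weight); PR AUC uses the step-wise estimator with precision held
# right-continuous, avoiding optimistic linear interpolation. Tied scores
# are grouped into single threshold steps.

#' Class vocabulary of the three-class problem
#' @return `c("benign", "VUS", "pathogenic")`.
#' @export
significance_classes <- function() c("benign", "VUS", "pathogenic")

#' One-vs-rest PR and ROC curves with AUCs
#'
#' Sorts CNVs by their class score and sweeps all distinct thresholds
#' (tied scores grouped), producing ROC and precision-recall curves and
#' their areas.
#'
#' @param scores numeric score for the positive class, higher = more
#'   confident.
#' @param truth true labels.
#' @param positive_class label treated as positive; all others negative.
#' @return list of class `ovr_curves`: `roc` (fpr/tpr), `pr`
#'   (recall/precision), `roc_auc`, `pr_auc`, `n_pos`, `n_neg`.
#' @export
one_vs_rest_curves <- function(scores, truth, positive_class) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive_class
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0)
    stop("need at least one positive and one negative example for class ",
         positive_class)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  roc <- data.frame(threshold = s[grp_end], fpr = fp / N, tpr = tp / P)
  roc0 <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  roc_auc <- sum(diff(roc0$fpr) * (utils::head(roc0$tpr, -1) +
                                     utils::tail(roc0$tpr, -1)) / 2)
  pr <- data.frame(threshold = s[grp_end], recall = tp / P,
                   precision = tp / (tp + fp))
  rec0 <- c(0, pr$recall)
  pr_auc <- sum(diff(rec0) * pr$precision)
  out <- list(roc = roc, pr = pr, roc_auc = roc_auc, pr_auc = pr_auc,
              n_pos = P, n_neg = N, positive_class = positive_class)
  class(out) <- "ovr_curves"
  out
}

#' @export
print.ovr_curves <- function(x, ...) {
  cat(sprintf("one-vs-rest curves for '%s': ROC AUC %.4f, PR AUC %.4f (%d+/%d-)\n",
              x$positive_class, x$roc_auc, x$pr_auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Complement scores for binary comparators
#'
#' Comparator tools emitting only a pathogenic probability get a benign
#' score as its complement, `1 - Pr(pathogenic)`.
#'
#' @param pathogenic_scores numeric vector.
#' @return `1 - pathogenic_scores`, order preserved.
#' @export
complement_scores <- function(pathogenic_scores) 1 - pathogenic_scores

#' Harmonize five-level predictions to three classes
#'
#' Likely-pathogenic maps to pathogenic and likely-benign to benign so
#' five-level tools compare fairly with three-class output; benign, VUS
#' and pathogenic pass through.
#'
#' @param labels character vector over benign / likely benign / VUS /
#'   likely pathogenic / pathogenic (case-insensitive; "LB"/"LP"/"B"/"P"
#'   abbreviations accepted).
#' @return character vector over the three-class vocabulary.
#' @export
harmonize_labels <- function(labels) {
  l <- tolower(trimws(as.character(labels)))
  map <- c("benign" = "benign", "b" = "benign",
           "likely benign" = "benign", "likely_benign" = "benign",
           "lb" = "benign",
           "vus" = "VUS", "uncertain significance" = "VUS",
           "uncertain_significance" = "VUS",
           "likely pathogenic" = "pathogenic",
           "likely_pathogenic" = "pathogenic", "lp" = "pathogenic",
           "pathogenic" = "pathogenic", "p" = "pathogenic")
  unknown <- setdiff(unique(l), names(map))
  if (length(unknown))
    stop("unknown significance label(s): ", paste(unknown, collapse = ", "))
  unname(map[l])
}

#' Multi-class performance summary
#'
#' Per-class one-vs-rest F1, their unweighted (macro) mean, overall
#' accuracy, and the confusion matrix raw and normalized by the totals of
#' the actual labels (rows).
#'
#' @param predicted,truth label vectors over the three-class vocabulary.
#' @param classes class order for the confusion matrix.
#' @return list of class `multiclass_summary`.
#' @export
multiclass_summary <- function(predicted, truth,
                               classes = significance_classes()) {
  if (!length(truth)) stop("empty input")
  predicted <- factor(predicted, levels = classes)
  truth <- factor(truth, levels = classes)
  if (anyNA(predicted) || anyNA(truth))
    stop("labels outside the class vocabulary")
  cm <- table(truth = truth, predicted = predicted)
  f1 <- vapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  rs <- rowSums(cm)
  norm <- sweep(cm, 1, ifelse(rs == 0, 1, rs), "/")
  out <- list(confusion = cm, confusion_normalized = norm,
              per_class_f1 = f1, macro_f1 = mean(f1),
              accuracy = sum(diag(cm)) / sum(cm), n = length(truth))
  class(out) <- "multiclass_summary"
  out
}

#' @export
print.multiclass_summary <- function(x, ...) {
  cat(sprintf("multiclass_summary (n = %d): accuracy %.4f, macro F1 %.4f\n",
              x$n, x$accuracy, x$macro_f1))
  cat("  per-class F1:",
      paste(sprintf("%s=%.4f", names(x$per_class_f1), x$per_class_f1),
            collapse = "  "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Benchmark a set of tools against shared truth labels
#'
#' For each tool, computes class-wise curves/AUCs from whatever scores it
#' provides: three-class probability tools get all three one-vs-rest
#' curves; single-score tools get pathogenic curves plus benign curves on
#' the complement score; label-only tools are excluded from curve metrics.
#' Tools providing labels additionally get the multi-class summary (after
#' harmonizing five-level labels).
#'
#' @param truth character vector of true three-class labels.
#' @param tools named list; each element a list with optional components
#'   `probs` (data frame with columns benign/VUS/pathogenic),
#'   `pathogenic_score` (numeric) and `labels` (character).
#' @return named list of per-tool reports (class `evaluation_report`).
#' @export
benchmark_tools <- function(truth, tools) {
  lapply(tools, function(tool) {
    rep <- list(curves = list(), summary = NULL)
    if (!is.null(tool$probs)) {
      for (cl in significance_classes())
        rep$curves[[cl]] <- one_vs_rest_curves(tool$probs[[cl]], truth, cl)
    } else if (!is.null(tool$pathogenic_score)) {
      rep$curves$pathogenic <-
        one_vs_rest_curves(tool$pathogenic_score, truth, "pathogenic")
      rep$curves$benign <-
        one_vs_rest_curves(complement_scores(tool$pathogenic_score),
                           truth, "benign")
    }
    if (!is.null(tool$labels))
      rep$summary <- multiclass_summary(harmonize_labels(tool$labels), truth)
    class(rep) <- "evaluation_report"
    rep
  })
}
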