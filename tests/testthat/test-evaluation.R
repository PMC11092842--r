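test_that("curves hit the forced endpoints and the hand-counted AUC", {
  truth <- c("pathogenic", "pathogenic", "benign", "benign")
  perfect <- one_vs_rest_curves(c(0.9, 0.8, 0.2, 0.1), truth, "pathogenic")
  expect_equal(perfect$roc_auc, 1.0)
  expect_equal(perfect$pr_auc, 1.0)
  inverted <- one_vs_rest_curves(c(0.1, 0.2, 0.8, 0.9), truth, "pathogenic")
  expect_equal(inverted$roc_auc, 0.0)
  # 2+/2-, scores .9(+) .8(-) .7(+) .6(-): 3 of 4 pairs ranked correctly
  mixed <- one_vs_rest_curves(c(0.9, 0.7, 0.8, 0.6), truth, "pathogenic")
  expect_equal(mixed$roc_auc, 0.75)
  expect_error(one_vs_rest_curves(c(0.1, 0.2), c("benign", "benign"),
                                  "pathogenic"), "positive")
})

test_that("trapezoid ROC AUC equals Mann-Whitney pair counting", {
  set.seed(12)
  for (rep in 1:60) {
    n <- sample(10:80, 1)
    truth <- sample(c("pathogenic", "benign"), n, TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(seq(0, 1, by = 0.05), n, TRUE)  # heavy ties
    got <- one_vs_rest_curves(scores, truth, "pathogenic")$roc_auc
    expect_equal(got, mw_auc(scores, truth, "pathogenic"))
    # duplicating the whole record set preserves every pair proportion
    got2 <- one_vs_rest_curves(c(scores, scores), c(truth, truth),
                               "pathogenic")$roc_auc
    expect_equal(got2, got)
  }
})

test_that("complement scores and label harmonization follow the contract", {
  expect_equal(complement_scores(c(0.7, 1.0, 0.25)), c(0.3, 0.0, 0.75))
  expect_equal(harmonize_labels(c("LP", "LB", "VUS", "pathogenic", "B")),
               c("pathogenic", "benign", "VUS", "pathogenic", "benign"))
  expect_equal(harmonize_labels("Likely benign"), "benign")
  expect_error(harmonize_labels("totally new"), "unknown")
})

test_that("multi-class summary reproduces hand arithmetic on a toy matrix", {
  # confusion [[8,2,0],[1,8,1],[0,2,8]] row-wise over (benign, VUS, path)
  classes <- significance_classes()
  truth <- rep(classes, each = 10)
  pred <- c(rep("benign", 8), rep("VUS", 2),
            "benign", rep("VUS", 8), "pathogenic",
            rep("VUS", 2), rep("pathogenic", 8))
  s <- multiclass_summary(pred, truth)
  expect_equal(s$accuracy, 0.8)
  expect_equal(unname(s$per_class_f1["benign"]), 16 / 19, tolerance = 1e-12)
  expect_equal(unname(rowSums(s$confusion)), rep(10, 3))
  expect_equal(unname(rowSums(s$confusion_normalized)), rep(1, 3))
  expect_equal(s$macro_f1, mean(s$per_class_f1))
  # macro F1 invariant to a consistent class relabeling
  perm <- c(benign = "pathogenic", VUS = "benign", pathogenic = "VUS")
  s2 <- multiclass_summary(unname(perm[pred]), unname(perm[truth]))
  expect_equal(s2$macro_f1, s$macro_f1)
  expect_error(multiclass_summary(character(), character()), "empty")
  expect_error(multiclass_summary("nope", "benign"), "vocabulary")
})

test_that("the benchmarking harness routes tool output shapes correctly", {
  set.seed(5)
  n <- 120
  truth <- sample(significance_classes(), n, TRUE)
  p_path <- ifelse(truth == "pathogenic", rbeta(n, 4, 2), rbeta(n, 2, 4))
  probs <- data.frame(benign = ifelse(truth == "benign", 0.6, 0.2),
                      VUS = 0.2, pathogenic = p_path)
  reports <- benchmark_tools(truth, list(
    full = list(probs = probs, labels = truth),
    scorer = list(pathogenic_score = p_path),
    labeler = list(labels = rep("VUS", n))))
  expect_named(reports$full$curves, significance_classes())
  expect_equal(reports$full$summary$accuracy, 1)  # truth fed back as labels
  # single-score tool: pathogenic curve + complement-based benign curve
  expect_named(reports$scorer$curves, c("pathogenic", "benign"))
  expect_equal(reports$scorer$curves$benign$roc_auc,
               one_vs_rest_curves(1 - p_path, truth, "benign")$roc_auc)
  # label-only tool is excluded from curve metrics
  expect_equal(length(reports$labeler$curves), 0)
  expect_false(is.null(reports$labeler$summary))
})
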