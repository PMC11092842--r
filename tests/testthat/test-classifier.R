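test_that("stratified folds carry every class and reject tiny classes", {
  y <- factor(rep(significance_classes(), c(20, 15, 10)))
  folds <- stratified_folds(y, 5, seed = 3)
  for (f in 1:5)
    expect_setequal(as.character(unique(y[folds == f])),
                    significance_classes())
  expect_error(stratified_folds(factor(rep(c("benign", "VUS"), c(3, 20))),
                                5), "smaller k")
})

test_that("architecture selection ranks the adequate learner first", {
  d <- .toy_xy(300, seed = 21)
  ranking <- select_architecture(d$x, d$y,
                                 roster = default_roster(c("multinom", "rf")),
                                 k = 5, seed = 9)
  expect_equal(ranking$architecture[1], "rf")   # nonlinear rule
  expect_gt(ranking$mean_macro_f1[1], ranking$mean_macro_f1[2])
  # determinism and the single-entry roster
  again <- select_architecture(d$x, d$y,
                               roster = default_roster(c("multinom", "rf")),
                               k = 5, seed = 9)
  expect_identical(ranking, again)
  solo <- select_architecture(d$x, d$y, roster = default_roster("cart"),
                              k = 5, seed = 9)
  expect_equal(solo$architecture, "cart")
  expect_error(select_architecture(d$x, d$y, roster = list()), "non-empty")
})

test_that("randomized search returns the winning draw deterministically", {
  d <- .toy_xy(250, seed = 22)
  arch <- default_roster("cart")$cart
  one <- tune_hyperparameters(d$x, d$y, arch, n_draws = 1, k = 3, seed = 4)
  set.seed(4)
  expect_identical(one$params, sample_hyperparameters(arch$space))
  t1 <- tune_hyperparameters(d$x, d$y, arch, n_draws = 8, k = 3, seed = 4)
  t2 <- tune_hyperparameters(d$x, d$y, arch, n_draws = 8, k = 3, seed = 4)
  expect_identical(t1$params, t2$params)
  expect_equal(t1$score, max(t1$draws$macro_f1))
  # a depth-1 stump cannot express the two-feature rule; an adequate
  # depth must win when both are on offer
  arch2 <- arch
  arch2$space <- list(maxdepth = list(type = "choice", values = list(1L, 10L)),
                      cp = list(type = "choice", values = list(0.001)),
                      minsplit = list(type = "choice", values = list(10L)))
  best <- tune_hyperparameters(d$x, d$y, arch2, n_draws = 10, k = 3, seed = 4)
  expect_equal(best$params$maxdepth, 10L)
  # empty space falls back to defaults with a note
  arch3 <- arch; arch3$space <- list()
  res <- tune_hyperparameters(d$x, d$y, arch3, n_draws = 5, k = 3, seed = 1)
  expect_identical(res$params, arch$defaults)
  expect_match(res$note, "defaults")
})

test_that("calibrated probabilities live on the simplex and maps are monotone", {
  d <- .toy_xy(240, seed = 23)
  arch <- default_roster("rf")$rf
  cal <- calibrate_and_fit(d$x, d$y, arch, arch$defaults, k = 4, seed = 2)
  probs <- apply_calibrators(cal$calibrators, cal$oof_probs)
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
  for (cl in significance_classes()) {
    map <- cal$calibrators[[cl]]
    expect_true(all(diff(map$y) >= -1e-12))  # isotonic by construction
    grid <- apply_isotonic(map, seq(0, 1, 0.01))
    expect_true(all(diff(grid) >= -1e-12))
  }
})

test_that("isotonic calibration does not worsen calibration error", {
  # one informative feature with known posteriors
  # (x^2, 2x(1-x), (1-x)^2); naive Bayes with a duplicated feature is
  # overconfident, so there is calibration error to remove
  gen <- function(n, seed) {
    set.seed(seed)
    x <- runif(n)
    p <- cbind(benign = (1 - x)^2, VUS = 2 * x * (1 - x), pathogenic = x^2)
    y <- apply(p, 1, function(pr) sample(colnames(p), 1, prob = pr))
    list(x = cbind(s1 = x, s2 = x + rnorm(n, 0, 0.01),
                   s3 = x + rnorm(n, 0, 0.01)),
         y = factor(y, levels = significance_classes()))
  }
  train <- gen(1200, 31); test <- gen(1200, 32)
  m <- cnv_classifier(as.data.frame(train$x), train$y, "DEL",
                      roster = default_roster("naive_bayes"),
                      folds = 5, n_draws = 3, seed = 6)
  raw <- predict(m, as.data.frame(test$x), calibrated = FALSE)
  cal <- predict(m, as.data.frame(test$x), calibrated = TRUE)
  mace <- function(p, ind) {
    bins <- cut(p, seq(0, 1, 0.1), include.lowest = TRUE)
    mean(abs(tapply(p, bins, mean) - tapply(ind, bins, mean)), na.rm = TRUE)
  }
  score <- function(preds) {
    cols <- c(benign = "pr_benign", VUS = "pr_vus",
              pathogenic = "pr_pathogenic")
    mean(vapply(significance_classes(), function(cl)
      mace(preds[[cols[[cl]]]], as.numeric(test$y == cl)), 0))
  }
  expect_lte(score(cal), score(raw) + 0.01)
})

test_that("prediction labels use the pathogenic > VUS > benign tie-break", {
  probs <- rbind(c(0.2, 0.3, 0.5), c(1, 1, 1) / 3, c(0.4, 0.4, 0.2),
                 c(0.5, 0.2, 0.3))
  colnames(probs) <- significance_classes()
  expect_equal(cnvclass:::.argmax_label(probs),
               c("pathogenic", "pathogenic", "VUS", "benign"))
})

test_that("prediction enforces CNV-type routing and handles empty input", {
  m <- fx_model()
  cnvs <- fx_cnvs()
  dup <- cnvs[cnvs$type == "DUP", ][1:3, ]
  class(dup) <- c("cnv_set", "data.frame")
  expect_error(predict(m, dup, bundle = fx_bundle()), "type mismatch")
  empty <- predict(m, fx_features()[0, ])
  expect_equal(nrow(empty), 0)
  expect_setequal(colnames(empty),
                  c("id", "pr_benign", "pr_vus", "pr_pathogenic", "label"))
})

test_that("training is deterministic end to end for a fixed seed", {
  d <- .toy_xy(180, seed = 25)
  fit_once <- function() {
    m <- cnv_classifier(as.data.frame(d$x), d$y, "DUP",
                        roster = default_roster(c("cart", "multinom")),
                        folds = 3, n_draws = 4, seed = 17)
    list(arch = m$architecture, hp = m$hyperparameters,
         ranking = m$cv_summary$architecture_ranking,
         preds = predict(m, as.data.frame(d$x)))
  }
  expect_identical(fit_once(), fit_once())
})

test_that("the selected model recovers a noiseless two-feature rule", {
  # labels are a deterministic function of exon count and length
  # surrogates; held-out macro F1 must reach 0.95
  d <- .toy_xy(420, seed = 26)
  h <- .toy_xy(420, seed = 27)
  m <- cnv_classifier(as.data.frame(d$x), d$y, "DEL",
                      roster = default_roster(c("rf", "cart", "multinom")),
                      folds = 5, n_draws = 10, seed = 8)
  s <- multiclass_summary(predict(m, as.data.frame(h$x))$label, h$y)
  expect_gte(s$macro_f1, 0.95)
})
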