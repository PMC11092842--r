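test_that("exact tree attributions match exhaustive-subset Shapley values", {
  set.seed(42)
  for (rep in 1:20) {
    M <- sample(2:5, 1)
    tr <- random_test_tree(M, sample(2:4, 1))
    ens <- tree_ensemble(list(tr), M)
    x <- matrix(runif(2 * M), 2, M)
    res <- tree_shap(ens, x)
    for (i in 1:2) {
      expect_equal(res$phi[i, ], brute_force_shap(tr, x[i, ], M),
                   tolerance = 1e-10)
      expect_equal(res$base + sum(res$phi[i, ]),
                   predict(ens, x)[i], tolerance = 1e-10)
    }
  }
})

test_that("a constant model attributes nothing to any feature", {
  leaf <- list(feature = NA_integer_, threshold = NA_real_,
               left = NA_integer_, right = NA_integer_, cover = 100,
               value = 0.7)
  ens <- tree_ensemble(list(leaf, leaf), 4)
  res <- tree_shap(ens, matrix(runif(12), 3, 4))
  expect_true(all(res$phi == 0))
  expect_equal(res$base, 0.7)
})

test_that("identically-used duplicated features share attribution equally", {
  # mirrored ensemble: one tree thresholds feature 1, its twin thresholds
  # feature 2 with identical structure and covers, so the ensemble is
  # symmetric in the two features
  stump <- function(f) list(feature = c(f, NA, NA),
                            threshold = c(0.5, NA, NA),
                            left = c(2L, NA, NA), right = c(3L, NA, NA),
                            cover = c(100, 60, 40), value = c(NA, 0, 1))
  ens <- tree_ensemble(list(stump(1L), stump(2L)), 3)
  x <- rbind(c(0.8, 0.8, 0.1), c(0.2, 0.2, 0.9))
  res <- tree_shap(ens, x)
  expect_equal(res$phi[, 1], res$phi[, 2], tolerance = 1e-12)
  expect_equal(res$phi[, 3], c(0, 0))   # never used: null player
})

test_that("attributions are confined to the features a model uses", {
  stump <- list(feature = c(2L, NA, NA), threshold = c(0.3, NA, NA),
                left = c(2L, NA, NA), right = c(3L, NA, NA),
                cover = c(10, 5, 5), value = c(NA, -1, 1))
  res <- tree_shap(tree_ensemble(list(stump), 5), matrix(runif(20), 4, 5))
  expect_true(all(res$phi[, -2] == 0))
  expect_true(all(res$phi[, 2] != 0))
})

test_that("the ranger adapter reproduces forest probabilities exactly", {
  m <- fx_model()
  Xt <- as.matrix(apply_transformer(m$transformer, fx_features()[1:40, ]))
  ens <- cnvclass:::ranger_tree_ensembles(m$fit, Xt, m$class_levels)
  pr <- predict(m$fit, data = Xt, num.threads = 1)$predictions
  for (cl in m$class_levels)
    expect_equal(predict(ens[[cl]], Xt), unname(pr[, cl]), tolerance = 1e-12)
})

test_that("attribute() satisfies local accuracy on fixture predictions", {
  m <- fx_model()
  cnvs <- fx_cnvs()
  del <- which(cnvs$type == "DEL")[1:12]
  feats <- fx_features()[del, ]
  att <- attribute(m, feats)
  raw <- predict(m, feats, calibrated = FALSE)
  raw_cols <- c(benign = "pr_benign", VUS = "pr_vus",
                pathogenic = "pr_pathogenic")
  for (cl in m$class_levels)
    expect_equal(att$base[[cl]] + rowSums(att$phi[[cl]]),
                 raw[[raw_cols[[cl]]]], tolerance = 1e-6)
  # ranking is invariant to feature column order
  perm <- sample(ncol(att$phi$pathogenic))
  feats_perm <- feats[, c("id", colnames(att$phi$pathogenic)[perm])]
  att2 <- attribute(m, feats_perm)
  r1 <- sort(colMeans(abs(att$phi$pathogenic)), decreasing = TRUE)
  r2 <- sort(colMeans(abs(att2$phi$pathogenic)), decreasing = TRUE)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("permutation sampling is exact in the local-accuracy sense", {
  d <- data.frame(a = runif(30), b = runif(30), c = runif(30))
  f <- function(m) as.matrix(m) %*% c(2, -1, 0) + 0.5
  res <- cnvclass:::permutation_shap(function(m) as.numeric(f(m)),
                                     as.matrix(d[1:5, ]), as.matrix(d),
                                     n_perm = 8, seed = 2)
  expect_equal(res$base + rowSums(res$phi), as.numeric(f(d[1:5, ])),
               tolerance = 1e-10)
  expect_equal(unname(res$phi[, "c"]), rep(0, 5))  # unused feature
  # seeded: identical across runs
  res2 <- cnvclass:::permutation_shap(function(m) as.numeric(f(m)),
                                      as.matrix(d[1:5, ]), as.matrix(d),
                                      n_perm = 8, seed = 2)
  expect_identical(res, res2)
})

test_that("tree-exact attribution refuses non-tree estimators", {
  d <- .toy_xy(120, seed = 51)
  m <- cnv_classifier(as.data.frame(d$x), d$y, "DEL",
                      roster = default_roster("multinom"), folds = 3,
                      n_draws = 2, seed = 3)
  expect_error(attribute(m, as.data.frame(d$x), method = "tree"),
               "permutation")
})

test_that("exports write ranked TSV twins deterministically", {
  m <- fx_model()
  feats <- fx_features()[fx_cnvs()$type == "DEL", ][1:10, ]
  att <- attribute(m, feats)
  dir <- withr::local_tempdir()
  bee <- file.path(dir, "bee.png")
  out <- export_beeswarm(att, "pathogenic", bee)
  expect_true(file.exists(out$image))
  tsv <- read.delim(out$tsv)
  expect_equal(nrow(tsv), nrow(feats) * length(att$feature_names))
  imp <- colMeans(abs(att$phi$pathogenic))
  expect_equal(tsv$feature[1], names(which.max(imp)))
  expect_equal(sort(unique(tsv$rank)), seq_along(att$feature_names))
  # byte-identical re-export
  h1 <- tools::md5sum(out$tsv)
  export_beeswarm(att, "pathogenic", file.path(dir, "bee2.png"),
                  tsv_path = file.path(dir, "bee2.tsv"))
  expect_identical(unname(h1),
                   unname(tools::md5sum(file.path(dir, "bee2.tsv"))))

  force <- export_force(att, feats$id[1], "pathogenic",
                        file.path(dir, "force.png"))
  ftsv <- read.delim(force$tsv)
  expect_equal(nrow(ftsv), length(att$feature_names))
  expect_equal(ftsv$output[1],
               att$base[["pathogenic"]] + sum(att$phi$pathogenic[1, ]),
               tolerance = 1e-6)
  expect_error(export_force(att, "no_such_cnv", "pathogenic",
                            file.path(dir, "f2.png")), "unknown cnv_id")
})
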