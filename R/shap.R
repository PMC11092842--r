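# Shapley-value feature attributions. Two routes:
#   * exact, polynomial-time TreeSHAP over a generic tree-ensemble
#     representation (path-dependent weighting by node covers), used for
#     tree estimators (the random-forest architecture, hand-built
#     ensembles);
#   * seeded permutation sampling with antithetic pairs for any other
#     estimator, exact in the local-accuracy sense relative to a fixed
#     background set.
# Attributions are computed on the pre-calibration estimator output for
# each class; base value is the cover-weighted (tree route) or
# background-mean (permutation route) expected output.

#' Build a tree ensemble for exact Shapley attribution
#'
#' A tree is a list of parallel node vectors (node 1 is the root):
#' `feature` (1-based column index, `NA` at leaves), `threshold`
#' (`x[feature] <= threshold` goes left), `left`, `right` (child indices),
#' `cover` (training weight reaching the node) and `value` (leaf output,
#' `NA` internally). The ensemble output is the mean of its trees.
#'
#' @param trees list of trees as described.
#' @param n_features number of feature columns.
#' @param feature_names optional column names.
#' @return object of class `tree_ensemble`.
#' @export
tree_ensemble <- function(trees, n_features, feature_names = NULL) {
  for (tr in trees) {
    stopifnot(all(c("feature", "threshold", "left", "right", "cover",
                    "value") %in% names(tr)))
    if (any(tr$feature > n_features, na.rm = TRUE))
      stop("tree references a feature beyond n_features")
  }
  obj <- list(trees = trees, n_features = n_features,
              feature_names = feature_names)
  class(obj) <- "tree_ensemble"
  obj
}

# Output of one tree for one observation.
.tree_predict_row <- function(tr, x) {
  j <- 1L
  while (!is.na(tr$feature[j]))
    j <- if (x[tr$feature[j]] <= tr$threshold[j]) tr$left[j] else tr$right[j]
  tr$value[j]
}

#' Predict with a `tree_ensemble`
#'
#' @param object a `tree_ensemble`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return numeric vector: mean tree output per row.
#' @export
predict.tree_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  vapply(seq_len(nrow(newdata)), function(i)
    mean(vapply(object$trees, .tree_predict_row, 0, x = newdata[i, ])), 0)
}

# Cover-weighted expected output of one tree (empty coalition value).
.tree_base <- function(tr) {
  leaves <- which(is.na(tr$feature))
  sum(tr$value[leaves] * tr$cover[leaves]) / tr$cover[1]
}

# Exact TreeSHAP for a single tree and observation (Lundberg's
# polynomial-time path algorithm). Path rows track the feature entering
# the path (d), its zero/one fractions (z, o) and the permutation weight
# (w); row 1 is the root placeholder.
.treeshap_one <- function(tr, x, M) {
  phi <- numeric(M)

  extend <- function(m, pz, po, pi) {
    l <- if (is.null(m)) 0L else nrow(m)
    m <- rbind(m, c(d = pi, z = pz, o = po, w = if (l == 0) 1 else 0))
    if (l > 0) for (i in l:1) {
      m[i + 1, "w"] <- m[i + 1, "w"] + po * m[i, "w"] * i / (l + 1)
      m[i, "w"] <- pz * m[i, "w"] * (l + 1 - i) / (l + 1)
    }
    m
  }
  unwind <- function(m, i) {
    l <- nrow(m)
    n <- m[l, "w"]
    oi <- m[i, "o"]; zi <- m[i, "z"]
    if (l >= 2) for (j in (l - 1):1) {
      if (oi != 0) {
        t <- m[j, "w"]
        m[j, "w"] <- n * l / (j * oi)
        n <- t - m[j, "w"] * zi * (l - j) / l
      } else {
        m[j, "w"] <- m[j, "w"] * l / (zi * (l - j))
      }
    }
    if (i < l) m[i:(l - 1), c("d", "z", "o")] <- m[(i + 1):l, c("d", "z", "o")]
    m[-l, , drop = FALSE]
  }

  recurse <- function(j, m, pz, po, pi) {
    m <- extend(m, pz, po, pi)
    if (is.na(tr$feature[j])) {
      l <- nrow(m)
      if (l >= 2) for (i in 2:l) {
        w <- sum(unwind(m, i)[, "w"])
        phi[m[i, "d"]] <<- phi[m[i, "d"]] +
          w * (m[i, "o"] - m[i, "z"]) * tr$value[j]
      }
    } else {
      d <- tr$feature[j]
      hot <- if (x[d] <= tr$threshold[j]) tr$left[j] else tr$right[j]
      cold <- if (hot == tr$left[j]) tr$right[j] else tr$left[j]
      iz <- 1; io <- 1
      if (nrow(m) >= 2) {
        k <- which(m[2:nrow(m), "d"] == d)
        if (length(k)) {
          k <- k[1] + 1L
          iz <- m[k, "z"]; io <- m[k, "o"]
          m <- unwind(m, k)
        }
      }
      recurse(hot, m, iz * tr$cover[hot] / tr$cover[j], io, d)
      recurse(cold, m, iz * tr$cover[cold] / tr$cover[j], 0, d)
    }
  }
  recurse(1L, NULL, 1, 1, 0L)
  phi
}

#' Exact Shapley values for a tree ensemble
#'
#' Path-dependent TreeSHAP: attributions satisfy local accuracy exactly,
#' `base + sum(phi) == predict(ensemble, x)` for every row.
#'
#' @param ensemble a [tree_ensemble()].
#' @param x numeric matrix of observations.
#' @return list with `phi` (matrix `nrow(x)` x `n_features`) and `base`
#'   (scalar expected output).
#' @export
tree_shap <- function(ensemble, x) {
  x <- as.matrix(x)
  M <- ensemble$n_features
  phi <- matrix(0, nrow(x), M)
  for (tr in ensemble$trees) {
    # the root placeholder row has d = 0; guard phi index by dropping it
    for (i in seq_len(nrow(x))) {
      p <- .treeshap_one(tr, x[i, ], M + 1L)  # slot M+1 absorbs d = 0 writes
      phi[i, ] <- phi[i, ] + p[seq_len(M)]
    }
  }
  phi <- phi / length(ensemble$trees)
  base <- mean(vapply(ensemble$trees, .tree_base, 0))
  colnames(phi) <- ensemble$feature_names
  list(phi = phi, base = base)
}

# --- ranger adapter -------------------------------------------------------

# Convert a fitted ranger probability forest into one tree_ensemble per
# class. Covers are reconstructed by routing the training rows through the
# recorded splits (values <= splitval go left).
ranger_tree_ensembles <- function(rf, x_train, classes) {
  x_train <- as.matrix(x_train)
  per_class <- lapply(classes, function(cl) list())
  names(per_class) <- classes
  for (t in seq_len(rf$num.trees)) {
    ti <- ranger::treeInfo(rf, t)
    nn <- nrow(ti)
    feature <- ifelse(ti$terminal, NA_integer_, ti$splitvarID + 1L)
    threshold <- ti$splitval
    left <- ti$leftChild + 1L
    right <- ti$rightChild + 1L
    cover <- numeric(nn)
    assign_cover <- function(j, idx) {
      cover[j] <<- length(idx)
      if (!is.na(feature[j])) {
        go_left <- x_train[idx, feature[j]] <= threshold[j]
        assign_cover(left[j], idx[go_left])
        assign_cover(right[j], idx[!go_left])
      }
    }
    assign_cover(1L, seq_len(nrow(x_train)))
    if (any(cover == 0 & is.na(feature)))
      cover[cover == 0] <- 1e-9   # unreachable leaf under this training set
    for (cl in classes) {
      col <- paste0("pred.", cl)
      value <- if (col %in% colnames(ti)) ti[[col]] else ti$prediction
      per_class[[cl]][[t]] <- list(feature = feature, threshold = threshold,
                                   left = left, right = right,
                                   cover = cover, value = value)
    }
  }
  lapply(per_class, tree_ensemble, n_features = ncol(x_train),
         feature_names = colnames(x_train))
}

# --- permutation sampling -------------------------------------------------

# Seeded permutation Shapley with antithetic pairs. f maps a matrix to a
# numeric vector. Local accuracy is exact relative to the background
# sequence: base + sum(phi_i) == f(x).
permutation_shap <- function(f, X, background, n_perm = 256, seed = 1) {
  X <- as.matrix(X); background <- as.matrix(background)
  M <- ncol(X)
  set.seed(seed)
  half <- max(1, floor(n_perm / 2))
  perms <- vector("list", 2 * half)
  for (i in seq_len(half)) {
    p <- sample.int(M)
    perms[[2 * i - 1]] <- p
    perms[[2 * i]] <- rev(p)
  }
  bg_idx <- rep_len(seq_len(nrow(background)), length(perms))
  base <- mean(f(background[bg_idx, , drop = FALSE]))
  phi <- matrix(0, nrow(X), M, dimnames = list(NULL, colnames(X)))
  for (r in seq_len(nrow(X))) {
    x <- X[r, ]
    # rows: for each perm, the background row morphing into x one
    # feature at a time (M+1 states)
    states <- matrix(0, length(perms) * (M + 1), M)
    k <- 0L
    for (pi in seq_along(perms)) {
      z <- background[bg_idx[pi], ]
      states[k + 1L, ] <- z
      for (step in seq_len(M)) {
        z[perms[[pi]][step]] <- x[perms[[pi]][step]]
        states[k + 1L + step, ] <- z
      }
      k <- k + M + 1L
    }
    colnames(states) <- colnames(X)
    fv <- f(states)
    k <- 0L
    for (pi in seq_along(perms)) {
      d <- diff(fv[(k + 1L):(k + M + 1L)])
      phi[r, perms[[pi]]] <- phi[r, perms[[pi]]] + d
      k <- k + M + 1L
    }
  }
  list(phi = phi / length(perms), base = base)
}

#' Per-class Shapley attributions for a fitted classifier
#'
#' Computes, for every class, a matrix of per-feature Shapley values plus
#' the class base value (expected estimator output). Attribution targets
#' the pre-calibration estimator on the transformed feature scale. The
#' exact tree route is used for the random-forest architecture (and any
#' `tree_ensemble`); other estimators use seeded permutation sampling.
#'
#' @param model a `cnv_classifier` (or a named list of `tree_ensemble`s,
#'   one per class).
#' @param X feature data frame or matrix; raw features are transformed
#'   with the model's fitted transformer.
#' @param method `"auto"`, `"tree"` (exact; errors for non-tree
#'   estimators) or `"permutation"`.
#' @param seed RNG seed for the permutation route.
#' @param n_perm permutations per observation (antithetic pairs).
#' @param background background rows for the permutation route (default:
#'   `X` itself, capped at 25 rows).
#' @return an object of class `attribution_matrix`: list with `phi`
#'   (per-class matrices), `base` (per-class), `classes`,
#'   `feature_names`, `X` (the attributed matrix), `ids`.
#' @export
attribute <- function(model, X, method = c("auto", "tree", "permutation"),
                      seed = 1, n_perm = 256, background = NULL) {
  method <- match.arg(method)
  ids <- if (is.data.frame(X) && "id" %in% colnames(X)) X$id else NULL

  if (inherits(model, "cnv_classifier")) {
    Xt <- if (!is.null(model$transformer))
      as.matrix(apply_transformer(model$transformer, X))
    else as.matrix(.feature_numeric(X))
    classes <- model$class_levels
    is_tree <- model$architecture == "rf"
    if (method == "tree" && !is_tree)
      stop("exact tree attribution needs a tree-ensemble estimator (got '",
           model$architecture, "'); use method = 'permutation'")
    use_tree <- is_tree && method != "permutation"
    if (use_tree) {
      cover_x <- if (!is.null(model$train_x)) model$train_x else Xt
      ens <- ranger_tree_ensembles(model$fit, cover_x, classes)
      res <- lapply(ens, tree_shap, x = Xt)
    } else {
      if (is.null(background))
        background <- Xt[seq_len(min(25, nrow(Xt))), , drop = FALSE]
      res <- lapply(stats::setNames(classes, classes), function(cl) {
        f <- function(m) model$arch_adapter$prob(model$fit, m, classes)[, cl]
        permutation_shap(f, Xt, background, n_perm = n_perm, seed = seed)
      })
    }
  } else if (is.list(model) && all(vapply(model, inherits, TRUE,
                                          "tree_ensemble"))) {
    Xt <- as.matrix(X)
    classes <- names(model)
    res <- lapply(model, tree_shap, x = Xt)
  } else stop("model must be a cnv_classifier or a list of tree_ensembles")

  out <- list(
    phi = lapply(res, function(r) {
      colnames(r$phi) <- colnames(Xt); r$phi
    }),
    base = vapply(res, function(r) r$base, 0),
    classes = classes, feature_names = colnames(Xt), X = Xt, ids = ids)
  class(out) <- "attribution_matrix"
  out
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("attribution_matrix: %d observations x %d features, classes: %s\n",
              nrow(x$X), length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  cat("  base values:", paste(sprintf("%s=%.4f", x$classes, x$base),
                              collapse = "  "), "\n")
  invisible(x)
}
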