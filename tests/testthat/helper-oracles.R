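# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they
# verify: naive all-pairs interval scans, a literal moving-average
# smoother, Mann-Whitney pair counting, and exhaustive-subset Shapley
# values on explicit trees.

# naive all-pairs overlap scan (oracle for the overlap index)
naive_overlap_scan <- function(intervals, probe) {
  hits <- which(
    intervals$chrom == probe$chrom &
      pmin(intervals$end, probe$end) - pmax(intervals$start, probe$start) >= 1)
  out <- intervals[hits, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

# literal centered moving-average smoother over a dense score vector;
# scores is a data frame (pos, score) of single-base values
naive_smoothed_max <- function(scores, start, end, window) {
  h <- (window - 1) / 2
  best <- -Inf
  for (p in start:(end - 1)) {
    inwin <- scores$score[scores$pos >= p - h & scores$pos <= p + h]
    if (length(inwin)) best <- max(best, mean(inwin))
  }
  if (is.finite(best)) best else NA_real_
}

# Mann-Whitney pair counting (oracle for trapezoid ROC AUC)
mw_auc <- function(scores, truth, positive_class) {
  pos <- scores[truth == positive_class]
  neg <- scores[truth != positive_class]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# conditional expectation of a tree output given feature subset S, using
# cover-weighted averaging at splits outside S
tree_expvalue <- function(tr, x, S) {
  rec <- function(j) {
    if (is.na(tr$feature[j])) return(tr$value[j])
    f <- tr$feature[j]
    if (f %in% S) {
      if (x[f] <= tr$threshold[j]) rec(tr$left[j]) else rec(tr$right[j])
    } else {
      (tr$cover[tr$left[j]] * rec(tr$left[j]) +
         tr$cover[tr$right[j]] * rec(tr$right[j])) / tr$cover[j]
    }
  }
  rec(1L)
}

# exhaustive-subset Shapley values for one tree (exponential; tiny M only)
brute_force_shap <- function(tr, x, M) {
  phi <- numeric(M)
  for (i in seq_len(M)) {
    others <- setdiff(seq_len(M), i)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(integer()) else
        utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(M - k - 1) / factorial(M)
      for (S in subsets)
        phi[i] <- phi[i] +
          w * (tree_expvalue(tr, x, c(S, i)) - tree_expvalue(tr, x, S))
    }
  }
  phi
}

# random binary tree with cover fractions, in the package's node-vector
# layout (built directly, not via any package constructor)
random_test_tree <- function(M, depth) {
  nodes <- list(feature = integer(), threshold = numeric(),
                left = integer(), right = integer(), cover = numeric(),
                value = numeric())
  grow <- function(d, cover) {
    id <- length(nodes$feature) + 1L
    nodes$feature[id] <<- NA; nodes$threshold[id] <<- NA
    nodes$left[id] <<- NA; nodes$right[id] <<- NA
    nodes$cover[id] <<- cover; nodes$value[id] <<- NA
    if (d < depth && stats::runif(1) < 0.8) {
      nodes$feature[id] <<- sample(M, 1)
      nodes$threshold[id] <<- stats::runif(1)
      frac <- stats::runif(1, 0.2, 0.8)
      l <- grow(d + 1, cover * frac)
      r <- grow(d + 1, cover * (1 - frac))
      nodes$left[id] <<- l; nodes$right[id] <<- r
    } else nodes$value[id] <<- stats::rnorm(1)
    id
  }
  grow(0, 100)
  nodes
}
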