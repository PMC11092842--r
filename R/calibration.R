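# Isotonic probability calibration, one-vs-rest. Out-of-fold raw class
# probabilities are regressed isotonically against the class indicator
# (weighted pool-adjacent-violators on tie-aggregated scores; linear
# interpolation between knots, clamped at the ends), then the three
# calibrated scores are renormalized onto the probability simplex.

# Weighted PAVA on (x, y, w) with x sorted strictly increasing.
# stats::isoreg is unweighted, so tie groups are pre-aggregated to
# weighted means and pooled here.
.pava <- function(y, w) {
  n <- length(y)
  ghat <- y; wght <- w; idx <- rep(1:n, 1)
  # blocks as vectors; classic stack-based PAVA
  vals <- numeric(0); wts <- numeric(0); sizes <- integer(0)
  for (i in seq_len(n)) {
    vals <- c(vals, y[i]); wts <- c(wts, w[i]); sizes <- c(sizes, 1L)
    while (length(vals) > 1 &&
           vals[length(vals) - 1] > vals[length(vals)]) {
      k <- length(vals)
      neww <- wts[k - 1] + wts[k]
      vals[k - 1] <- (vals[k - 1] * wts[k - 1] + vals[k] * wts[k]) / neww
      wts[k - 1] <- neww
      sizes[k - 1] <- sizes[k - 1] + sizes[k]
      vals <- vals[-k]; wts <- wts[-k]; sizes <- sizes[-k]
    }
  }
  rep(vals, sizes)
}

#' Fit an isotonic calibration map
#'
#' @param score raw classifier scores.
#' @param outcome 0/1 indicator of the positive class.
#' @return an object of class `isotonic_map`; apply with
#'   [apply_isotonic()]. The map is non-decreasing by construction.
#' @export
fit_isotonic <- function(score, outcome) {
  stopifnot(length(score) == length(outcome))
  ord <- order(score)
  s <- score[ord]; y <- as.numeric(outcome)[ord]
  ux <- unique(s)
  grp <- match(s, ux)
  wy <- tapply(y, grp, mean)
  ww <- tapply(y, grp, length)
  fit <- .pava(as.numeric(wy), as.numeric(ww))
  obj <- list(x = ux, y = fit)
  class(obj) <- "isotonic_map"
  obj
}

#' Apply an isotonic calibration map
#'
#' Linear interpolation between fitted knots; scores beyond the training
#' range are clamped to the boundary values.
#'
#' @param map an `isotonic_map`.
#' @param score numeric vector.
#' @return calibrated scores in \[0, 1\].
#' @export
apply_isotonic <- function(map, score) {
  if (length(map$x) == 1) return(rep(map$y, length(score)))
  stats::approx(map$x, map$y, xout = score, method = "linear",
                rule = 2, ties = "ordered")$y
}

# One calibrator per class, fitted on out-of-fold probabilities.
fit_calibrators <- function(oof_probs, y, classes) {
  lapply(stats::setNames(classes, classes), function(cl)
    fit_isotonic(oof_probs[, cl], as.numeric(y == cl)))
}

# Calibrate a raw probability matrix and renormalize to the simplex.
apply_calibrators <- function(calibrators, raw_probs) {
  q <- vapply(names(calibrators), function(cl)
    apply_isotonic(calibrators[[cl]], raw_probs[, cl]),
    numeric(nrow(raw_probs)))
  q <- matrix(q, nrow = nrow(raw_probs),
              dimnames = list(NULL, names(calibrators)))
  rs <- rowSums(q)
  zero <- rs <= 0
  if (any(zero)) {
    q[zero, ] <- 1 / ncol(q)
    rs[zero] <- 1
  }
  q / rs
}
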