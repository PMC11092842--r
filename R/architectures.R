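# Architecture roster: a pluggable set of multi-class learners behind a
# uniform adapter interface. Each entry provides fit(x, y, params, seed),
# prob(model, x) returning an n x 3 matrix with columns in class-level
# order, defaults, and a randomized-search space (shipped in
# inst/config/hyperparameters.yaml). The selection machinery, not the
# roster census, is the contract: callers can pass any roster subset or
# additions.

.hyper_spaces <- function() {
  path <- system.file("config", "hyperparameters.yaml", package = "cnvclass")
  if (!nzchar(path)) path <- file.path("inst", "config", "hyperparameters.yaml")
  yaml::read_yaml(path)
}

#' Draw one hyperparameter set from a space specification
#'
#' Uses the current RNG stream; callers seed it.
#'
#' @param space named list of parameter specs (`type` in int / uniform /
#'   loguniform / choice).
#' @return named list of sampled values; empty space gives an empty list.
#' @export
sample_hyperparameters <- function(space) {
  if (is.null(space) || !length(space)) return(list())
  lapply(space, function(sp) {
    switch(sp$type,
      int = as.integer(floor(stats::runif(1, sp$min, sp$max + 1))),
      uniform = stats::runif(1, sp$min, sp$max),
      loguniform = exp(stats::runif(1, log(sp$min), log(sp$max))),
      choice = sp$values[[sample.int(length(sp$values), 1)]],
      stop("unknown hyperparameter type: ", sp$type))
  })
}

.prob_in_level_order <- function(p, levels) {
  p <- as.matrix(p)
  miss <- setdiff(levels, colnames(p))
  for (m in miss) p <- cbind(p, stats::setNames(data.frame(rep(0, nrow(p))), m))
  p <- as.matrix(p)[, levels, drop = FALSE]
  p[is.na(p)] <- 0
  rs <- rowSums(p)
  p / ifelse(rs == 0, 1, rs)
}

.arch_defs <- function() {
  spaces <- .hyper_spaces()
  defs <- list(
    rf = list(
      defaults = list(num.trees = 300, mtry_frac = 0.4, min.node.size = 5),
      fit = function(x, y, params, seed) {
        mtry <- max(1, round(params$mtry_frac * ncol(x)))
        ranger::ranger(x = x, y = y, probability = TRUE,
                       num.trees = params$num.trees, mtry = mtry,
                       min.node.size = params$min.node.size,
                       seed = seed, num.threads = 1)
      },
      prob = function(model, x, levels)
        .prob_in_level_order(stats::predict(model, data = x,
                                            num.threads = 1)$predictions,
                             levels)),
    gbt = list(
      defaults = list(nrounds = 80, eta = 0.2, max_depth = 4,
                      subsample = 1.0, colsample_bytree = 1.0),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                       label = as.integer(y) - 1L)
        booster <- xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = nlevels(y), eta = params$eta,
                        max_depth = params$max_depth,
                        subsample = params$subsample,
                        colsample_bytree = params$colsample_bytree,
                        nthread = 1),
          data = dtrain, nrounds = params$nrounds, verbose = 0)
        list(booster = booster, levels = levels(y))
      },
      prob = function(model, x, levels) {
        p <- stats::predict(model$booster, xgboost::xgb.DMatrix(as.matrix(x)))
        p <- matrix(p, ncol = length(model$levels), byrow = TRUE,
                    dimnames = list(NULL, model$levels))
        .prob_in_level_order(p, levels)
      }),
    cart = list(
      defaults = list(cp = 0.01, minsplit = 20, maxdepth = 30),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        d <- data.frame(x, check.names = FALSE)
        d$.y <- y
        rpart::rpart(.y ~ ., data = d, method = "class",
                     control = rpart::rpart.control(
                       cp = params$cp, minsplit = params$minsplit,
                       maxdepth = min(30, params$maxdepth), xval = 0))
      },
      prob = function(model, x, levels)
        .prob_in_level_order(stats::predict(
          model, newdata = data.frame(x, check.names = FALSE),
          type = "prob"), levels)),
    multinom = list(
      defaults = list(decay = 0.001),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        d <- data.frame(x, check.names = FALSE)
        d$.y <- y
        nnet::multinom(.y ~ ., data = d, decay = params$decay,
                       maxit = 200, trace = FALSE)
      },
      prob = function(model, x, levels) {
        p <- stats::predict(model, newdata = data.frame(x, check.names = FALSE),
                            type = "probs")
        if (is.null(dim(p))) p <- matrix(p, ncol = length(model$lev),
                                         dimnames = list(NULL, model$lev))
        .prob_in_level_order(p, levels)
      }),
    glmnet = list(
      defaults = list(alpha = 0.5, lambda = 0.001),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        glmnet::glmnet(as.matrix(x), y, family = "multinomial",
                       alpha = params$alpha, lambda = params$lambda)
      },
      prob = function(model, x, levels) {
        p <- stats::predict(model, as.matrix(x), type = "response")
        .prob_in_level_order(p[, , 1], levels)
      }),
    svm_rbf = list(
      defaults = list(cost = 1, gamma = 0.1),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        e1071::svm(as.matrix(x), y, kernel = "radial", cost = params$cost,
                   gamma = params$gamma, probability = TRUE)
      },
      prob = function(model, x, levels) {
        pr <- stats::predict(model, as.matrix(x), probability = TRUE)
        .prob_in_level_order(attr(pr, "probabilities"), levels)
      }),
    naive_bayes = list(
      defaults = list(laplace = 0),
      fit = function(x, y, params, seed) {
        e1071::naiveBayes(as.matrix(x), y, laplace = params$laplace)
      },
      prob = function(model, x, levels)
        .prob_in_level_order(stats::predict(model, as.matrix(x),
                                            type = "raw"), levels)),
    lda = list(
      defaults = list(),
      fit = function(x, y, params, seed) {
        x <- as.matrix(x)
        keep <- apply(x, 2, function(v) stats::sd(v) > 1e-10)
        fit <- MASS::lda(x[, keep, drop = FALSE], grouping = y)
        list(fit = fit, keep = keep)
      },
      prob = function(model, x, levels) {
        x <- as.matrix(x)[, model$keep, drop = FALSE]
        .prob_in_level_order(stats::predict(model$fit, x)$posterior, levels)
      }))
  for (nm in names(defs)) {
    defs[[nm]]$id <- nm
    defs[[nm]]$space <- spaces[[nm]]
  }
  defs
}

#' Default architecture roster
#'
#' Eight common multi-class learners: random forest (`rf`), gradient
#' boosted trees (`gbt`), CART (`cart`), multinomial logistic regression
#' (`multinom`), elastic-net multinomial (`glmnet`), RBF support vector
#' machine (`svm_rbf`), Gaussian naive Bayes (`naive_bayes`) and linear
#' discriminant analysis (`lda`).
#'
#' @param ids which architectures to include, in ranking-tie-break order.
#' @return named list of architecture adapter objects.
#' @export
default_roster <- function(ids = c("rf", "gbt", "cart", "multinom", "glmnet",
                                   "svm_rbf", "naive_bayes", "lda")) {
  defs <- .arch_defs()
  unknown <- setdiff(ids, names(defs))
  if (length(unknown))
    stop("unknown architecture id(s): ", paste(unknown, collapse = ", "))
  defs[ids]
}
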