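#' The ten-algorithm registry
#'
#' Names of the classical algorithms covered by the comparison grid, spanning
#' single trees, bagged and boosted tree ensembles and linear models. The
#' four gradient-boosting slots are all served by the xgboost library,
#' configured to each method's characteristic growth policy: \code{gbt} uses
#' classic depth-wise boosting (depth 3, learning rate 0.1), \code{xgboost}
#' uses the library defaults (depth 6, learning rate 0.3), \code{lightgbm}
#' uses histogram binning with leaf-wise (loss-guided) growth capped at 31
#' leaves, and \code{catboost} uses shallow symmetric-style trees with a low
#' learning rate and row subsampling. \code{adaboost} is an in-package SAMME
#' implementation boosting depth-1 rpart stumps.
#'
#' @return character vector of the ten algorithm names.
#' @export
org_algorithms <- function() {
  c("decision_tree", "random_forest", "adaboost", "catboost", "gbt",
    "xgboost", "lightgbm", "extra_trees", "logistic_regression", "linear_svm")
}

LINEAR_ALGOS <- c("logistic_regression", "linear_svm")
XGB_ALGOS <- c("catboost", "gbt", "xgboost", "lightgbm")

xgb_slot_params <- function(algorithm) {
  switch(algorithm,
    gbt      = list(max_depth = 3, eta = 0.1, nrounds = 100),
    xgboost  = list(max_depth = 6, eta = 0.3, nrounds = 100),
    lightgbm = list(tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = 31, max_depth = 0, eta = 0.1, nrounds = 100),
    catboost = list(max_depth = 6, eta = 0.06, subsample = 0.8, nrounds = 150))
}

#' Train one classifier
#'
#' Fits one of the registry algorithms on a feature matrix and returns a
#' uniform model wrapper. Linear algorithms receive standardized features
#' when the matrix is a 2D-descriptor family (fingerprint bits are left
#' raw); the scaling is fitted on the training rows and stored for
#' prediction. All engine randomness is seeded.
#'
#' @param x numeric feature matrix (rows = molecules).
#' @param y labels (2 or more classes).
#' @param algorithm one of \code{\link{org_algorithms}()}.
#' @param seed integer seed.
#' @param params named list of engine hyperparameter overrides; recorded in
#'   the fitted object.
#' @param standardize force feature standardization on or off (default:
#'   linear algorithm on a \code{"2d"} matrix).
#' @return object of class \code{probe_model}.
#' @export
train_classifier <- function(x, y, algorithm, seed = 1, params = list(),
                             standardize = NULL) {
  algorithm <- match.arg(algorithm, org_algorithms())
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) < 2) stopf("train_classifier(): y has a single class")
  classes <- levels(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  family <- attr(x, "family")
  if (is.null(standardize))
    standardize <- algorithm %in% LINEAR_ALGOS && identical(family, "2d")
  scaling <- NULL
  if (standardize) {
    ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
    x <- scale(x, center = ctr, scale = scl)
    scaling <- list(center = ctr, scale = scl)
  }

  fit <- with_seed(seed, {
    if (algorithm == "decision_tree") {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      do.call(rpart::rpart,
              c(list(.y ~ ., data = df, method = "class"), params))
    } else if (algorithm == "random_forest") {
      do.call(randomForest::randomForest,
              c(list(x = x, y = y, ntree = params$ntree %||% 500),
                params[setdiff(names(params), "ntree")]))
    } else if (algorithm == "extra_trees") {
      ranger::ranger(x = x, y = y, probability = TRUE,
                     splitrule = "extratrees", num.random.splits = 1,
                     num.trees = params$num.trees %||% 500,
                     seed = seed, num.threads = 1)
    } else if (algorithm == "adaboost") {
      fit_samme(x, y, n_rounds = params$n_rounds %||% 50,
                max_depth = params$max_depth %||% 1)
    } else if (algorithm %in% XGB_ALGOS) {
      slot <- utils::modifyList(xgb_slot_params(algorithm), params)
      nrounds <- slot$nrounds; slot$nrounds <- NULL
      obj <- if (nlevels(y) == 2) list(objective = "binary:logistic")
             else list(objective = "multi:softprob", num_class = nlevels(y))
      dtr <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(params = c(slot, obj, list(nthread = 1, seed = seed)),
                         data = dtr, nrounds = nrounds, verbose = 0)
    } else if (algorithm == "logistic_regression") {
      fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
      lam <- params$lambda %||% (1 / nrow(x))
      glmnet::glmnet(x, y, family = fam, alpha = 0, lambda = lam,
                     standardize = FALSE)
    } else { # linear_svm
      e1071::svm(x = x, y = y, kernel = "linear", probability = TRUE,
                 scale = FALSE, cost = params$cost %||% 1)
    }
  })

  structure(list(algorithm = algorithm, fit = fit, classes = classes,
                 feature_names = colnames(x), family = family,
                 scaling = scaling, seed = seed, params = params,
                 n_train = nrow(x)),
            class = "probe_model")
}

# ---- SAMME adaptive boosting over rpart stumps -----------------------------

fit_samme <- function(x, y, n_rounds = 50, max_depth = 1) {
  n <- nrow(x); K <- nlevels(y)
  w <- rep(1 / n, n)
  df <- data.frame(x, check.names = FALSE)
  stumps <- list(); alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    df$.y <- y
    st <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = max_depth,
                                                      cp = 0, minsplit = 2,
                                                      xval = 0))
    pred <- predict(st, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break          # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break               # perfect stump, votes saturate
  }
  structure(list(stumps = stumps, alphas = alphas, classes = levels(y)),
            class = "samme_fit")
}

predict_samme <- function(object, x) {
  df <- data.frame(x, check.names = FALSE)
  K <- length(object$classes)
  votes <- matrix(0, nrow(df), K, dimnames = list(NULL, object$classes))
  for (m in seq_along(object$stumps)) {
    pred <- predict(object$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + object$alphas[m]
  }
  # softmax of the (scaled) vote margins -> probability-like scores
  v <- votes - apply(votes, 1, max)
  p <- exp(v / max(1, mean(abs(object$alphas))))
  p / rowSums(p)
}

# ---- prediction ------------------------------------------------------------

#' Class-probability predictions
#'
#' Returns the probability matrix (one named column per class, rows summing
#' to 1) or the hard label obtained as the argmax with a deterministic
#' lowest-index tie-break.
#'
#' @param object a \code{probe_model}.
#' @param newdata feature matrix with the same columns the model was
#'   trained on (a width mismatch is fatal and reports both widths).
#' @param type \code{"prob"} or \code{"class"}.
#' @param ... unused.
#' @export
predict.probe_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)))
    colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
  if (ncol(newdata) != length(object$feature_names))
    stopf("feature width mismatch: model trained on %d features, newdata has %d",
          length(object$feature_names), ncol(newdata))
  if (!is.null(object$scaling))
    newdata <- scale(newdata, center = object$scaling$center,
                     scale = object$scaling$scale)
  alg <- object$algorithm
  fit <- object$fit
  prob <-
    if (alg == "decision_tree") {
      predict(fit, data.frame(newdata, check.names = FALSE), type = "prob")
    } else if (alg == "random_forest") {
      predict(fit, newdata, type = "prob")
    } else if (alg == "extra_trees") {
      predict(fit, data = newdata, num.threads = 1)$predictions
    } else if (alg == "adaboost") {
      predict_samme(fit, newdata)
    } else if (alg %in% XGB_ALGOS) {
      p <- predict(fit, xgboost::xgb.DMatrix(newdata))
      if (length(object$classes) == 2) cbind(1 - p, p) else p
    } else if (alg == "logistic_regression") {
      p <- predict(fit, newdata, type = "response")
      if (length(dim(p)) == 3) p <- p[, , 1]
      if (is.null(dim(p)) || ncol(p) == 1) cbind(1 - as.numeric(p), as.numeric(p)) else p
    } else {
      p <- attr(predict(fit, newdata, probability = TRUE), "probabilities")
      p[, object$classes, drop = FALSE]
    }
  prob <- as.matrix(prob)
  colnames(prob) <- object$classes
  prob <- prob / rowSums(prob)
  rownames(prob) <- rownames(newdata)
  if (type == "prob") return(prob)
  object$classes[apply(prob, 1, which.max)]   # which.max = lowest-index tie-break
}

#' @method print probe_model
#' @export
print.probe_model <- function(x, ...) {
  cat("probe_model:", x$algorithm, "|", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), ") |", length(x$feature_names),
      "features", if (!is.null(x$family)) paste0("[", x$family, "]") else "",
      "| n =", x$n_train, "\n")
  invisible(x)
}
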