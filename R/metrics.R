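#' Stratified train/test split
#'
#' Splits row indices into a training and a test partition, stratified by
#' label: within each class, \code{round(train_fraction * n_class)} rows go
#' to training. Classes with fewer than 2 members are kept entirely in the
#' training partition with a warning. Reproducible for a fixed seed.
#'
#' @param y labels.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_dataset <- function(y, train_fraction = 0.8, seed = 1) {
  y <- as.character(y)
  if (!length(y)) stopf("split_dataset(): empty label vector")
  train <- integer(); test <- integer()
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < 2) {
        warnf("class '%s' has %d member(s); kept entirely in train", cl, length(idx))
        train <- c(train, idx)
        next
      }
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      tr <- sample(idx, n_tr)
      train <- c(train, tr)
      test <- c(test, setdiff(idx, tr))
    }
  })
  list(train = sort(train), test = sort(test))
}

#' Stratified cross-validation folds
#'
#' @param y labels.
#' @param folds requested fold count; reduced with a warning if some class
#'   has fewer members than folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments (1..folds).
#' @export
make_folds <- function(y, folds = 5, seed = 1) {
  y <- as.character(y)
  min_class <- min(table(y))
  if (min_class < folds) {
    warnf("fold count reduced from %d to %d (smallest class has %d members)",
          folds, max(2L, min_class), min_class)
    folds <- max(2L, min_class)
  }
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

# binary AUC: probability that a positive outranks a negative (ties count 1/2)
auc_binary <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics with binary or support-weighted averaging
#'
#' Computes accuracy, AUC, recall and precision plus the confusion matrix.
#' For binary tasks the positive class drives recall/precision and the AUC is
#' the rank statistic of the positive-class probability. For multiclass
#' tasks the weighted variants are support-weighted one-vs-rest averages; by
#' construction the weighted recall equals the accuracy. Classes absent from
#' \code{y_true} are skipped for one-vs-rest AUC and the weights renormalized
#' (with a warning).
#'
#' @param y_true,y_pred true and predicted labels.
#' @param y_prob probability matrix with one named column per class; rows
#'   must sum to 1 (tolerance 1e-9). Optional: without it AUC is NA.
#' @param average \code{"binary"} or \code{"weighted"}; \code{"auto"} picks
#'   binary for two classes.
#' @param positive positive class for binary averaging (default: second of
#'   the sorted class labels).
#' @return list: \code{acc}, \code{auc}, \code{recall}, \code{precision},
#'   \code{confusion}.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob = NULL,
                            average = c("auto", "binary", "weighted"),
                            positive = NULL) {
  average <- match.arg(average)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- if (!is.null(y_prob)) colnames(y_prob) else sort(unique(c(y_true, y_pred)))
  if (!is.null(y_prob)) {
    if (is.null(colnames(y_prob))) stopf("y_prob must have class column names")
    bad <- abs(rowSums(y_prob) - 1) > 1e-9
    if (any(bad)) stopf("y_prob rows do not sum to 1 (max deviation %.3g)",
                        max(abs(rowSums(y_prob) - 1)))
  }
  if (average == "auto") average <- if (length(classes) == 2) "binary" else "weighted"

  tt <- factor(y_true, levels = classes)
  pp <- factor(y_pred, levels = classes)
  confusion <- table(true = tt, predicted = pp)
  acc <- mean(y_true == y_pred)

  if (average == "binary") {
    if (length(classes) != 2) stopf("binary averaging requires exactly 2 classes")
    positive <- positive %||% classes[2]
    if (!positive %in% classes) stopf("positive class '%s' not among classes", positive)
    tp <- sum(y_true == positive & y_pred == positive)
    fn <- sum(y_true == positive & y_pred != positive)
    fp <- sum(y_true != positive & y_pred == positive)
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    auc <- if (!is.null(y_prob)) auc_binary(y_prob[, positive], y_true == positive)
           else NA_real_
  } else {
    present <- classes[classes %in% y_true]
    if (length(present) < length(classes) && !is.null(y_prob))
      warnf("classes absent from y_true skipped for OVR AUC: %s",
            paste(setdiff(classes, present), collapse = ", "))
    support <- vapply(present, function(cl) sum(y_true == cl), 0)
    w <- support / sum(support)
    rec <- vapply(present, function(cl) {
      tp <- sum(y_true == cl & y_pred == cl)
      tp / sum(y_true == cl)
    }, 0)
    prec <- vapply(present, function(cl) {
      denom <- sum(y_pred == cl)
      if (denom > 0) sum(y_true == cl & y_pred == cl) / denom else 0
    }, 0)
    recall <- sum(w * rec)
    precision <- sum(w * prec)
    auc <- if (!is.null(y_prob)) {
      aucs <- vapply(present, function(cl) auc_binary(y_prob[, cl], y_true == cl), 0)
      sum(w * aucs)
    } else NA_real_
  }
  list(acc = acc, auc = auc, recall = recall, precision = precision,
       confusion = confusion)
}

#' Cross-validate one algorithm on one feature matrix
#'
#' Stratified k-fold cross-validation; per-fold metrics are aggregated as
#' mean and standard deviation. Folds degenerating to a single class are
#' skipped with a warning.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param algorithm one of \code{\link{org_algorithms}()}.
#' @param folds fold count (default 5).
#' @param seed integer seed (controls folds and any algorithm randomness).
#' @param positive positive class for binary metrics.
#' @param params optional engine hyperparameter overrides.
#' @return list with \code{per_fold} (data frame), \code{mean} and \code{sd}
#'   named metric vectors, and \code{fold_assignment}.
#' @export
cross_validate <- function(x, y, algorithm, folds = 5, seed = 1,
                           positive = NULL, params = list()) {
  if (folds < 2) stopf("cross_validate(): folds must be >= 2")
  y <- as.character(y)
  fold_of <- make_folds(y, folds, seed)
  folds <- max(fold_of)
  rows <- list()
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    if (length(unique(y[te])) < 2 && length(unique(y)) == 2) {
      warnf("fold %d is single-class; skipped", f)
      next
    }
    fit <- train_classifier(x[tr, , drop = FALSE], y[tr], algorithm,
                            seed = seed + f, params = params)
    prob <- predict(fit, x[te, , drop = FALSE], type = "prob")
    pred <- predict(fit, x[te, , drop = FALSE], type = "class")
    met <- compute_metrics(y[te], pred, prob, positive = positive)
    rows[[length(rows) + 1]] <-
      data.frame(fold = f, acc = met$acc, auc = met$auc,
                 recall = met$recall, precision = met$precision)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("acc", "auc", "recall", "precision")
  list(per_fold = per_fold,
       mean = vapply(metric_cols, function(cn) mean(per_fold[[cn]], na.rm = TRUE), 0),
       sd = vapply(metric_cols, function(cn) stats::sd(per_fold[[cn]], na.rm = TRUE), 0),
       fold_assignment = fold_of)
}
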