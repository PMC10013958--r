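#' Feature-family by algorithm comparison grid
#'
#' Trains and evaluates every (feature family, algorithm) combination under a
#' shared protocol: one stratified 80/20 split per task (identical across
#' cells), stratified k-fold cross-validation on the training partition, and
#' a final fit evaluated on the held-out test partition. The best cell is
#' flagged by test accuracy with cross-validation accuracy as tie-break (and
#' deterministic name order after that). A cell whose training fails is
#' marked failed and the grid continues.
#'
#' @param features named list mapping family name to a feature matrix; all
#'   matrices must have the same rows in the same order.
#' @param y labels, one per row.
#' @param algorithms algorithm names (default: the full ten-member registry).
#' @param seed integer seed shared by the split, the folds and the engines.
#' @param folds cross-validation fold count.
#' @param train_fraction training share of the split.
#' @param positive positive class for binary metrics.
#' @param task optional task label carried into the report.
#' @return object of class \code{eval_grid}: list with \code{cells} (one data
#'   frame row per combination: CV mean/sd and test metrics), \code{best}
#'   (family, algorithm), the \code{split}, and \code{confusions}.
#' @export
grid_compare <- function(features, y, algorithms = org_algorithms(), seed = 1,
                         folds = 5, train_fraction = 0.8, positive = NULL,
                         task = NA_character_) {
  if (!length(features) || !length(algorithms))
    stopf("grid_compare(): need at least one family and one algorithm")
  if (is.null(names(features))) stopf("grid_compare(): features must be a named list")
  y <- as.character(y)
  n <- length(y)
  if (!all(vapply(features, nrow, 0) == n))
    stopf("grid_compare(): all feature matrices must have one row per label")

  split <- split_dataset(y, train_fraction = train_fraction, seed = seed)
  rows <- list(); confusions <- list()
  for (fam in names(features)) {
    Xf <- features[[fam]]
    for (alg in algorithms) {
      cell <- tryCatch({
        cv <- cross_validate(Xf[split$train, , drop = FALSE], y[split$train],
                             alg, folds = folds, seed = seed, positive = positive)
        fit <- train_classifier(Xf[split$train, , drop = FALSE], y[split$train],
                                alg, seed = seed)
        prob <- predict(fit, Xf[split$test, , drop = FALSE], type = "prob")
        pred <- predict(fit, Xf[split$test, , drop = FALSE], type = "class")
        tm <- compute_metrics(y[split$test], pred, prob, positive = positive)
        confusions[[paste(fam, alg, sep = ".")]] <- tm$confusion
        data.frame(family = fam, algorithm = alg, failed = FALSE,
                   cv_acc = cv$mean[["acc"]], cv_acc_sd = cv$sd[["acc"]],
                   cv_auc = cv$mean[["auc"]], cv_auc_sd = cv$sd[["auc"]],
                   cv_recall = cv$mean[["recall"]], cv_precision = cv$mean[["precision"]],
                   test_acc = tm$acc, test_auc = tm$auc,
                   test_recall = tm$recall, test_precision = tm$precision,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warnf("grid cell (%s, %s) failed: %s", fam, alg, conditionMessage(e))
        data.frame(family = fam, algorithm = alg, failed = TRUE,
                   cv_acc = NA, cv_acc_sd = NA, cv_auc = NA, cv_auc_sd = NA,
                   cv_recall = NA, cv_precision = NA, test_acc = NA,
                   test_auc = NA, test_recall = NA, test_precision = NA,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- cell
    }
  }
  cells <- do.call(rbind, rows)
  ok <- !cells$failed
  best <- NULL
  if (any(ok)) {
    o <- order(-cells$test_acc, -cells$cv_acc, cells$family, cells$algorithm,
               na.last = TRUE)
    o <- o[ok[o]]
    best <- cells[o[1], c("family", "algorithm")]
  }
  structure(list(cells = cells, best = best, split = split, seed = seed,
                 task = task, confusions = confusions),
            class = "eval_grid")
}

#' @method print eval_grid
#' @export
print.eval_grid <- function(x, digits = 3, ...) {
  cat("eval_grid", if (!is.na(x$task)) paste0("[", x$task, "]") else "",
      ":", nrow(x$cells), "cells, seed", x$seed, "\n")
  df <- x$cells[, c("family", "algorithm", "cv_acc", "cv_auc", "test_acc", "test_auc")]
  df[3:6] <- lapply(df[3:6], round, digits)
  print(df, row.names = FALSE)
  if (!is.null(x$best))
    cat("best cell (test acc, tie-break cv acc):", x$best$family, "/",
        x$best$algorithm, "\n")
  invisible(x)
}

#' Heatmap-ready accuracy matrix of a grid
#'
#' @param x an \code{eval_grid}.
#' @param metric which cell metric to tabulate.
#' @return matrix with families as rows and algorithms as columns.
#' @export
heatmap_matrix <- function(x, metric = "test_acc") {
  stopifnot(inherits(x, "eval_grid"))
  fams <- unique(x$cells$family); algs <- unique(x$cells$algorithm)
  m <- matrix(NA_real_, length(fams), length(algs), dimnames = list(fams, algs))
  for (i in seq_len(nrow(x$cells)))
    m[x$cells$family[i], x$cells$algorithm[i]] <- x$cells[[metric]][i]
  m
}
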