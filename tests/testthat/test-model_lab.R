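# exhaustive concordant/discordant pair count, support-weighted for multiclass
auc_pair_oracle <- function(y, prob) {
  classes <- colnames(prob)
  present <- classes[classes %in% y]
  aucs <- w <- numeric(length(present))
  for (ci in seq_along(present)) {
    cl <- present[ci]
    pos <- which(y == cl); neg <- which(y != cl)
    s <- 0
    for (i in pos) for (j in neg)
      s <- s + (prob[i, cl] > prob[j, cl]) + 0.5 * (prob[i, cl] == prob[j, cl])
    aucs[ci] <- s / (length(pos) * length(neg))
    w[ci] <- length(pos)
  }
  sum(aucs * w / sum(w))
}

metric_count_oracle <- function(y, pred, positive = NULL, average) {
  if (average == "binary") {
    tp <- sum(y == positive & pred == positive)
    fn <- sum(y == positive & pred != positive)
    fp <- sum(y != positive & pred == positive)
    list(recall = tp / (tp + fn), precision = if (tp + fp) tp / (tp + fp) else 0)
  } else {
    present <- sort(unique(y))
    w <- vapply(present, function(cl) mean(y == cl), 0)
    rec <- vapply(present, function(cl) sum(y == cl & pred == cl) / sum(y == cl), 0)
    prec <- vapply(present, function(cl) {
      d <- sum(pred == cl); if (d) sum(y == cl & pred == cl) / d else 0
    }, 0)
    list(recall = sum(w * rec), precision = sum(w * prec))
  }
}

random_instance <- function(n, k) {
  classes <- letters[seq_len(k)]
  y <- sample(classes, n, replace = TRUE)
  while (length(unique(y)) < 2) y <- sample(classes, n, replace = TRUE)
  prob <- matrix(rexp(n * k), n, k, dimnames = list(NULL, classes))
  prob <- prob / rowSums(prob)
  pred <- classes[apply(prob, 1, which.max)]
  list(y = y, prob = prob, pred = pred)
}

test_that("stratified split honours fractions, strata and the seed", {
  y <- rep(c("a", "b"), each = 5)
  sp <- split_dataset(y, seed = 4)
  expect_length(sp$train, 8); expect_length(sp$test, 2)
  expect_equal(as.integer(table(y[sp$train])), c(4L, 4L))
  expect_identical(sp, split_dataset(y, seed = 4))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))

  y2 <- c(rep("big", 90), rep("small", 10))
  sp2 <- split_dataset(y2, seed = 1)
  expect_length(sp2$test, 20)
  expect_equal(as.integer(table(y2[sp2$test])), c(18L, 2L))

  expect_warning(sp3 <- split_dataset(c(rep("a", 9), "b"), seed = 1), "kept entirely")
  expect_true(which(c(rep("a", 9), "b") == "b") %in% sp3$train)
})

test_that("perfect and forced metric values are exact", {
  y <- c("a", "a", "b", "b")
  prob <- cbind(a = c(.9, .8, .3, .1), b = c(.1, .2, .7, .9))
  m <- compute_metrics(y, y, prob, positive = "a")
  expect_equal(m$acc, 1); expect_equal(m$recall, 1); expect_equal(m$precision, 1)
  expect_equal(m$auc, 1)
  expect_equal(unname(diag(m$confusion)), c(2, 2))
  expect_error(compute_metrics(y, y, prob * 2), "sum to 1")
})

test_that("metrics match brute-force counting oracles to 1e-12", {
  set.seed(99)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    inst <- random_instance(sample(8:30, 1), k)
    avg <- if (k == 2) "binary" else "weighted"
    pos <- if (k == 2) "b" else NULL
    m <- compute_metrics(inst$y, inst$pred, inst$prob,
                         average = avg, positive = pos)
    o <- metric_count_oracle(inst$y, inst$pred, pos, avg)
    expect_equal(m$acc, mean(inst$y == inst$pred), tolerance = 1e-12)
    expect_equal(m$recall, o$recall, tolerance = 1e-12)
    expect_equal(m$precision, o$precision, tolerance = 1e-12)
    oracle_auc <- if (k == 2) {
      suppressWarnings(auc_pair_oracle(inst$y,
                                       inst$prob[, "b", drop = FALSE])) # positive col
    } else suppressWarnings(auc_pair_oracle(inst$y, inst$prob))
    got <- suppressWarnings(m$auc)
    expect_equal(got, oracle_auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(2)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  p <- runif(40)
  prob <- cbind(a = 1 - p, b = p)
  m1 <- compute_metrics(y, ifelse(p > .5, "b", "a"), prob, positive = "b")
  q <- plogis(5 * qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)))
  prob2 <- cbind(a = 1 - q, b = q)
  m2 <- compute_metrics(y, ifelse(p > .5, "b", "a"), prob2, positive = "b")
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
})

test_that("every registry algorithm trains, predicts proper probabilities and reproduces", {
  set.seed(31)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- ifelse(X[, 1] + X[, 2] + rnorm(n, sd = .3) > 0, "pos", "neg")
  for (alg in org_algorithms()) {
    fit <- train_classifier(X, y, alg, seed = 5)
    prob <- predict(fit, X, type = "prob")
    expect_equal(dim(prob), c(n, 2))
    expect_equal(colnames(prob), c("neg", "pos"))
    expect_true(all(abs(rowSums(prob) - 1) < 1e-9))
    cls <- predict(fit, X, type = "class")
    expect_equal(cls, colnames(prob)[apply(prob, 1, which.max)])
    expect_gt(mean(cls == y), 0.8)
    fit2 <- train_classifier(X, y, alg, seed = 5)
    expect_equal(predict(fit2, X, type = "prob"), prob, tolerance = 1e-8)
  }
  expect_error(predict(fit, X[, 1:3]), "width mismatch")
})

test_that("multiclass probability rows sum to one for tree and linear engines", {
  set.seed(13)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4)
  y <- c("u", "v", "w")[1 + (X[, 1] > 0) + (X[, 2] > 0)]
  for (alg in c("lightgbm", "random_forest", "logistic_regression", "decision_tree")) {
    fit <- train_classifier(X, y, alg, seed = 2)
    prob <- predict(fit, X, type = "prob")
    expect_equal(colnames(prob), c("u", "v", "w"))
    expect_true(all(abs(rowSums(prob) - 1) < 1e-9))
  }
})

test_that("cross-validation separates blobs and collapses to chance on shuffled labels", {
  set.seed(21)
  n <- 200
  X <- rbind(matrix(rnorm(n, 0), n / 2, 2), matrix(rnorm(n, 6), n / 2, 2))
  y <- rep(c("a", "b"), each = n / 2)
  cv <- cross_validate(X, y, "decision_tree", seed = 1, positive = "b")
  expect_equal(unname(cv$mean["acc"]), 1.0)
  expect_equal(nrow(cv$per_fold), 5)

  n2 <- 400
  X2 <- matrix(rnorm(n2 * 4), n2, 4)
  y2 <- sample(rep(c("a", "b"), each = n2 / 2))
  cv2 <- cross_validate(X2, y2, "lightgbm", seed = 3, positive = "b")
  expect_gte(unname(cv2$mean["auc"]), 0.35)
  expect_lte(unname(cv2$mean["auc"]), 0.65)
})

test_that("fold counts adapt to small classes with a warning", {
  y <- c(rep("a", 20), rep("b", 3))
  expect_warning(f <- make_folds(y, folds = 5, seed = 1), "reduced")
  expect_equal(max(f), 3)
  y2 <- rep(c("a", "b"), each = 25)
  f2 <- make_folds(y2, folds = 5, seed = 1)
  expect_true(all(table(f2) == 10))
})

test_that("the comparison grid shares one split, flags the best cell and survives failures", {
  set.seed(77)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5)
  y <- ifelse(X[, 1] > 0, "hit", "miss")
  one <- grid_compare(list(fam = X), y, algorithms = "decision_tree", seed = 2,
                      positive = "hit")
  expect_equal(nrow(one$cells), 1)

  g <- grid_compare(list(f1 = X, f2 = cbind(X, X[, 1])), y,
                    algorithms = c("decision_tree", "logistic_regression"),
                    seed = 2, positive = "hit")
  expect_equal(nrow(g$cells), 4)
  expect_true(all(g$cells$test_acc >= 0.9))
  expect_false(any(g$cells$failed))
  best <- g$cells[order(-g$cells$test_acc, -g$cells$cv_acc,
                        g$cells$family, g$cells$algorithm), ][1, ]
  expect_equal(g$best$family, best$family)
  expect_equal(g$best$algorithm, best$algorithm)
  hm <- heatmap_matrix(g)
  expect_equal(dim(hm), c(2, 2))
})
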