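make_binary_fit <- function(alg, n = 150, seed = 17) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  X <- cbind(X, dead = 1)            # constant column: never split on
  y <- ifelse(X[, 1] - X[, 2] + rnorm(n, sd = .4) > 0, "yes", "no")
  list(fit = train_classifier(X, y, alg, seed = seed), X = X, y = y)
}

test_that("tree SHAP is additive and ignores unused features", {
  b <- make_binary_fit("gbt")
  sh <- shap_attributions(b$fit, b$X, class = "yes")
  expect_true(all(abs(rowSums(sh$values) + sh$base - sh$margin) < 1e-5))
  expect_true(all(sh$values[, "dead"] == 0))
})

test_that("linear SHAP is additive to machine precision", {
  b <- make_binary_fit("logistic_regression")
  sh <- shap_attributions(b$fit, b$X, class = "yes")
  expect_true(all(abs(rowSums(sh$values) + sh$base - sh$margin) < 1e-9))
  expect_true(all(sh$values[, "dead"] == 0))
})

test_that("multiclass SHAP explains the requested class additively", {
  set.seed(3)
  X <- matrix(rnorm(180 * 4), 180, 4)
  colnames(X) <- paste0("g", 1:4)
  y <- c("u", "v", "w")[1 + (X[, 1] > 0) + (X[, 2] > 0)]
  fit <- train_classifier(X, y, "lightgbm", seed = 3)
  sh <- shap_attributions(fit, X, class = "v")
  expect_equal(sh$class, "v")
  expect_true(all(abs(rowSums(sh$values) + sh$base - sh$margin) < 1e-4))
  expect_error(shap_attributions(fit, X, class = "zz"), "not a model class")
})

test_that("unsupported engines fail naming the algorithm", {
  b <- make_binary_fit("random_forest")
  expect_error(shap_attributions(b$fit, b$X), "random_forest")
})

test_that("a single stump yields exactly two attribution levels matching the margins", {
  set.seed(8)
  X <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "x1"))
  y <- ifelse(X[, 1] > 0, "a", "b")
  fit <- train_classifier(X, y, "gbt", seed = 1,
                          params = list(nrounds = 1, max_depth = 1))
  sh <- shap_attributions(fit, X, class = "b")
  expect_equal(length(unique(round(sh$values[, 1], 10))), 2)
  # closed form: the single feature's value is the margin minus the base
  expect_true(all(abs(sh$values[, 1] - (sh$margin - sh$base)) < 1e-5))
})

test_that("gain importance covers the full feature set with zeros for unused features", {
  b <- make_binary_fit("lightgbm")
  imp <- feature_importance(b$fit)
  expect_equal(names(imp), colnames(b$X))
  expect_equal(unname(imp["dead"]), 0)
  expect_gt(imp["f1"], imp["dead"])
  expect_equal(sum(imp), 1, tolerance = 1e-6)   # gains are normalized shares
})

test_that("min-max normalization maps to [0,1], keeps rank order, max becomes 1", {
  x <- c(a = 3, b = 1, c = 10, d = 1)
  n <- minmax_normalize(x)
  expect_equal(unname(n["c"]), 1)
  expect_equal(unname(n["b"]), 0)
  expect_equal(order(n), order(x))
  expect_true(all(minmax_normalize(c(2, 2, 2)) == 0))
})

test_that("top-k consensus is a prefix intersection with strict universe checks", {
  u <- paste0("k", 1:20)
  expect_length(topk_consensus(u, u, 15), 15)
  expect_length(topk_consensus(u, rev(u), 5), 0)
  expect_setequal(topk_consensus(u, c(u[3:1], u[4:20]), 3), u[1:3])
  expect_error(topk_consensus(u, paste0("m", 1:20), 5), "universes")
  expect_error(topk_consensus(u, u, 25), "exceeds")
})

test_that("rank_features breaks ties by name deterministically", {
  s <- c(zeta = 1, alpha = 1, mid = 2)
  expect_equal(rank_features(s), c("mid", "alpha", "zeta"))
})

test_that("heteroatom fraction counts N/O/P keys and flags charge/disconnection", {
  expect_equal(as.numeric(heteroatom_fraction("MACCS29")), 1.0)  # phosphorus
  keys <- maccs_keys()
  carbon_only <- keys$name[keys$supported & !keys$has_N & !keys$has_O & !keys$has_P]
  expect_equal(as.numeric(heteroatom_fraction(carbon_only[1:5])), 0)
  # hand-count oracle: P key and N key are heteroatom; iodine and ring are not
  mixed <- c("MACCS29", "MACCS161", "MACCS27", "MACCS165")
  expect_equal(as.numeric(heteroatom_fraction(mixed)), 0.5)
  flagged <- attr(heteroatom_fraction(c("MACCS49", "MACCS166", "MACCS29")), "flagged")
  expect_setequal(flagged, c("MACCS49", "MACCS166"))
  expect_error(heteroatom_fraction("MACCS999"), "unknown")
})

test_that("directional summary recovers planted signs on a linear model", {
  set.seed(12)
  n <- 300
  X <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
              dimnames = list(NULL, c("up", "down", "noise", "dead")))
  X[, "dead"] <- 0
  z <- 2 * X[, "up"] - 2 * X[, "down"] + rnorm(n, sd = .5)
  y <- ifelse(z > 0, "pos", "neg")
  fit <- train_classifier(X, y, "logistic_regression", seed = 1)
  sh <- shap_attributions(fit, X, class = "pos")
  d <- directional_summary(sh, X)
  expect_equal(d$direction[d$feature == "up"], "positive")
  expect_equal(d$direction[d$feature == "down"], "negative")
  expect_equal(d$direction[d$feature == "dead"], "neutral")
})

test_that("the attribution report assembles normalized scores, ranks and consensus", {
  b <- make_binary_fit("lightgbm")
  rep <- attribution_report(b$fit, b$X, k = c(2, 4))
  pf <- rep$per_feature
  expect_equal(max(pf$shap_norm), 1)
  expect_equal(max(pf$gain_norm), 1)
  expect_equal(sort(pf$rank_shap), seq_len(nrow(pf)))
  expect_true(all(lengths(rep$consensus) <= c(2, 4)))
  # normalization preserves the shap ranking
  expect_equal(order(-pf$shap_norm, pf$feature), order(pf$rank_shap))
})
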