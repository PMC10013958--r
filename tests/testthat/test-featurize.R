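test_that("MACCS fingerprints have 166 named binary keys and are deterministic", {
  X <- featurize(c(a = "CC(=O)Oc1ccccc1C(=O)O", b = "CCO"), "maccs")
  expect_equal(ncol(X), 166)
  expect_equal(colnames(X), paste0("MACCS", 1:166))
  expect_true(all(X %in% c(0, 1)))
  X2 <- featurize(c(a = "CC(=O)Oc1ccccc1C(=O)O", b = "CCO"), "maccs")
  expect_identical(X, X2)
})

test_that("methane sets no aromatic-ring keys; salts set the fragment key", {
  X <- featurize(c(m = "C"), "maccs")
  expect_equal(unname(X[1, c("MACCS125", "MACCS162", "MACCS165")]), c(0, 0, 0))
  salt <- featurize(c(s = "C[N+](C)(C)C.[Cl-]"), "maccs")
  expect_equal(unname(salt[1, "MACCS166"]), 1)
  expect_equal(unname(salt[1, "MACCS49"]), 1)   # charged species
  mono <- featurize(c(s = "C[N+](C)(C)CCO"), "maccs")
  expect_equal(unname(mono[1, "MACCS166"]), 0)
  # two fused aromatic rings -> key 125
  naph <- featurize(c(n = "c1ccc2ccccc2c1"), "maccs")
  expect_equal(unname(naph[1, "MACCS125"]), 1)
})

test_that("unparsable SMILES are rejected, not silently dropped", {
  X <- featurize(c(good = "CCO", bad = "xx##"), "maccs")
  expect_equal(nrow(X), 1)
  expect_equal(attr(X, "rejects")$id, "bad")
  expect_error(featurize("CCO", family = "pubchem"), "no backend")
})

test_that("folded ECFP4 has the requested width and binary values", {
  X <- featurize(c(a = "c1ccc2ccccc2c1CCN"), "ecfp4", nbits = 256)
  expect_equal(ncol(X), 256)
  expect_true(all(X %in% c(0, 1)))
  expect_gt(sum(X), 0)
})

test_that("2D descriptors encode chemistry-forced orderings", {
  D <- featurize(c(benzene = "c1ccccc1", phenol = "Oc1ccccc1"), "2d")
  expect_gt(D["phenol", "hbd"], D["benzene", "hbd"])
  expect_equal(unname(D["benzene", "total_formal_charge"]), 0)
  expect_identical(D, featurize(c(benzene = "c1ccccc1", phenol = "Oc1ccccc1"), "2d"))
  cat_d <- featurize(c(x = "C[N+](C)(C)C.[Cl-]"), "2d")
  expect_equal(unname(cat_d[1, "total_formal_charge"]), 0) # ion pair nets to zero
  expect_equal(unname(cat_d[1, "n_pos_atoms"]), 1)
  expect_equal(unname(cat_d[1, "n_fragments"]), 2)
})

test_that("MACCS key table resolves the named keys with element annotations", {
  keys <- maccs_keys()
  expect_equal(nrow(keys), 166)
  expect_true(keys$has_P[keys$key == 29])       # phosphorus key
  expect_true(keys$is_charge[keys$key == 49])   # charge key
  expect_true(keys$is_disconnection[keys$key == 166])
  expect_false(keys$has_N[keys$key == 27] || keys$has_O[keys$key == 27])  # iodine
})

greedy_selection_oracle <- function(x, cut) {
  # enumerate all pairwise correlations and simulate the greedy keep-first scan
  v <- apply(x, 2, stats::var)
  alive <- which(v > 0)
  cm <- abs(stats::cor(x[, alive, drop = FALSE]))
  kept <- integer()
  for (j in seq_along(alive)) {
    if (!length(kept) || all(cm[j, kept] <= cut)) kept <- c(kept, j)
  }
  colnames(x)[alive[kept]]
}

test_that("feature selection matches the brute-force greedy oracle", {
  set.seed(42)
  for (rep in 1:5) {
    x <- matrix(rnorm(50 * 20), 50, 20)
    # plant three highly correlated pairs and one constant column
    for (p in 1:3) x[, 10 + p] <- x[, p] + rnorm(50, sd = 0.02)
    x[, 20] <- 1
    colnames(x) <- sprintf("f%02d", 1:20)
    sel <- select_features(x, corr_cut = 0.95)
    expect_equal(sel$kept, greedy_selection_oracle(x, 0.95))
    expect_true("f20" %in% sel$dropped$name)
    # idempotent on its own output
    sel2 <- select_features(sel$matrix, corr_cut = 0.95)
    expect_equal(sel2$kept, sel$kept)
    expect_equal(nrow(sel2$dropped), 0)
  }
})

test_that("duplicated and constant columns are reduced as forced", {
  x <- cbind(a = rnorm(30), b = rnorm(30))
  x <- cbind(x, c = x[, "a"], d = 5)
  sel <- select_features(x)
  expect_setequal(sel$kept, c("a", "b"))
  expect_error(select_features(x[1, , drop = FALSE]), "2 rows")
})

test_that("kept columns never exceed the correlation cut against their anchors", {
  set.seed(9)
  x <- matrix(rnorm(40 * 12), 40, 12)
  x[, 5] <- x[, 1] * 0.999 + rnorm(40, sd = 1e-3)
  sel <- select_features(x, corr_cut = 0.9)
  cm <- abs(stats::cor(sel$matrix))
  diag(cm) <- 0
  # for the greedy keep-first scheme every kept/kept pair must be <= cut
  expect_true(all(cm <= 0.9 + 1e-12))
})

test_that("missing-value columns are dropped or median-imputed from stored stats", {
  set.seed(4)
  x <- matrix(rnorm(20 * 4), 20, 4)
  colnames(x) <- c("w", "x", "y", "z")
  x[1:10, 1] <- NaN                 # 50% missing -> dropped
  x[1, 2] <- NA                     # 5% missing -> imputed
  sel <- select_features(x)
  expect_false("w" %in% sel$kept)
  expect_true("x" %in% sel$kept)
  expect_equal(unname(sel$matrix[1, "x"]), stats::median(x[-1, 2]))
  # the stored medians drive imputation of new data
  new <- x[1:3, sel$kept]
  new[2, "y"] <- NA
  applied <- apply_selection(sel, new)
  expect_equal(unname(applied[2, "y"]), unname(sel$medians[["y"]]))
})
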