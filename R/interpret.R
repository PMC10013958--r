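#' Per-sample SHAP attributions
#'
#' Exact tree-path (TreeSHAP) attributions for the xgboost-backed boosting
#' models, and the linear decomposition \code{coef * (x - mean(x))} for the
#' ridge logistic model. Attributions are additive: per-sample values plus
#' the base value reproduce the model margin. For multiclass models the
#' attributions of one class are returned (mitochondria by default when
#' present, matching the targeting question the framework asks).
#'
#' @param model a \code{probe_model} whose algorithm is one of the boosting
#'   slots or \code{logistic_regression}; other engines are unsupported and
#'   raise an error naming the type.
#' @param x feature matrix to explain.
#' @param class for multiclass models, the class whose attributions are
#'   returned.
#' @return object of class \code{shap_attribution}: list with \code{values}
#'   (n x d matrix), \code{base} (per-sample base value), \code{margin}
#'   (per-sample model margin, for additivity checks) and \code{class}.
#' @export
shap_attributions <- function(model, x, class = NULL) {
  stopifnot(inherits(model, "probe_model"))
  if (!is.matrix(x)) x <- as.matrix(x)
  K <- length(model$classes)
  if (is.null(class))
    class <- if ("mitochondria" %in% model$classes) "mitochondria" else model$classes[min(2, K)]
  ci <- match(class, model$classes)
  if (is.na(ci)) stopf("class '%s' is not a model class", class)
  if (!is.null(model$scaling))
    x <- scale(x, center = model$scaling$center, scale = model$scaling$scale)

  if (model$algorithm %in% XGB_ALGOS) {
    dm <- xgboost::xgb.DMatrix(x)
    contrib <- predict(model$fit, dm, predcontrib = TRUE)
    margin <- predict(model$fit, dm, outputmargin = TRUE)
    if (K == 2) {
      vals <- contrib[, seq_len(ncol(x)), drop = FALSE]
      base <- contrib[, ncol(x) + 1]
      if (ci == 1) { vals <- -vals; base <- -base; margin <- -margin }
    } else {
      vals <- contrib[, ci, seq_len(ncol(x)), drop = TRUE]
      if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(x))
      base <- contrib[, ci, ncol(x) + 1]
      margin <- margin[, ci]
    }
  } else if (model$algorithm == "logistic_regression") {
    cf <- glmnet::coef.glmnet(model$fit)
    if (is.list(cf)) {          # multinomial: one coefficient block per class
      beta <- as.numeric(cf[[ci]])[-1]
      a0 <- as.numeric(cf[[ci]])[1]
    } else {
      beta <- as.numeric(cf)[-1]
      a0 <- as.numeric(cf)[1]
      if (ci == 1) { beta <- -beta; a0 <- -a0 }
    }
    mu <- colMeans(x)
    vals <- sweep(x, 2, mu) * rep(beta, each = nrow(x))
    base <- rep(a0 + sum(beta * mu), nrow(x))
    margin <- as.numeric(x %*% beta) + a0
  } else {
    stopf("SHAP attributions are not supported for algorithm '%s'", model$algorithm)
  }
  colnames(vals) <- model$feature_names
  structure(list(values = vals, base = base, margin = margin, class = class),
            class = "shap_attribution")
}

#' Tree gain importance (with split-count alongside)
#'
#' Split-gain importance for the boosting models (the gradient-boosting
#' convention), absolute coefficients for the linear model. Features the
#' model never used score 0, so the vector always covers the full feature
#' set.
#'
#' @param model a \code{probe_model}.
#' @return named numeric vector over all model features, attribute
#'   \code{frequency} carrying the split-count ranking for tree models.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "probe_model"))
  nm <- model$feature_names
  out <- stats::setNames(numeric(length(nm)), nm)
  if (model$algorithm %in% XGB_ALGOS) {
    imp <- xgboost::xgb.importance(model = model$fit)
    out[imp$Feature] <- imp$Gain
    freq <- stats::setNames(numeric(length(nm)), nm)
    freq[imp$Feature] <- imp$Frequency
    attr(out, "frequency") <- freq
  } else if (model$algorithm == "logistic_regression") {
    cf <- glmnet::coef.glmnet(model$fit)
    if (is.list(cf)) {
      beta <- rowMeans(abs(vapply(cf, function(b) as.numeric(b)[-1],
                                  numeric(length(nm)))))
    } else beta <- abs(as.numeric(cf)[-1])
    out[] <- beta
  } else if (model$algorithm == "random_forest") {
    imp <- randomForest::importance(model$fit)
    out[rownames(imp)] <- imp[, 1]
  } else if (model$algorithm == "decision_tree") {
    vi <- model$fit$variable.importance
    out[names(vi)] <- vi
  } else {
    stopf("feature importance is not available for algorithm '%s'", model$algorithm)
  }
  out
}

#' Min-max normalization to [0, 1]
#'
#' Rescales scores so the maximum is 1 and the minimum 0; rank order is
#' preserved. A constant vector (no spread to normalize) maps to all zeros.
#' @param x numeric vector.
#' @return rescaled vector.
#' @export
minmax_normalize <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(stats::setNames(rep(0, length(x)), names(x)))
  (x - rng[1]) / diff(rng)
}

#' Rank features by score, ties broken by name
#' @param scores named numeric vector.
#' @return character vector of feature names in decreasing score order.
#' @export
rank_features <- function(scores) {
  stopifnot(!is.null(names(scores)))
  names(scores)[order(-scores, names(scores))]
}

#' Top-k consensus of two rankings
#'
#' The intersection of the two top-k prefixes, i.e. the features both the
#' SHAP ranking and the importance ranking place in their top k.
#'
#' @param rank_a,rank_b character vectors: full feature rankings over the
#'   same feature universe.
#' @param k prefix length.
#' @return character vector (subset of both prefixes, at most k features).
#' @export
topk_consensus <- function(rank_a, rank_b, k) {
  if (!setequal(rank_a, rank_b))
    stopf("rankings cover different feature universes")
  if (k > length(rank_a)) stopf("k = %d exceeds the universe size %d", k, length(rank_a))
  intersect(rank_a[seq_len(k)], rank_b[seq_len(k)])
}

#' Heteroatom share of a MACCS feature set
#'
#' The fraction of MACCS keys in a set whose definition mentions nitrogen,
#' oxygen or phosphorus. Charge and disconnection keys do not count toward
#' the fraction but are flagged separately in the \code{"flagged"} attribute,
#' since they encode ionization rather than element content.
#'
#' @param features character vector of key names (e.g. \code{"MACCS29"}).
#' @param keys key definition table (default \code{\link{maccs_keys}()}).
#' @return fraction in [0, 1]; attribute \code{flagged} lists the charge /
#'   disconnection keys present in the set.
#' @export
heteroatom_fraction <- function(features, keys = maccs_keys()) {
  idx <- match(features, keys$name)
  if (anyNA(idx))
    stopf("unknown feature name(s): %s", paste(features[is.na(idx)], collapse = ", "))
  hetero <- keys$has_N[idx] | keys$has_O[idx] | keys$has_P[idx]
  out <- mean(hetero)
  attr(out, "flagged") <- features[keys$is_charge[idx] | keys$is_disconnection[idx]]
  out
}

#' Directional summary of attributions
#'
#' For each feature, the mean SHAP value among samples where the feature is
#' active (bit = 1 for fingerprints; all samples for continuous features),
#' labeled positive / negative / neutral with a dead zone of 1e-6 around
#' zero. A positive direction means the feature pushes predictions toward
#' the explained class.
#'
#' @param shap a \code{shap_attribution}.
#' @param x the feature matrix that was explained.
#' @return data frame: \code{feature}, \code{mean_shap_active},
#'   \code{n_active}, \code{direction}.
#' @export
directional_summary <- function(shap, x) {
  stopifnot(inherits(shap, "shap_attribution"))
  if (!is.matrix(x)) x <- as.matrix(x)
  binary <- all(x %in% c(0, 1))
  means <- vapply(seq_len(ncol(x)), function(j) {
    act <- if (binary) x[, j] == 1 else rep(TRUE, nrow(x))
    if (!any(act)) return(0)
    mean(shap$values[act, j])
  }, 0)
  n_act <- if (binary) colSums(x == 1) else rep(nrow(x), ncol(x))
  data.frame(feature = colnames(x),
             mean_shap_active = means,
             n_active = as.integer(n_act),
             direction = ifelse(abs(means) < 1e-6, "neutral",
                                ifelse(means > 0, "positive", "negative")),
             stringsAsFactors = FALSE)
}

#' Full attribution report for a fitted model
#'
#' Combines the SHAP ranking (mean absolute attribution) and the gain
#' importance ranking: min-max normalized scores, ranks under both methods,
#' top-k consensus sets, the directional summary, and -- for MACCS models --
#' the heteroatom fraction of the top-50 consensus-eligible keys.
#'
#' @param model a supported \code{probe_model}.
#' @param x feature matrix to explain.
#' @param k consensus prefix sizes.
#' @param class multiclass class of interest.
#' @return object of class \code{attribution_report}.
#' @export
attribution_report <- function(model, x, k = c(15, 30, 50), class = NULL) {
  sh <- shap_attributions(model, x, class = class)
  mean_abs <- colMeans(abs(sh$values))
  mean_signed <- colMeans(sh$values)
  gain <- feature_importance(model)
  rank_shap <- rank_features(mean_abs)
  rank_gain <- rank_features(gain)
  consensus <- lapply(stats::setNames(k, paste0("top", k)), function(kk)
    topk_consensus(rank_shap, rank_gain, kk))
  per_feature <- data.frame(
    feature = names(mean_abs),
    mean_abs_shap = unname(mean_abs),
    mean_signed_shap = unname(mean_signed),
    gain = unname(gain[names(mean_abs)]),
    shap_norm = unname(minmax_normalize(mean_abs)),
    gain_norm = unname(minmax_normalize(gain[names(mean_abs)])),
    rank_shap = match(names(mean_abs), rank_shap),
    rank_gain = match(names(mean_abs), rank_gain),
    stringsAsFactors = FALSE)
  hetero <- NULL
  if (identical(model$family, "maccs") ||
      all(grepl("^MACCS\\d+$", names(mean_abs)))) {
    top50 <- rank_shap[seq_len(min(50, length(rank_shap)))]
    hetero <- heteroatom_fraction(top50)
  }
  structure(list(per_feature = per_feature, consensus = consensus,
                 directional = directional_summary(sh, x),
                 heteroatom_top50 = hetero, class = sh$class),
            class = "attribution_report")
}

#' @method print attribution_report
#' @export
print.attribution_report <- function(x, n = 10, ...) {
  cat("attribution_report (class:", x$class, ")\n")
  top <- x$per_feature[order(x$per_feature$rank_shap), ][seq_len(n), ]
  print(top[, c("feature", "mean_abs_shap", "gain", "rank_shap", "rank_gain")],
        row.names = FALSE)
  for (nm in names(x$consensus))
    cat(nm, "consensus:", length(x$consensus[[nm]]), "features\n")
  if (!is.null(x$heteroatom_top50))
    cat(sprintf("heteroatom fraction of SHAP top-50: %.2f\n",
                as.numeric(x$heteroatom_top50)))
  invisible(x)
}
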