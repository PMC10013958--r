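#' Configuration of the four-level cascade
#'
#' Each level may use its own feature family and algorithm; defaults follow
#' the best-performing combinations of the model comparison: ECFP4 with
#' ridge logistic regression for probe-vs-compound, MACCS with leaf-wise
#' gradient boosting for the two organelle levels, and the 2D descriptor set
#' with gradient boosting for colocalization quality.
#'
#' @param families named character vector (\code{b_pvsc}, \code{b_mvsp},
#'   \code{m_pvsp}, \code{b_mcol}) of feature families.
#' @param algorithms named character vector of algorithm names per level.
#' @param nbits folded ECFP4 width.
#' @param smote_mcol balance the colocalization table with SMOTE before
#'   fitting.
#' @return list of class \code{cascade_config}.
#' @export
cascade_config <- function(families = c(b_pvsc = "ecfp4", b_mvsp = "maccs",
                                        m_pvsp = "maccs", b_mcol = "2d"),
                           algorithms = c(b_pvsc = "logistic_regression",
                                          b_mvsp = "lightgbm",
                                          m_pvsp = "lightgbm",
                                          b_mcol = "lightgbm"),
                           nbits = 1024, smote_mcol = TRUE) {
  stopifnot(all(TASKS %in% names(families)), all(TASKS %in% names(algorithms)))
  structure(list(families = families[TASKS], algorithms = algorithms[TASKS],
                 nbits = nbits, smote_mcol = smote_mcol),
            class = "cascade_config")
}

featurize_cached <- function(smiles, family, nbits, cache) {
  key <- family
  if (is.null(cache[[key]])) {
    cache[[key]] <- featurize(stats::setNames(smiles, smiles), family = family,
                              nbits = nbits)
  } else {
    missing <- setdiff(smiles, rownames(cache[[key]]))
    if (length(missing))
      cache[[key]] <- rbind(cache[[key]],
                            featurize(stats::setNames(missing, missing),
                                      family = family, nbits = nbits))
  }
  out <- cache[[key]][intersect(smiles, rownames(cache[[key]])), , drop = FALSE]
  attr(out, "family") <- family
  out
}

#' Fit the multilevel organelle-targeting cascade
#'
#' Trains the four models of the framework on a curated molecule set: the
#' probe-vs-compound gate, the mitochondria-vs-other binary, the
#' six-organelle multiclass, and the colocalization-quality model. Each level
#' is fitted on its full task table (the cascade is the deployment object;
#' use \code{\link{grid_compare}} for protocolized evaluation). The
#' colocalization level optionally balances its classes with
#' \code{\link{smote}}, and 2D descriptor matrices pass through the
#' variance/correlation selection pipeline whose state is stored for
#' prediction.
#'
#' @param x a keyed, deduplicated \code{molecule_set}.
#' @param config a \code{\link{cascade_config}}.
#' @param seed integer seed.
#' @param coloc_threshold,dyes forwarded to the colocalization labeling.
#' @return object of class \code{probe_cascade}.
#' @export
fit_cascade <- function(x, config = cascade_config(), seed = 1,
                        coloc_threshold = 0.8, dyes = MITOTRACKER_DYES) {
  stopifnot(inherits(x, "molecule_set"), inherits(config, "cascade_config"))
  tabs <- build_task_tables(x, coloc_threshold = coloc_threshold, dyes = dyes)
  cache <- new.env(parent = emptyenv())
  models <- list(); selections <- list()
  for (task in TASKS) {
    tab <- tabs[[task]]
    if (nrow(tab) < 4 || length(unique(tab$label)) < 2)
      stopf("task table '%s' is too small to fit (%d rows, %d classes)",
            task, nrow(tab), length(unique(tab$label)))
    fam <- config$families[[task]]
    X <- featurize_cached(tab$smiles, fam, config$nbits, cache)
    X <- X[tab$smiles, , drop = FALSE]
    y <- tab$label
    if (identical(fam, "2d")) {
      sel <- select_features(X)
      selections[[task]] <- sel
      X <- sel$matrix
      attr(X, "family") <- "2d"
    }
    if (task == "b_mcol" && config$smote_mcol && length(unique(y)) == 2) {
      bal <- smote(X, y, k = 5, seed = seed)
      fam_attr <- attr(X, "family")
      X <- bal$x; y <- bal$y
      attr(X, "family") <- fam_attr
    }
    models[[task]] <- train_classifier(X, y, config$algorithms[[task]], seed = seed)
  }
  structure(list(models = models, config = config, selections = selections,
                 seed = seed,
                 n_task = vapply(tabs[TASKS], nrow, 0L),
                 coloc_threshold = coloc_threshold, dyes = dyes),
            class = "probe_cascade")
}

#' @method print probe_cascade
#' @export
print.probe_cascade <- function(x, ...) {
  cat("probe_cascade (4 levels, seed", paste0(x$seed, "):\n"))
  for (task in TASKS) {
    m <- x$models[[task]]
    cat(sprintf("  %-7s %-20s %-6s n=%d classes=[%s]\n", task, m$algorithm,
                x$config$families[[task]], x$n_task[[task]],
                paste(m$classes, collapse = ", ")))
  }
  invisible(x)
}

#' @method summary probe_cascade
#' @export
summary.probe_cascade <- function(object, ...) {
  print(object)
  cat("level gating: np_compound terminates at level 1; levels 2 and 3 run\n")
  cat("for every predicted probe; level 4 runs only for level-3 mitochondria.\n")
  invisible(object)
}

#' Run molecules through the fitted cascade
#'
#' Level 1 is always evaluated. For every molecule predicted \code{probe},
#' levels 2 and 3 are both evaluated -- the multiclass level re-examines
#' molecules the binary level called \code{other}, and a conflict between the
#' two verdicts is reported in the \code{disagreement} flag, never silently
#' resolved. Level 4 (colocalization quality) is evaluated exactly when the
#' level-3 verdict is mitochondria. With \code{consensus = TRUE} molecules
#' whose level-3 mitochondria probability is below 0.5 despite winning the
#' argmax are additionally marked \code{"uncertain"}.
#'
#' @param object a \code{probe_cascade}.
#' @param newdata character vector of SMILES (optionally named), or a
#'   \code{molecule_set}.
#' @param consensus add the \code{"uncertain"} qualifier described above.
#' @param sets optional character vector tagging each molecule with a design
#'   set (used by \code{\link{cascade_flow}}).
#' @param ... unused.
#' @return data frame of class \code{cascade_result}: per-level labels and
#'   probabilities, disagreement flag and terminal category; rejected
#'   (unparsable) molecules are reported in the \code{rejects} attribute.
#' @export
predict.probe_cascade <- function(object, newdata, consensus = FALSE,
                                  sets = NULL, ...) {
  if (inherits(newdata, "molecule_set")) {
    smiles <- ifelse(is.na(newdata$molecules$canonical_smiles),
                     newdata$molecules$smiles, newdata$molecules$canonical_smiles)
    ids <- newdata$molecules$id
    if (is.null(sets)) sets <- newdata$molecules$set
  } else {
    smiles <- as.character(newdata)
    ids <- names(newdata) %||% smiles
  }
  if (is.null(sets)) sets <- rep(NA_character_, length(smiles))

  parsed <- ob_valid(smiles)
  rejects <- data.frame(id = ids[!parsed], smiles = smiles[!parsed],
                        reason = rep("unparsable SMILES", sum(!parsed)),
                        stringsAsFactors = FALSE)
  smiles <- smiles[parsed]; ids <- ids[parsed]; sets <- sets[parsed]
  n <- length(smiles)
  cache <- new.env(parent = emptyenv())

  level_X <- function(task, rows) {
    fam <- object$config$families[[task]]
    X <- featurize_cached(smiles[rows], fam, object$config$nbits, cache)
    X <- X[smiles[rows], , drop = FALSE]
    if (!is.null(object$selections[[task]]))
      X <- apply_selection(object$selections[[task]], X)
    X
  }

  out <- data.frame(id = ids, smiles = smiles, set = sets,
                    l1_label = NA_character_, l1_p_probe = NA_real_,
                    l2_label = NA_character_, l2_p_mito = NA_real_,
                    l3_label = NA_character_, l3_p_max = NA_real_,
                    l3_p_mito = NA_real_,
                    l4_label = NA_character_, l4_p_good = NA_real_,
                    disagreement = FALSE, terminal = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0) {
    attr(out, "rejects") <- rejects
    class(out) <- c("cascade_result", "data.frame")
    return(out)
  }

  p1 <- predict(object$models$b_pvsc, level_X("b_pvsc", seq_len(n)), type = "prob")
  out$l1_p_probe <- p1[, "probe"]
  out$l1_label <- object$models$b_pvsc$classes[apply(p1, 1, which.max)]

  probe_rows <- which(out$l1_label == "probe")
  if (length(probe_rows)) {
    p2 <- predict(object$models$b_mvsp, level_X("b_mvsp", probe_rows), type = "prob")
    out$l2_p_mito[probe_rows] <- p2[, "mitochondria"]
    out$l2_label[probe_rows] <- object$models$b_mvsp$classes[apply(p2, 1, which.max)]

    p3 <- predict(object$models$m_pvsp, level_X("m_pvsp", probe_rows), type = "prob")
    out$l3_label[probe_rows] <- object$models$m_pvsp$classes[apply(p3, 1, which.max)]
    out$l3_p_max[probe_rows] <- apply(p3, 1, max)
    if ("mitochondria" %in% colnames(p3))
      out$l3_p_mito[probe_rows] <- p3[, "mitochondria"]

    l2_mito <- out$l2_label[probe_rows] == "mitochondria"
    l3_mito <- out$l3_label[probe_rows] == "mitochondria"
    out$disagreement[probe_rows] <- l2_mito != l3_mito

    mito_rows <- probe_rows[l3_mito]
    if (length(mito_rows)) {
      p4 <- predict(object$models$b_mcol, level_X("b_mcol", mito_rows), type = "prob")
      out$l4_p_good[mito_rows] <- p4[, "good"]
      out$l4_label[mito_rows] <- object$models$b_mcol$classes[apply(p4, 1, which.max)]
    }
  }

  out$terminal <- ifelse(out$l1_label == "np_compound", "np_compound",
                  ifelse(out$l3_label != "mitochondria", paste0("probe/", out$l3_label),
                         paste0("mitochondria/", out$l4_label)))
  if (consensus) {
    unc <- !is.na(out$l3_label) & out$l3_label == "mitochondria" &
      !is.na(out$l3_p_mito) & out$l3_p_mito < 0.5
    out$terminal[unc] <- paste0(out$terminal[unc], "/uncertain")
  }
  attr(out, "rejects") <- rejects
  class(out) <- c("cascade_result", "data.frame")
  out
}

#' Level-to-level flow accounting (Sankey table)
#'
#' Counts every level-to-level transition per design set: the set node into
#' the level-1 verdict, level-1 probes into the level-2 verdict, level 2 into
#' level 3, and level-3 mitochondria into the level-4 verdict. Counts are
#' conserved at every level: a node's inbound count equals its outbound plus
#' terminal count.
#'
#' @param results a \code{cascade_result} from \code{predict.probe_cascade}.
#' @return data frame (\code{set}, \code{level}, \code{from}, \code{to},
#'   \code{count}) suitable for Sankey plotting.
#' @export
cascade_flow <- function(results) {
  stopifnot(inherits(results, "cascade_result"))
  r <- results
  r$set[is.na(r$set)] <- "all"
  edges <- list()
  add <- function(set, level, from, to) {
    t <- table(from, to)
    for (i in seq_len(nrow(t))) for (j in seq_len(ncol(t)))
      if (t[i, j] > 0)
        edges[[length(edges) + 1]] <<- data.frame(
          set = set, level = level, from = rownames(t)[i], to = colnames(t)[j],
          count = as.integer(t[i, j]), stringsAsFactors = FALSE)
  }
  for (s in unique(r$set)) {
    ri <- r[r$set == s, , drop = FALSE]
    add(s, 1L, rep(s, nrow(ri)), ri$l1_label)
    probe <- ri[ri$l1_label == "probe", , drop = FALSE]
    if (nrow(probe)) {
      add(s, 2L, paste0("L1:", probe$l1_label), paste0("L2:", probe$l2_label))
      add(s, 3L, paste0("L2:", probe$l2_label), paste0("L3:", probe$l3_label))
      mito <- probe[probe$l3_label == "mitochondria", , drop = FALSE]
      if (nrow(mito))
        add(s, 4L, paste0("L3:", mito$l3_label), paste0("L4:", mito$l4_label))
    }
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
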