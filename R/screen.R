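#' Define a screening rule on a molecular property
#'
#' @param property property (column) name, e.g. \code{"toxicity"},
#'   \code{"synthetic_accessibility"}, \code{"logp"}.
#' @param direction \code{"max_allowed"} (value must not exceed the bound),
#'   \code{"min_allowed"} (must not fall below it) or \code{"range"}
#'   (two bounds, low < high).
#' @param bound numeric bound (length 2 for \code{"range"}).
#' @param rationale free-text justification carried into reports.
#' @return object of class \code{screening_rule}.
#' @export
screening_rule <- function(property, direction = c("max_allowed", "min_allowed", "range"),
                           bound, rationale = "") {
  direction <- match.arg(direction)
  if (direction == "range") {
    if (length(bound) != 2 || bound[1] >= bound[2])
      stopf("range rule needs bounds low < high")
  } else if (length(bound) != 1) {
    stopf("%s rule needs a single bound", direction)
  }
  structure(list(property = property, direction = direction,
                 bound = bound, rationale = rationale),
            class = "screening_rule")
}

#' Default candidate-screening rules
#'
#' Configuration defaults, not literature claims: toxicity probability at
#' most 0.3, synthetic accessibility at most 6 (on the 1 = easy to 10 = hard
#' scale), logP between 1 and 6 (lipophilic enough to cross membranes, short
#' of grease).
#' @return list of \code{screening_rule}s.
#' @export
default_rules <- function() {
  list(screening_rule("toxicity", "max_allowed", 0.3,
                      "probability of high acute toxicity"),
       screening_rule("synthetic_accessibility", "max_allowed", 6,
                      "tractable synthesis"),
       screening_rule("logp", "range", c(1, 6),
                      "lipophilicity window for membrane permeation"))
}

#' Load an ADMET-style property table
#'
#' Reads a CSV (or accepts a data frame) keyed by molecule with numeric
#' property columns. Toxicity probabilities outside [0, 1] and synthetic
#' accessibility outside [1, 10] are rejected row-wise with a reason, as are
#' non-numeric property values.
#'
#' @param x path to a CSV or a data frame. The key column defaults to
#'   \code{inchikey}, falling back to \code{id}.
#' @param key name of the key column.
#' @return data frame of valid rows keyed by \code{key}; rejected rows are
#'   reported in the \code{rejects} attribute.
#' @export
load_property_table <- function(x, key = NULL) {
  tab <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  key <- key %||% intersect(c("inchikey", "id"), names(tab))[1]
  if (is.na(key) || !key %in% names(tab))
    stopf("property table needs a key column ('inchikey' or 'id')")
  prop_cols <- setdiff(names(tab), key)
  reasons <- character(nrow(tab))
  for (cn in prop_cols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad_num <- !is.na(tab[[cn]]) & is.na(v)
    reasons[bad_num & reasons == ""] <- sprintf("non-numeric %s", cn)
    tab[[cn]] <- v
  }
  if ("toxicity" %in% prop_cols) {
    bad <- !is.na(tab$toxicity) & (tab$toxicity < 0 | tab$toxicity > 1)
    reasons[bad & reasons == ""] <- "toxicity outside [0, 1]"
  }
  if ("synthetic_accessibility" %in% prop_cols) {
    bad <- !is.na(tab$synthetic_accessibility) &
      (tab$synthetic_accessibility < 1 | tab$synthetic_accessibility > 10)
    reasons[bad & reasons == ""] <- "synthetic accessibility outside [1, 10]"
  }
  ok <- reasons == ""
  rejects <- data.frame(key = tab[[key]][!ok], reason = reasons[!ok],
                        stringsAsFactors = FALSE)
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "key") <- key
  attr(out, "rejects") <- rejects
  out
}

rule_pass <- function(rule, values) {
  switch(rule$direction,
         max_allowed = values <= rule$bound,
         min_allowed = values >= rule$bound,
         range = values >= rule$bound[1] & values <= rule$bound[2])
}

#' Screen cascade candidates on precomputed properties
#'
#' Restricts to molecules whose cascade terminal is
#' \code{"mitochondria/good"}, evaluates every rule against the property
#' table, and ranks the passing shortlist lexicographically by (ascending
#' toxicity, ascending synthetic accessibility, descending logP). Each
#' reported row carries a pass/fail flag per rule; a missing property value
#' fails the rule. Molecules named in \code{keep} are retained on the
#' shortlist regardless of rule outcomes (flags still reported), supporting
#' the judgment call a chemist may make against the automated ranking.
#'
#' @param results a \code{cascade_result}.
#' @param properties table from \code{\link{load_property_table}}.
#' @param rules list of \code{\link{screening_rule}}s; an empty list
#'   passes all candidates through with a warning.
#' @param keep character vector of molecule keys to retain regardless.
#' @return object of class \code{screening_report}: list with
#'   \code{shortlist}, \code{candidates} (all cascade-passing rows with
#'   flags) and \code{rules}.
#' @export
screen_candidates <- function(results, properties, rules = default_rules(),
                              keep = character()) {
  stopifnot(inherits(results, "cascade_result"))
  key <- attr(properties, "key") %||% "inchikey"
  cand <- results[!is.na(results$terminal) &
                    results$terminal == "mitochondria/good", , drop = FALSE]
  merge_key <- if (key %in% names(cand)) key else "id"
  cand <- merge(cand, properties, by.x = merge_key, by.y = key,
                all.x = TRUE, sort = FALSE)
  missing_key <- setdiff(properties[[key]], results[[merge_key]])
  if (length(missing_key))
    warnf("%d property rows have no cascade result", length(missing_key))

  if (!length(rules)) {
    warnf("empty rule set: passing all cascade candidates through")
    pass_all <- rep(TRUE, nrow(cand))
  } else {
    need <- vapply(rules, `[[`, "", "property")
    absent <- setdiff(need, names(cand))
    if (length(absent))
      stopf("property column(s) missing for active rule(s): %s",
            paste(absent, collapse = ", "))
    flags <- vapply(rules, function(rl) {
      p <- rule_pass(rl, cand[[rl$property]])
      p & !is.na(p)
    }, logical(nrow(cand)))
    if (is.vector(flags)) flags <- matrix(flags, nrow = nrow(cand))
    colnames(flags) <- vapply(rules, function(rl)
      paste0("pass_", rl$property), "")
    cand <- cbind(cand, flags)
    pass_all <- rowSums(!flags) == 0
  }
  cand$pass_all <- pass_all
  short <- cand[pass_all | cand[[merge_key]] %in% keep, , drop = FALSE]
  ord <- order(if ("toxicity" %in% names(short)) short$toxicity else rep(0, nrow(short)),
               if ("synthetic_accessibility" %in% names(short))
                 short$synthetic_accessibility else rep(0, nrow(short)),
               -(if ("logp" %in% names(short)) short$logp else rep(0, nrow(short))))
  short <- short[ord, , drop = FALSE]
  rownames(short) <- NULL
  structure(list(shortlist = short, candidates = cand, rules = rules,
                 keep = keep),
            class = "screening_report")
}

#' @method print screening_report
#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report:", nrow(x$candidates), "cascade-passing candidates,",
      nrow(x$shortlist), "on the shortlist\n")
  for (rl in x$rules)
    cat(sprintf("  rule: %s %s %s\n", rl$property, rl$direction,
                paste(rl$bound, collapse = "..")))
  invisible(x)
}

#' Quantile summary of a property table
#'
#' @param properties property table.
#' @param probs quantile probabilities.
#' @return matrix of quantiles (type 7), one row per numeric property.
#' @export
property_summary <- function(properties, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  num <- names(properties)[vapply(properties, is.numeric, TRUE)]
  t(vapply(num, function(cn)
    stats::quantile(properties[[cn]], probs = probs, na.rm = TRUE, type = 7),
    numeric(length(probs))))
}
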