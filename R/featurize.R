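FP_FAMILIES <- c("maccs", "ecfp4", "2d")

# cache for the parsed MACCS key table
.orgprobe_env <- new.env(parent = emptyenv())

#' MACCS key definition table
#'
#' Parses the 166 public MACCS key definitions from the SMARTS table that
#' OpenBabel itself matches against (shipped with ChemmineOB), so key numbers
#' in feature names always agree with the bits the featurizer sets. Each key
#' is annotated with the elements its SMARTS mentions and with charge /
#' disconnection flags used by \code{\link{heteroatom_fraction}}. Keys 125
#' (more than one aromatic ring) and 166 (disconnected fragments) are counting
#' keys with no SMARTS pattern; the featurizer computes them from ring
#' perception and fragment count directly.
#'
#' @return data frame with columns \code{key}, \code{name}, \code{smarts},
#'   \code{description}, \code{has_N}, \code{has_O}, \code{has_P},
#'   \code{is_charge}, \code{is_disconnection}, \code{supported}.
#' @export
maccs_keys <- function() {
  if (!is.null(.orgprobe_env$maccs_table)) return(.orgprobe_env$maccs_table)
  path <- system.file("openbabel_data", "MACCS.txt", package = "ChemmineOB")
  if (!nzchar(path) || !file.exists(path))
    stopf("MACCS definition table not found in ChemmineOB installation")
  lines <- readLines(path, warn = FALSE)
  pat <- "^\\s*(\\d+):\\('(.*)',(\\d+)\\),?\\s*(#\\s*(.*))?$"
  hit <- grepl(pat, lines)
  key <- as.integer(sub(pat, "\\1", lines[hit]))
  smarts <- sub(pat, "\\2", lines[hit])
  desc <- trimws(sub(pat, "\\5", lines[hit]))
  tab <- data.frame(key = 1:166, name = paste0("MACCS", 1:166),
                    smarts = NA_character_, description = NA_character_,
                    stringsAsFactors = FALSE)
  ok <- key >= 1 & key <= 166
  tab$smarts[key[ok]] <- smarts[ok]
  tab$description[key[ok]] <- desc[ok]
  tab$supported <- !is.na(tab$smarts) & tab$smarts != "?"
  # element mentions: scan SMARTS with two-letter symbols removed first
  scan <- gsub("Cl|Br|Se|Si|Sn|Li|Na|Ca|Mg|Al", "", ifelse(tab$supported, tab$smarts, ""))
  tab$has_N <- grepl("N|n|#7", scan)
  tab$has_O <- grepl("O|o|#8", scan)
  tab$has_P <- grepl("P|p|#15", scan)
  tab$is_charge <- grepl("\\+|-\\]|;-|,-", scan) & tab$supported
  tab$is_disconnection <- tab$key == 166L
  tab$description[tab$key == 125L] <- "Aromatic Ring > 1"
  tab$description[tab$key == 166L] <- "Fragments (disconnected structure)"
  .orgprobe_env$maccs_table <- tab
  tab
}

# aromatic ring count (5- and 6-membered, the sizes aromaticity perception
# assigns here) via unique SMARTS matches; called with a live handle
ob_aromatic_rings <- function(mol) {
  as.integer(ChemmineOB::smartsSearch_OB(list(mol), "a1aaaaa1", uniqueMatches = TRUE) +
             ChemmineOB::smartsSearch_OB(list(mol), "a1aaaa1", uniqueMatches = TRUE))
}

#' Compute a feature matrix for a set of molecules
#'
#' Supported families: \code{"maccs"} (the 166 public MACCS substructure
#' keys, named \code{MACCS1}..\code{MACCS166}), \code{"ecfp4"} (circular
#' Morgan fingerprint of radius 2, folded to \code{nbits} bits) and
#' \code{"2d"} (the open physicochemical/topological descriptor set of
#' \code{\link{descriptors_2d}}). Fingerprint bits are computed by OpenBabel
#' SMARTS matching; the two MACCS counting keys without SMARTS patterns are
#' filled in directly (key 125 from aromatic SSSR ring count, key 166 from
#' the number of disconnected fragments). Deterministic: the same SMILES
#' always yields the same row.
#'
#' @param smiles character vector of SMILES; names (or the SMILES themselves)
#'   become row names.
#' @param family feature family.
#' @param nbits width of the folded ECFP4 fingerprint.
#' @return numeric matrix with attribute \code{family}; unparsable SMILES are
#'   dropped and reported in the \code{rejects} attribute.
#' @export
featurize <- function(smiles, family = c("maccs", "ecfp4", "2d"), nbits = 1024) {
  family <- match.arg(family, choices = c(FP_FAMILIES, "atompair", "pubchem", "cdk"))
  if (family %in% c("atompair", "pubchem", "cdk"))
    stopf("fingerprint family '%s' has no backend in this installation; supported: %s",
          family, paste(FP_FAMILIES, collapse = ", "))
  ids <- names(smiles) %||% smiles
  ok <- ob_valid(smiles)
  rejects <- data.frame(id = ids[!ok], smiles = smiles[!ok],
                        reason = rep("unparsable SMILES", sum(!ok)),
                        stringsAsFactors = FALSE)
  smiles <- unname(smiles[ok]); ids <- ids[ok]
  if (!length(smiles)) {
    out <- matrix(numeric(0), nrow = 0,
                  ncol = switch(family, maccs = 166, ecfp4 = nbits, `2d` = length(DESC_NAMES)))
    colnames(out) <- switch(family, maccs = paste0("MACCS", 1:166),
                            ecfp4 = sprintf("ECFP4_%04d", seq_len(nbits) - 1L),
                            `2d` = DESC_NAMES)
    attr(out, "family") <- family; attr(out, "rejects") <- rejects
    return(out)
  }

  if (family == "maccs") {
    rows <- ob_batch(smiles, function(mol) {
      fp <- ChemmineOB::fingerprint_OB(list(mol), "MACCS")
      if (is.matrix(fp)) fp <- fp[1, ]
      c(fp[1:166], arom = ob_aromatic_rings(mol))
    })
    out <- do.call(rbind, rows)
    arom <- out[, 167]
    out <- out[, 1:166, drop = FALSE]
    out[, 125] <- as.numeric(arom > 1)
    out[, 166] <- as.numeric(smiles_fragments(smiles) > 1L)
    colnames(out) <- paste0("MACCS", 1:166)
  } else if (family == "ecfp4") {
    rows <- ob_batch(smiles, function(mol) {
      fp <- ChemmineOB::fingerprint_OB(list(mol), "ECFP4")
      if (is.matrix(fp)) fp[1, ] else fp
    })
    fp <- do.call(rbind, rows)
    fold <- (seq_len(ncol(fp)) - 1L) %% nbits
    out <- matrix(0, nrow(fp), nbits)
    for (j in seq_len(ncol(fp))) {
      tgt <- fold[j] + 1L
      out[, tgt] <- pmax(out[, tgt], fp[, j])
    }
    colnames(out) <- sprintf("ECFP4_%04d", seq_len(nbits) - 1L)
  } else {
    i <- 0L
    rows <- ob_batch(smiles, function(mol) {
      i <<- i + 1L
      descriptor_row(mol, smiles[i])
    })
    out <- do.call(rbind, rows)
    colnames(out) <- DESC_NAMES
  }
  rownames(out) <- ids
  storage.mode(out) <- "double"
  attr(out, "family") <- family
  attr(out, "rejects") <- rejects
  out
}

# ---- open 2D descriptor set ------------------------------------------------

DESC_NAMES <- c(
  "mol_weight", "slogp", "tpsa", "molar_refractivity", "hbd", "hba",
  "n_atoms_heavy", "n_bonds", "n_carbon", "n_nitrogen", "n_oxygen",
  "n_phosphorus", "n_sulfur", "n_halogen", "n_hetero", "frac_hetero",
  "total_formal_charge", "n_pos_atoms", "n_neg_atoms", "abs_charge_sum",
  "n_fragments", "n_rings", "n_aromatic_rings",
  "frac_aromatic_atoms", "n_sp3_carbon", "frac_csp3", "n_rotatable_bonds",
  "n_double_bonds", "n_triple_bonds", "wiener_index", "zagreb_m1",
  "zagreb_m2", "randic_index", "graph_diameter", "graph_radius",
  "mean_distance", "eccentric_connectivity", "graph_density",
  "n_methyl", "n_amine_basic", "n_carbonyl")

# single-molecule descriptor vector; NAs recorded on failure and handled by
# select_features() cleaning downstream
descriptor_row <- function(mol, smi) {
  out <- stats::setNames(rep(NA_real_, length(DESC_NAMES)), DESC_NAMES)
  res <- try({
    props <- ChemmineOB::prop_OB(list(mol))
    natoms <- ob_api("OBMol_NumHvyAtoms")(mol)
    atoms <- lapply(seq_len(ob_api("OBMol_NumAtoms")(mol)),
                    function(i) ob_api("OBMol_GetAtom")(mol, i))
    z <- vapply(atoms, function(a) ob_api("OBAtom_GetAtomicNum")(a), 0L)
    heavy <- z > 1
    atoms <- atoms[heavy]; z <- z[heavy]
    chg <- vapply(atoms, function(a) ob_api("OBAtom_GetFormalCharge")(a), 0L)
    arom <- vapply(atoms, function(a) isTRUE(ob_api("OBAtom_IsAromatic")(a)), TRUE)
    hyb <- vapply(atoms, function(a) ob_api("OBAtom_GetHyb")(a), 0L)

    out["mol_weight"] <- props$MW
    out["slogp"] <- props$logP
    out["tpsa"] <- props$TPSA
    out["molar_refractivity"] <- props$MR
    out["hbd"] <- props$HBD
    out["hba"] <- props$HBA2
    out["n_atoms_heavy"] <- natoms
    out["n_carbon"] <- sum(z == 6)
    out["n_nitrogen"] <- sum(z == 7)
    out["n_oxygen"] <- sum(z == 8)
    out["n_phosphorus"] <- sum(z == 15)
    out["n_sulfur"] <- sum(z == 16)
    out["n_halogen"] <- sum(z %in% c(9, 17, 35, 53))
    out["n_hetero"] <- sum(z != 6)
    out["frac_hetero"] <- if (natoms > 0) sum(z != 6) / natoms else 0
    out["total_formal_charge"] <- sum(chg)
    out["n_pos_atoms"] <- sum(chg > 0)
    out["n_neg_atoms"] <- sum(chg < 0)
    out["abs_charge_sum"] <- sum(abs(chg))
    nfrag <- smiles_fragments(smi)
    out["n_fragments"] <- nfrag
    out["n_aromatic_rings"] <- ob_aromatic_rings(mol)
    out["frac_aromatic_atoms"] <- if (natoms > 0) sum(arom) / natoms else 0
    out["n_sp3_carbon"] <- sum(z == 6 & hyb == 3)
    out["frac_csp3"] <- if (sum(z == 6) > 0) sum(z == 6 & hyb == 3) / sum(z == 6) else 0
    out["n_rotatable_bonds"] <-
      ChemmineOB::smartsSearch_OB(list(mol), "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]")
    out["n_methyl"] <- ChemmineOB::smartsSearch_OB(list(mol), "[CH3]")
    out["n_amine_basic"] <- ChemmineOB::smartsSearch_OB(list(mol), "[NX3;!$(N=*);!$(NC=O)]")
    out["n_carbonyl"] <- ChemmineOB::smartsSearch_OB(list(mol), "[CX3]=[OX1]")

    # heavy-atom graph topology
    nb <- ob_api("OBMol_NumBonds")(mol)
    edges <- if (nb > 0) {
      el <- vapply(seq_len(nb) - 1L, function(i) {
        b <- ob_api("OBMol_GetBond")(mol, i)
        c(ob_api("OBBond_GetBeginAtomIdx")(b), ob_api("OBBond_GetEndAtomIdx")(b),
          ob_api("OBBond_GetBondOrder")(b))
      }, numeric(3))
      t(el)
    } else matrix(numeric(0), 0, 3)
    out["n_bonds"] <- nrow(edges)
    out["n_rings"] <- max(0, nrow(edges) - natoms + nfrag)  # cyclomatic number
    out["n_double_bonds"] <- sum(edges[, 3] == 2)
    out["n_triple_bonds"] <- sum(edges[, 3] == 3)
    if (natoms >= 2 && nrow(edges)) {
      g <- igraph::graph_from_edgelist(cbind(edges[, 1], edges[, 2]), directed = FALSE)
      deg <- igraph::degree(g)
      dm <- igraph::distances(g)
      fin <- is.finite(dm) & dm > 0
      out["wiener_index"] <- sum(dm[fin]) / 2
      out["zagreb_m1"] <- sum(deg^2)
      out["zagreb_m2"] <- sum(deg[edges[, 1]] * deg[edges[, 2]])
      out["randic_index"] <- sum(1 / sqrt(deg[edges[, 1]] * deg[edges[, 2]]))
      ecc <- apply(dm, 1, function(r) max(r[is.finite(r)]))
      out["graph_diameter"] <- max(ecc)
      out["graph_radius"] <- min(ecc)
      out["mean_distance"] <- mean(dm[fin])
      out["eccentric_connectivity"] <- sum(ecc * deg)
      out["graph_density"] <- nrow(edges) / choose(length(deg), 2)
    } else {
      out[c("wiener_index", "zagreb_m1", "zagreb_m2", "randic_index",
            "graph_diameter", "graph_radius", "mean_distance",
            "eccentric_connectivity", "graph_density")] <- 0
    }
    NULL
  }, silent = TRUE)
  out
}

#' Compute the open 2D descriptor set
#'
#' A compact, fully open replacement for commercial 2D descriptor packages:
#' OpenBabel physicochemical properties (logP, TPSA, molar refractivity,
#' hydrogen-bond counts), element and formal-charge composition, ring
#' statistics, and topological indices (Wiener, Zagreb, Randic, eccentric
#' connectivity) computed on the heavy-atom graph. Covers the descriptor
#' concept groups that matter for organelle targeting: charge, shape,
#' surface area and lipophilicity.
#'
#' @param smiles character vector of SMILES.
#' @return numeric matrix, one named row per parsable molecule.
#' @export
descriptors_2d <- function(smiles) featurize(smiles, family = "2d")

# ---- feature selection -----------------------------------------------------

#' Variance/correlation feature selection
#'
#' The cleaning pipeline applied to descriptor matrices before modelling:
#' (1) columns with more than \code{na_frac} missing values are dropped,
#' remaining missing values are median-imputed (medians are stored so the
#' same imputation applies to test data); (2) zero-variance columns are
#' dropped; (3) a greedy scan in column order drops any column whose absolute
#' Pearson correlation with an already-kept column exceeds \code{corr_cut}.
#' The procedure is deterministic and idempotent on its own output.
#'
#' @param x numeric feature matrix, n >= 2 rows.
#' @param corr_cut correlation threshold above which the later column of a
#'   pair is dropped.
#' @param na_frac maximum tolerated fraction of missing values per column.
#' @return object of class \code{feature_selection}: list with the reduced
#'   \code{matrix}, \code{kept} names, a \code{dropped} report (name, reason)
#'   and the imputation \code{medians}.
#' @export
select_features <- function(x, corr_cut = 0.95, na_frac = 0.10) {
  if (nrow(x) < 2) stopf("select_features() needs at least 2 rows (correlation undefined)")
  nm <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- nm
  dropped <- data.frame(name = character(), reason = character(),
                        stringsAsFactors = FALSE)

  na_share <- colMeans(is.na(x) | is.nan(x) | is.infinite(x))
  bad <- na_share > na_frac
  if (any(bad))
    dropped <- rbind(dropped, data.frame(name = nm[bad], reason = "missing values",
                                         stringsAsFactors = FALSE))
  x <- x[, !bad, drop = FALSE]
  x[!is.finite(x)] <- NA
  meds <- apply(x, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- meds[j]
  }

  v <- apply(x, 2, stats::var)
  zv <- v == 0 | is.na(v)
  if (any(zv))
    dropped <- rbind(dropped, data.frame(name = colnames(x)[zv],
                                         reason = "zero variance",
                                         stringsAsFactors = FALSE))
  x <- x[, !zv, drop = FALSE]

  keep <- logical(ncol(x))
  if (ncol(x)) {
    cm <- suppressWarnings(abs(stats::cor(x)))
    for (j in seq_len(ncol(x))) {
      anchors <- which(keep)
      if (!length(anchors) || all(cm[j, anchors] <= corr_cut, na.rm = TRUE)) {
        keep[j] <- TRUE
      } else {
        dropped <- rbind(dropped, data.frame(
          name = colnames(x)[j],
          reason = sprintf("|corr| > %.2f with %s", corr_cut,
                           colnames(x)[anchors[which(cm[j, anchors] > corr_cut)[1]]]),
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- x[, keep, drop = FALSE]
  structure(list(matrix = out, kept = colnames(out), dropped = dropped,
                 medians = meds, corr_cut = corr_cut, na_frac = na_frac,
                 family = attr(x, "family")),
            class = "feature_selection")
}

#' Apply a fitted feature selection to new data
#'
#' Restricts new rows to the kept columns and applies the stored training
#' medians to missing entries, so no information from the new data leaks into
#' the selection.
#' @param sel a \code{feature_selection}.
#' @param x new feature matrix with the original columns.
#' @return reduced matrix.
#' @export
apply_selection <- function(sel, x) {
  stopifnot(inherits(sel, "feature_selection"))
  missing_cols <- setdiff(sel$kept, colnames(x))
  if (length(missing_cols))
    stopf("new data lacks selected columns: %s", paste(missing_cols, collapse = ", "))
  x <- x[, sel$kept, drop = FALSE]
  for (j in colnames(x)) {
    miss <- !is.finite(x[, j])
    if (any(miss)) x[miss, j] <- sel$medians[[j]]
  }
  x
}

#' @method print feature_selection
#' @export
print.feature_selection <- function(x, ...) {
  cat("feature_selection:", length(x$kept), "kept,", nrow(x$dropped), "dropped",
      sprintf("(corr_cut = %.2f)\n", x$corr_cut))
  if (nrow(x$dropped)) print(table(reason = sub(" with.*$", "", x$dropped$reason)))
  invisible(x)
}
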