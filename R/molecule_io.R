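#' Organelle classes recognised by the package
#'
#' The six subcellular compartments a curated probe may be labeled with.
#' @export
ORGANELLES <- c("golgi", "endoplasmic_reticulum", "lysosome",
                "cell_membrane", "mitochondria", "nucleus")

#' Prediction tasks of the multilevel framework
#' @export
TASKS <- c("b_pvsc", "b_mvsp", "m_pvsp", "b_mcol")

#' Default colocalization dye filter (MitoTracker pair)
#' @export
MITOTRACKER_DYES <- c("MitoTracker Green", "MitoTracker Red")

#' Read a molecule table
#'
#' Reads molecules from CSV (columns \code{smiles} plus optional \code{role},
#' \code{organelle}, \code{coloc_dye}, \code{coloc_r}, \code{set}, \code{id}),
#' SMI (one SMILES per line, optional whitespace-separated id) or SDF. Every
#' input row is either parsed into a record or collected into the rejects
#' table with a reason -- rows are never silently dropped. A molecule with
#' several colocalization measurements appears on several CSV rows sharing the
#' same id/SMILES; the structure is recorded once and each measurement becomes
#' one row of the colocalization table.
#'
#' @param path file to read.
#' @param format one of \code{"csv"}, \code{"smi"}, \code{"sdf"} (default
#'   guessed from the file extension).
#' @return An object of class \code{molecule_set}: a list with elements
#'   \code{molecules} (data frame: id, smiles, canonical_smiles, inchikey,
#'   role, organelle, set), \code{coloc} (id, dye, r) and \code{rejects}
#'   (id, smiles, reason). \code{canonical_smiles}/\code{inchikey} are NA
#'   until \code{\link{standardize_and_key}} is applied.
#' @export
parse_molecules <- function(path, format = c("auto", "csv", "smi", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", smi = "smi", sdf = "sdf", "csv")
  }
  if (!file.exists(path)) stopf("input file not found: %s", path)

  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(raw)) stopf("CSV is missing the mandatory 'smiles' column")
    n <- nrow(raw)
    id <- if ("id" %in% names(raw)) as.character(raw$id) else sprintf("mol%05d", seq_len(n))
    df <- data.frame(
      id = id,
      smiles = as.character(raw$smiles),
      role = if ("role" %in% names(raw)) as.character(raw$role)
             else rep(NA_character_, n),
      organelle = if ("organelle" %in% names(raw)) as.character(raw$organelle)
                  else rep(NA_character_, n),
      set = if ("set" %in% names(raw)) as.character(raw$set)
            else rep(NA_character_, n),
      stringsAsFactors = FALSE)
    coloc <- data.frame(id = character(), dye = character(), r = numeric(),
                        stringsAsFactors = FALSE)
    if (all(c("coloc_dye", "coloc_r") %in% names(raw))) {
      has_r <- !is.na(raw$coloc_r) & nzchar(as.character(raw$coloc_dye) %||% "")
      coloc <- data.frame(id = id[has_r],
                          dye = as.character(raw$coloc_dye)[has_r],
                          r = as.numeric(raw$coloc_r)[has_r],
                          stringsAsFactors = FALSE)
    }
    # collapse repeated rows of the same molecule (multi-record input)
    first <- !duplicated(df$id)
    mols <- df[first, , drop = FALSE]
  } else if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    mols <- data.frame(
      id = vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("mol%05d", i), ""),
      smiles = vapply(parts, `[[`, "", 1),
      role = NA_character_, organelle = NA_character_, set = NA_character_,
      stringsAsFactors = FALSE)
    coloc <- data.frame(id = character(), dye = character(), r = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    mols <- data.frame(
      id = ChemmineR::sdfid(sdf), smiles = smi,
      role = NA_character_, organelle = NA_character_, set = NA_character_,
      stringsAsFactors = FALSE)
    coloc <- data.frame(id = character(), dye = character(), r = numeric(),
                        stringsAsFactors = FALSE)
  }

  ok <- ob_valid(mols$smiles)
  rejects <- data.frame(id = mols$id[!ok], smiles = mols$smiles[!ok],
                        reason = rep("unparsable SMILES", sum(!ok)), stringsAsFactors = FALSE)
  mols <- mols[ok, , drop = FALSE]
  mols$canonical_smiles <- rep(NA_character_, nrow(mols))
  mols$inchikey <- rep(NA_character_, nrow(mols))
  coloc <- coloc[coloc$id %in% mols$id, , drop = FALSE]
  rownames(mols) <- NULL
  new_molecule_set(mols, coloc, rejects)
}

new_molecule_set <- function(molecules, coloc, rejects) {
  bad <- !is.na(molecules$organelle) & !(molecules$organelle %in% ORGANELLES)
  if (any(bad))
    stopf("unknown organelle label(s): %s",
          paste(unique(molecules$organelle[bad]), collapse = ", "))
  if (nrow(coloc) && any(coloc$r < -1 | coloc$r > 1))
    stopf("colocalization coefficients outside [-1, 1]: corrupt input")
  structure(list(molecules = molecules, coloc = coloc, rejects = rejects),
            class = "molecule_set")
}

#' @method print molecule_set
#' @export
print.molecule_set <- function(x, ...) {
  m <- x$molecules
  cat("molecule_set:", nrow(m), "molecules,", nrow(x$coloc),
      "colocalization records,", nrow(x$rejects), "rejects\n")
  if (nrow(m)) {
    keyed <- sum(!is.na(m$inchikey))
    cat("  keyed:", keyed, "/", nrow(m), "\n")
    if (any(!is.na(m$role)))
      print(table(role = m$role, useNA = "ifany"))
    if (any(!is.na(m$organelle)))
      print(table(organelle = m$organelle, useNA = "ifany"))
  }
  invisible(x)
}

#' Canonicalize structures and assign InChIKeys
#'
#' Canonical SMILES and the 27-character InChIKey are generated for every
#' record. All disconnected fragments (counterions of cationic dyes) are
#' retained: charge and disconnection carry targeting signal, so salts are
#' never stripped down to a parent fragment. Records whose InChI generation
#' fails move to the rejects table.
#'
#' @param x a \code{molecule_set} from \code{\link{parse_molecules}}, or a
#'   character vector of SMILES (returned as a keyed \code{molecule_set}).
#' @return the \code{molecule_set} with \code{canonical_smiles} and
#'   \code{inchikey} filled in.
#' @export
standardize_and_key <- function(x) {
  if (is.character(x)) {
    mols <- data.frame(id = names(x) %||% sprintf("mol%05d", seq_along(x)),
                       smiles = unname(x), role = NA_character_,
                       organelle = NA_character_, set = NA_character_,
                       canonical_smiles = NA_character_,
                       inchikey = NA_character_, stringsAsFactors = FALSE)
    x <- new_molecule_set(mols,
                          data.frame(id = character(), dye = character(),
                                     r = numeric(), stringsAsFactors = FALSE),
                          data.frame(id = character(), smiles = character(),
                                     reason = character(), stringsAsFactors = FALSE))
  }
  stopifnot(inherits(x, "molecule_set"))
  m <- x$molecules
  if (!nrow(m)) return(x)
  m$canonical_smiles <- ob_canonical(m$smiles)
  m$inchikey <- ob_inchikey(m$smiles)
  bad <- is.na(m$canonical_smiles) | is.na(m$inchikey)
  if (any(bad)) {
    x$rejects <- rbind(x$rejects,
                       data.frame(id = m$id[bad], smiles = m$smiles[bad],
                                  reason = "InChI/canonicalization failure",
                                  stringsAsFactors = FALSE))
    m <- m[!bad, , drop = FALSE]
  }
  rownames(m) <- NULL
  x$molecules <- m
  x$coloc <- x$coloc[x$coloc$id %in% m$id, , drop = FALSE]
  x
}

#' Remove duplicate structures within a label
#'
#' Within each category label (the role/organelle combination by default) only
#' the first occurrence of an InChIKey is kept; the same structure may still
#' appear under two different labels, which is deliberate -- a molecule
#' reported against two organelles is evidence for both classes. Deterministic
#' given input order, and idempotent.
#'
#' @param x a keyed \code{molecule_set}.
#' @param by label columns defining the dedup group.
#' @return the deduplicated \code{molecule_set}.
#' @export
deduplicate <- function(x, by = c("role", "organelle")) {
  stopifnot(inherits(x, "molecule_set"))
  m <- x$molecules
  if (!nrow(m)) return(x)
  if (any(is.na(m$inchikey)))
    stopf("deduplicate() requires keyed records; run standardize_and_key() first")
  grp <- do.call(paste, c(lapply(by, function(col) ifelse(is.na(m[[col]]), "<NA>", m[[col]])),
                          sep = "\r"))
  keep <- !duplicated(paste(grp, m$inchikey, sep = "\r"))
  x$molecules <- m[keep, , drop = FALSE]
  rownames(x$molecules) <- NULL
  x
}

#' Label mitochondrial colocalization quality
#'
#' Colocalization measurements are filtered to the requested dyes (the
#' MitoTracker Green/Red pair by default); the arithmetic mean of a molecule's
#' surviving coefficients is compared to the threshold. A mean not below the
#' threshold labels the molecule \code{"good"}, a lower mean \code{"weak"}; a
#' molecule with no surviving record is \code{"not_applicable"}. The boundary
#' (mean exactly equal to the threshold) is \code{"good"}.
#'
#' @param x a keyed \code{molecule_set}, or a data frame with columns
#'   \code{id}, \code{dye}, \code{r} (then \code{keys} maps id to structure).
#' @param threshold acceptance threshold on the mean Pearson coefficient,
#'   in (0, 1).
#' @param dyes character vector of dye tags that count as the reference pair.
#' @return data frame with one row per keyed molecule: \code{inchikey},
#'   \code{mean_r}, \code{n_records}, \code{coloc_label}.
#' @export
label_colocalization <- function(x, threshold = 0.8, dyes = MITOTRACKER_DYES) {
  if (!(threshold > 0 && threshold < 1)) stopf("threshold must lie in (0, 1)")
  if (inherits(x, "molecule_set")) {
    coloc <- x$coloc
    key_of <- stats::setNames(x$molecules$inchikey, x$molecules$id)
    keys <- unique(x$molecules$inchikey)
  } else {
    coloc <- x
    key_of <- stats::setNames(as.character(coloc$id), coloc$id)
    keys <- unique(key_of)
  }
  if (nrow(coloc) && any(coloc$r < -1 | coloc$r > 1))
    stopf("colocalization coefficients outside [-1, 1]: corrupt input")
  keep <- coloc$dye %in% dyes
  coloc <- coloc[keep, , drop = FALSE]
  coloc$inchikey <- unname(key_of[coloc$id])
  agg <- if (nrow(coloc)) {
    s <- tapply(coloc$r, coloc$inchikey, mean)
    n <- tapply(coloc$r, coloc$inchikey, length)
    data.frame(inchikey = names(s), mean_r = as.numeric(s),
               n_records = as.integer(n), stringsAsFactors = FALSE)
  } else {
    data.frame(inchikey = character(), mean_r = numeric(),
               n_records = integer(), stringsAsFactors = FALSE)
  }
  out <- data.frame(inchikey = keys, stringsAsFactors = FALSE)
  out <- merge(out, agg, by = "inchikey", all.x = TRUE, sort = FALSE)
  out$n_records[is.na(out$n_records)] <- 0L
  out$coloc_label <- ifelse(out$n_records == 0L, "not_applicable",
                            ifelse(out$mean_r >= threshold, "good", "weak"))
  out[match(keys, out$inchikey), , drop = FALSE]
}

#' Assemble the four task tables
#'
#' Builds the labeled tables that drive the multilevel framework:
#' \describe{
#'   \item{b_pvsc}{mitochondria-targeted probes vs mitochondria-targeted
#'     non-probe compounds (labels \code{probe}/\code{np_compound}).}
#'   \item{b_mvsp}{probes targeting mitochondria vs probes targeting any other
#'     organelle (labels \code{mitochondria}/\code{other}).}
#'   \item{m_pvsp}{six-organelle multiclass table over all organelle-labeled
#'     probes.}
#'   \item{b_mcol}{\code{good} vs \code{weak} colocalization among
#'     mitochondria probes with applicable dye records.}
#' }
#' A molecule may appear in several tables. Records carrying an organelle
#' label but no role are rejected with a reason.
#'
#' @param x a keyed, deduplicated \code{molecule_set}.
#' @param coloc_threshold,dyes forwarded to \code{\link{label_colocalization}}.
#' @return named list of four data frames (\code{inchikey}, \code{smiles},
#'   \code{label}), each of class \code{task_table} with attributes
#'   \code{task} and \code{labels}; the list carries a \code{rejects}
#'   attribute.
#' @export
build_task_tables <- function(x, coloc_threshold = 0.8, dyes = MITOTRACKER_DYES) {
  stopifnot(inherits(x, "molecule_set"))
  m <- x$molecules
  if (nrow(m) && any(is.na(m$inchikey)))
    stopf("build_task_tables() requires keyed records")
  bad <- !is.na(m$organelle) & is.na(m$role)
  rejects <- data.frame(id = m$id[bad], smiles = m$smiles[bad],
                        reason = rep("organelle label without role label", sum(bad)),
                        stringsAsFactors = FALSE)
  m <- m[!bad, , drop = FALSE]
  smi <- ifelse(is.na(m$canonical_smiles), m$smiles, m$canonical_smiles)

  mk <- function(idx, label, task, domain) {
    t <- data.frame(inchikey = m$inchikey[idx], smiles = smi[idx],
                    label = label, stringsAsFactors = FALSE)
    t <- t[!duplicated(paste(t$inchikey, t$label, sep = "\r")), , drop = FALSE]
    rownames(t) <- NULL
    structure(t, task = task, labels = domain, class = c("task_table", "data.frame"))
  }

  probe <- !is.na(m$role) & m$role == "probe"
  np <- !is.na(m$role) & m$role == "np_compound"
  mito <- !is.na(m$organelle) & m$organelle == "mitochondria"
  orglab <- !is.na(m$organelle)

  i1 <- which((probe | np) & mito)
  b_pvsc <- mk(i1, ifelse(probe[i1], "probe", "np_compound"),
               "b_pvsc", c("probe", "np_compound"))
  i2 <- which(probe & orglab)
  b_mvsp <- mk(i2, ifelse(mito[i2], "mitochondria", "other"),
               "b_mvsp", c("mitochondria", "other"))
  m_pvsp <- mk(i2, m$organelle[i2], "m_pvsp", ORGANELLES)

  cl <- label_colocalization(x, threshold = coloc_threshold, dyes = dyes)
  lab <- stats::setNames(cl$coloc_label, cl$inchikey)
  i4 <- which(probe & mito & lab[m$inchikey] %in% c("good", "weak"))
  b_mcol <- mk(i4, unname(lab[m$inchikey[i4]]), "b_mcol", c("good", "weak"))

  structure(list(b_pvsc = b_pvsc, b_mvsp = b_mvsp,
                 m_pvsp = m_pvsp, b_mcol = b_mcol),
            rejects = rejects)
}

#' Write a curated molecule set to CSV
#'
#' Emits the curated table and a rejects table (UTF-8, with header).
#' @param x a \code{molecule_set}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_curated <- function(x, dir) {
  stopifnot(inherits(x, "molecule_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "curated.csv")
  p2 <- file.path(dir, "rejects.csv")
  p3 <- file.path(dir, "coloc.csv")
  utils::write.csv(x$molecules, p1, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(x$rejects, p2, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(x$coloc, p3, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(p1, p2, p3))
}
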