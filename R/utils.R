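# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Accessor for OpenBabel API bindings that ChemmineOB builds but does not
# export (OBMol/OBAtom/OBBond/OBRing methods).
ob_api <- local({
  cache <- new.env(parent = emptyenv())
  function(fn) {
    if (is.null(cache[[fn]]))
      cache[[fn]] <- utils::getFromNamespace(fn, "ChemmineOB")
    cache[[fn]]
  }
})

# Which SMILES does OpenBabel accept? Probed one molecule at a time (a batch
# conversion would abort at the first bad entry). Charges (tetraalkyl
# ammonium/phosphonium cations) are preserved because molecules never
# round-trip through a connection-table format.
ob_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    !is.na(ob_convert1(s, "CAN"))
  }, TRUE, USE.NAMES = FALSE)
}

# Apply `f(mol)` to every molecule of a batch of pre-validated SMILES while
# the OpenBabel handle is alive (handles must never escape the callback: the
# underlying C++ object is freed when forEachMol advances).
ob_batch <- function(smiles, f) {
  res <- vector("list", length(smiles))
  if (!length(smiles)) return(res)
  i <- 0L
  ChemmineOB::forEachMol("SMILES",
                         paste0(paste(smiles, collapse = "\n"), "\n"),
                         function(mol) {
                           i <<- i + 1L
                           res[[i]] <<- f(mol)
                           NULL
                         })
  if (i != length(smiles))
    stopf("OpenBabel parsed %d of %d SMILES in a pre-validated batch", i, length(smiles))
  res
}

# Single-molecule format conversion returning NA on failure.
ob_convert1 <- function(smiles, to) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n")),
                  error = function(e) "")
  out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

ob_canonical <- function(smiles) {
  vapply(smiles, ob_convert1, "", to = "CAN", USE.NAMES = FALSE)
}

ob_inchikey <- function(smiles) {
  out <- vapply(smiles, ob_convert1, "", to = "INCHIKEY", USE.NAMES = FALSE)
  out[!is.na(out) & nchar(out) != 27] <- NA_character_
  out
}

# Number of disconnected fragments in a SMILES string ('.' separators).
smiles_fragments <- function(smiles) {
  lengths(strsplit(smiles, ".", fixed = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
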