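# Fragment grammar: conjugated scaffolds with two substitution slots (%A
# carries the recognition group, %B a decoration), plus class-specific
# recognition fragments written attachment-atom-first so they drop into a
# parenthesized branch. Valid-by-construction SMILES, transparent ground
# truth, no training required.

SYNTH_SCAFFOLDS <- c(
  naphthalene    = "c1ccc2cc(%A)c(%B)cc2c1",
  stilbene       = "c1cc(%B)ccc1C=Cc1ccc(%A)cc1",
  coumarin       = "O=C1C(%A)=Cc2cc(%B)ccc2O1",
  quinoline      = "c1ccc2nc(%A)cc(%B)c2c1",
  benzothiazole  = "c1cc(%B)c2c(c1)nc(%A)s2",
  anthracene     = "c1ccc2cc3cc(%A)c(%B)cc3cc2c1")

# cationic mitochondria anchors and their counterions
SYNTH_ANCHORS <- c(tpp  = "CC[P+](c1ccccc1)(c1ccccc1)c1ccccc1",
                   pyri = "C[n+]1ccc(C)cc1",
                   quat = "C[N+](C)(C)C")
SYNTH_IONS <- c(tpp = ".[Br-]", pyri = ".[I-]", quat = ".[Cl-]")

# recognition heads of the non-mitochondria classes
SYNTH_HEADS <- list(
  golgi = c("C(=O)NCCO", "NC(=O)CCCCCCC"),
  endoplasmic_reticulum = c("S(=O)(=O)NC", "NS(C)(=O)=O", "S(=O)(=O)C"),
  lysosome = c("N1CCOCC1", "N(C)C", "N1CCCC1", "N(CC)CC"),
  cell_membrane = c("N(CCCCCCCC)CCCCCCCC", "OCCCCCCCCCCCC"),
  nucleus = c("NC(=N)N", "C(=N)N"))

# a share of lysosome probes are themselves cationic dyes -- same onium
# chemotypes as the mitochondria anchors but archived as acetate rather than
# halide salts -- and a share of endoplasmic-reticulum probes are
# water-solubilized sodium sulfonates (anionic salts). Charge, disconnection
# and generic halogen content are therefore each imperfect evidence on their
# own; the anchor-specific keys (phosphorus, onium carbon, the individual
# halide counterions) carry the remaining mitochondria signal.
SYNTH_DECOY_FRACTION <- 1 / 3
SYNTH_DECOY_ANCHORS <- SYNTH_ANCHORS[c("pyri", "quat")]
SYNTH_DECOY_ION <- ".CC(=O)[O-]"
SYNTH_SULFONATE_FRACTION <- 1 / 2
SYNTH_SULFONATE_HEAD <- "S(=O)(=O)[O-]"
SYNTH_SULFONATE_ION <- ".[Na+]"

SYNTH_LINKERS <- c("", "C", "CC", "CCCC")
SYNTH_DECO <- c("", "C", "CC", "O", "OC", "CO", "C(=O)C", "F",
                "CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC")
SYNTH_DECO_LIPO <- c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 2, 2, 2)

# neutral scaffolds without recognition groups (non-probe compounds);
# slot fragment sets are disjoint so symmetric scaffolds cannot collide
SYNTH_NP_A <- c("F", "Cl", "Br", "C(C)=O", "C(=O)OC", "OC(=O)C")
SYNTH_NP_B <- c("", "C", "CC", "CCC", "OC", "OCC")

# design-set decorations (response sites / photophysics handles), disjoint
# from SYNTH_DECO so designed molecules never duplicate library molecules
SYNTH_SET_DECO <- list(
  ESIPT = c("O", "OC", "OCC"),
  ICT = c("N(C)C", "N(CC)CC", "[N+](=O)[O-]", "C#N", "N(C)CC",
          "OCCN(C)C", "N1CCCCC1", "C=C"),
  ALP = c("OP(=O)(O)O", "COP(=O)(O)O"),
  ROS = c("B(O)O", "B1OC(C)(C)C(C)(C)O1"),
  VIS = c("C=Cc1ccccc1", "C=CC#N", "C(C)=C"))

# MACCS keys the cationic-anchor grammar plants by construction, in
# decreasing grammar-level enrichment: halogen content (the halide
# counterions), charge, the onium carbon environment, disconnected
# fragments, and the iodide counterion of the pyridinium salts.
# Complementary rather than redundant: acetate-salt lysosome decoys,
# sulfonate ER dyes, fluoro decorations and hydrates ensure no single key
# separates mitochondria on its own. Frozen from featurizing the grammar.
SYNTH_PLANTED_KEYS <- c("MACCS134", "MACCS49", "MACCS30", "MACCS166", "MACCS27")

substitute_slots <- function(scaffold, a, b) {
  s <- sub("(%A)", if (nzchar(a)) paste0("(", a, ")") else "", scaffold, fixed = TRUE)
  sub("(%B)", if (nzchar(b)) paste0("(", b, ")") else "", s, fixed = TRUE)
}

#' Specification of a synthetic probe library
#'
#' Fixes the generation conditions: total probe count split over the six
#' organelle classes in the skewed proportions organelle-probe collections
#' show (mitochondria dominating, Golgi/membrane/nucleus rare), a non-probe
#' compound arm, a label-noise rate, and the colocalization model -- a
#' logistic curve in the planted lipophilicity level plus Gaussian
#' measurement noise, clipped to [0, 1], centred so most mitochondria probes
#' fall in the 0.8--1 band.
#'
#' @param n total number of probes across the six organelle classes.
#' @param noise label-noise rate: the probability an organelle label is
#'   swapped across the mitochondria/other divide (structures and ground
#'   truth are never perturbed).
#' @param seed integer seed.
#' @param np_fraction non-probe compounds as a fraction of \code{n}.
#' @param coloc list: \code{intercept}, \code{slope} (on the lipophilicity
#'   level), \code{sd} of the record noise, \code{p_applicable} (share of
#'   mitochondria probes measured against the MitoTracker pair).
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n = 1200, noise = 0.05, seed = 7,
                           np_fraction = 236 / 1622,
                           coloc = list(intercept = 1.8, slope = 0.8,
                                        sd = 0.05, p_applicable = 0.92)) {
  base <- c(golgi = 40, endoplasmic_reticulum = 153, lysosome = 361,
            cell_membrane = 36, mitochondria = 982, nucleus = 50)
  counts <- round(base / sum(base) * n)
  counts["mitochondria"] <- counts["mitochondria"] + (n - sum(counts))
  structure(list(n = n, counts = counts,
                 n_np = round(np_fraction * n),
                 noise = noise, seed = seed, coloc = coloc),
            class = "synthetic_spec")
}

# enumerate the combination grid of one class and sample `count` rows
sample_combos <- function(count, heads, linkers, decos, n_scaffold = length(SYNTH_SCAFFOLDS)) {
  grid <- expand.grid(scaffold = seq_len(n_scaffold), head = seq_along(heads),
                      linker = seq_along(linkers), deco = seq_along(decos))
  if (count > nrow(grid))
    stopf("requested %d molecules but the grammar spans only %d combinations",
          count, nrow(grid))
  grid[sample(nrow(grid), count), , drop = FALSE]
}

#' Generate a synthetic probe library with known ground truth
#'
#' Emits SMILES from the fragment grammar: mitochondria-class molecules
#' carry a cationic anchor (triarylphosphonium, pyridinium or quaternary
#' ammonium, with its counterion) and lipophilic decorations; lysosome
#' molecules carry basic amine heads (deliberately the most confusable
#' class); endoplasmic reticulum, Golgi, membrane and nucleus classes carry
#' their own recognition fragments; non-probe compounds are neutral
#' scaffolds without recognition groups. Colocalization records for
#' mitochondria probes are drawn from the spec's logistic-lipophilicity
#' model against the MitoTracker dye pair (a small share only carries an
#' off-pair dye record and is thus not applicable). Every emitted SMILES is
#' re-parsed as a self-check; generation is fully reproducible for a fixed
#' seed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list of class \code{synthetic_library}: \code{molecules} (id,
#'   smiles, role, organelle, set), \code{coloc} (id, dye, r), and
#'   \code{truth} (per-molecule generating class, lipophilicity level,
#'   latent colocalization mean and good/weak assignment, plus
#'   \code{planted_keys}).
#' @export
generate_library <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    rows <- list(); coloc <- list(); truth <- list()
    serial <- 0L
    emit <- function(smiles, role, organelle, lipo) {
      serial <<- serial + 1L
      id <- sprintf("syn%05d", serial)
      rows[[serial]] <<- data.frame(id = id, smiles = smiles, role = role,
                                    organelle = organelle, set = NA_character_,
                                    stringsAsFactors = FALSE)
      truth[[serial]] <<- data.frame(id = id, true_role = role,
                                     true_organelle = organelle,
                                     lipo_level = lipo,
                                     coloc_latent = NA_real_,
                                     coloc_mean_r = NA_real_,
                                     coloc_good = NA,
                                     stringsAsFactors = FALSE)
      id
    }

    for (org in names(spec$counts)) {
      cnt <- spec$counts[[org]]
      if (cnt == 0) next
      if (org == "mitochondria") {
        combos <- sample_combos(cnt, SYNTH_ANCHORS, SYNTH_LINKERS, SYNTH_DECO)
        for (i in seq_len(nrow(combos))) {
          cb <- combos[i, ]
          anchor <- names(SYNTH_ANCHORS)[cb$head]
          smi <- paste0(
            substitute_slots(SYNTH_SCAFFOLDS[[cb$scaffold]],
                             paste0(SYNTH_LINKERS[cb$linker], SYNTH_ANCHORS[[anchor]]),
                             SYNTH_DECO[cb$deco]),
            SYNTH_IONS[[anchor]])
          lipo <- SYNTH_DECO_LIPO[cb$deco]
          id <- emit(smi, "probe", org, lipo)
          # colocalization records
          latent <- stats::plogis(spec$coloc$intercept + spec$coloc$slope * lipo)
          truth[[serial]]$coloc_latent <- latent
          if (stats::runif(1) < spec$coloc$p_applicable) {
            n_rec <- sample(1:2, 1)
            dyes <- sample(MITOTRACKER_DYES, n_rec, replace = TRUE)
            r <- pmin(1, pmax(0, latent + stats::rnorm(n_rec, 0, spec$coloc$sd)))
            coloc[[length(coloc) + 1]] <- data.frame(id = id, dye = dyes, r = r,
                                                     stringsAsFactors = FALSE)
            truth[[serial]]$coloc_mean_r <- mean(r)
            truth[[serial]]$coloc_good <- mean(r) >= 0.8
          } else {
            coloc[[length(coloc) + 1]] <- data.frame(
              id = id, dye = "LysoTracker Red",
              r = pmin(1, pmax(0, latent + stats::rnorm(1, 0, spec$coloc$sd))),
              stringsAsFactors = FALSE)
          }
        }
      } else {
        n_decoy <- if (org == "lysosome") round(SYNTH_DECOY_FRACTION * cnt) else 0L
        n_sulfo <- if (org == "endoplasmic_reticulum")
          round(SYNTH_SULFONATE_FRACTION * cnt) else 0L
        heads <- SYNTH_HEADS[[org]]
        combos <- sample_combos(cnt - n_decoy - n_sulfo, heads,
                                SYNTH_LINKERS, SYNTH_DECO)
        for (i in seq_len(nrow(combos))) {
          cb <- combos[i, ]
          smi <- substitute_slots(SYNTH_SCAFFOLDS[[cb$scaffold]],
                                  paste0(SYNTH_LINKERS[cb$linker], heads[[cb$head]]),
                                  SYNTH_DECO[cb$deco])
          # neutral probes are sometimes archived as hydrates: a disconnected
          # structure (key 166) is correlated with, but not identical to,
          # being an ion pair (key 49)
          if (stats::runif(1) < 0.15) smi <- paste0(smi, ".O")
          emit(smi, "probe", org, SYNTH_DECO_LIPO[cb$deco])
        }
        if (n_decoy > 0) {
          dc <- sample_combos(n_decoy, SYNTH_DECOY_ANCHORS, SYNTH_LINKERS, SYNTH_DECO)
          for (i in seq_len(nrow(dc))) {
            cb <- dc[i, ]
            smi <- paste0(
              substitute_slots(SYNTH_SCAFFOLDS[[cb$scaffold]],
                               paste0(SYNTH_LINKERS[cb$linker],
                                      SYNTH_DECOY_ANCHORS[[cb$head]]),
                               SYNTH_DECO[cb$deco]),
              SYNTH_DECOY_ION)
            emit(smi, "probe", org, SYNTH_DECO_LIPO[cb$deco])
          }
        }
        if (n_sulfo > 0) {
          sc <- sample_combos(n_sulfo, SYNTH_SULFONATE_HEAD, SYNTH_LINKERS, SYNTH_DECO)
          for (i in seq_len(nrow(sc))) {
            cb <- sc[i, ]
            smi <- paste0(
              substitute_slots(SYNTH_SCAFFOLDS[[cb$scaffold]],
                               paste0(SYNTH_LINKERS[cb$linker], SYNTH_SULFONATE_HEAD),
                               SYNTH_DECO[cb$deco]),
              SYNTH_SULFONATE_ION)
            emit(smi, "probe", org, SYNTH_DECO_LIPO[cb$deco])
          }
        }
      }
    }

    # non-probe compounds: mitochondria-localizing but featureless scaffolds
    if (spec$n_np > 0) {
      combos <- sample_combos(spec$n_np, SYNTH_NP_A, SYNTH_LINKERS[1],
                              SYNTH_NP_B)
      for (i in seq_len(nrow(combos))) {
        cb <- combos[i, ]
        smi <- substitute_slots(SYNTH_SCAFFOLDS[[cb$scaffold]],
                                SYNTH_NP_A[cb$head], SYNTH_NP_B[cb$deco])
        # a share of collection compounds are archived as hydrates, so a
        # disconnected structure does not imply an ion pair
        if (stats::runif(1) < 0.3) smi <- paste0(smi, ".O")
        emit(smi, "np_compound", "mitochondria", 0)
      }
    }

    empty_mols <- data.frame(id = character(), smiles = character(),
                             role = character(), organelle = character(),
                             set = character(), stringsAsFactors = FALSE)
    molecules <- if (length(rows)) do.call(rbind, rows) else empty_mols
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(id = character(), true_role = character(),
                             true_organelle = character(), lipo_level = numeric(),
                             coloc_latent = numeric(), coloc_mean_r = numeric(),
                             coloc_good = logical(), stringsAsFactors = FALSE)
    coloc <- if (length(coloc)) do.call(rbind, coloc)
             else data.frame(id = character(), dye = character(), r = numeric())

    # symmetric label noise across the mitochondria/other divide
    molecules$organelle_true <- molecules$organelle
    probe_idx <- which(molecules$role == "probe")
    flip <- probe_idx[stats::runif(length(probe_idx)) < spec$noise]
    others <- setdiff(ORGANELLES, "mitochondria")
    for (i in flip) {
      molecules$organelle[i] <-
        if (molecules$organelle_true[i] == "mitochondria")
          sample(others, 1) else "mitochondria"
    }
  })

  # self-check: every emitted SMILES must parse
  bad <- !ob_valid(molecules$smiles)
  if (any(bad))
    stopf("generator grammar emitted unparsable SMILES: %s",
          paste(utils::head(molecules$smiles[bad], 3), collapse = " ; "))

  structure(list(molecules = molecules[, c("id", "smiles", "role", "organelle", "set")],
                 coloc = coloc,
                 truth = list(table = truth,
                              label_noise_flips = molecules$id[molecules$organelle !=
                                                                 molecules$organelle_true],
                              planted_keys = SYNTH_PLANTED_KEYS,
                              seed = spec$seed)),
            class = "synthetic_library")
}

#' @method print synthetic_library
#' @export
print.synthetic_library <- function(x, ...) {
  cat("synthetic_library:", nrow(x$molecules), "molecules,",
      nrow(x$coloc), "colocalization records\n")
  print(table(role = x$molecules$role, organelle = x$molecules$organelle))
  invisible(x)
}

#' Convert a synthetic library to a molecule set
#'
#' @param x a \code{synthetic_library}.
#' @return a \code{molecule_set} ready for \code{\link{standardize_and_key}}.
#' @export
as_molecule_set <- function(x) {
  stopifnot(inherits(x, "synthetic_library"))
  m <- x$molecules
  m$canonical_smiles <- NA_character_
  m$inchikey <- NA_character_
  new_molecule_set(m, x$coloc,
                   data.frame(id = character(), smiles = character(),
                              reason = character(), stringsAsFactors = FALSE))
}

#' Generate the five tagged design sets
#'
#' Five sub-libraries of designed mitochondria-signal molecules tagged
#' ESIPT / ICT / ALP / ROS / VIS, with the library sizes used for the flow
#' (Sankey) accounting: 70, 451, 21, 37 and 54 molecules (633 total) by
#' default. Each set pairs the cationic-anchor grammar with a set-specific
#' decoration (hydroxy handles for ESIPT, donor/acceptor groups for ICT,
#' phosphate response sites for ALP, boronates for ROS, molecular-rotor
#' vinyls for VIS). Byte-identical output for a fixed seed.
#'
#' @param spec a \code{\link{synthetic_spec}} (only the seed is used).
#' @param sizes named integer vector of set sizes.
#' @return a \code{molecule_set} with the \code{set} column filled.
#' @export
generate_design_sets <- function(spec = synthetic_spec(),
                                 sizes = c(ESIPT = 70, ICT = 451, ALP = 21,
                                           ROS = 37, VIS = 54)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  with_seed(spec$seed + 1L, {
    serial <- 0L
    for (s in names(sizes)) {
      decos <- SYNTH_SET_DECO[[s]]
      if (is.null(decos)) decos <- SYNTH_DECO
      combos <- sample_combos(sizes[[s]], SYNTH_ANCHORS, SYNTH_LINKERS, decos)
      for (i in seq_len(nrow(combos))) {
        cb <- combos[i, ]
        anchor <- names(SYNTH_ANCHORS)[cb$head]
        smi <- paste0(
          substitute_slots(SYNTH_SCAFFOLDS[[cb$scaffold]],
                           paste0(SYNTH_LINKERS[cb$linker], SYNTH_ANCHORS[[anchor]]),
                           decos[cb$deco]),
          SYNTH_IONS[[anchor]])
        serial <- serial + 1L
        rows[[serial]] <- data.frame(id = sprintf("design%04d", serial),
                                     smiles = smi, role = NA_character_,
                                     organelle = NA_character_, set = s,
                                     stringsAsFactors = FALSE)
      }
    }
  })
  m <- do.call(rbind, rows)
  bad <- !ob_valid(m$smiles)
  if (any(bad))
    stopf("design-set grammar emitted unparsable SMILES: %s",
          paste(utils::head(m$smiles[bad], 3), collapse = " ; "))
  m$canonical_smiles <- NA_character_
  m$inchikey <- NA_character_
  new_molecule_set(m,
                   data.frame(id = character(), dye = character(), r = numeric(),
                              stringsAsFactors = FALSE),
                   data.frame(id = character(), smiles = character(),
                              reason = character(), stringsAsFactors = FALSE))
}
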