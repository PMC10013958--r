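test_that("CSV parsing keeps every row as a record or a reject", {
  p <- write_mol_csv(data.frame(smiles = c("CCO", "c1ccccc1", "CC(=O)O"),
                                role = "probe", organelle = "mitochondria"))
  ms <- parse_molecules(p)
  expect_equal(nrow(ms$molecules), 3)
  expect_equal(nrow(ms$rejects), 0)

  p2 <- write_mol_csv(data.frame(smiles = c("CCO", "not_a_smiles", "c1ccccc1")))
  ms2 <- parse_molecules(p2)
  expect_equal(nrow(ms2$molecules), 2)
  expect_equal(nrow(ms2$rejects), 1)
  expect_match(ms2$rejects$reason, "unparsable")
  expect_equal(nrow(ms2$molecules) + nrow(ms2$rejects), 3)

  p3 <- write_mol_csv(data.frame(smiles = character()))
  ms3 <- parse_molecules(p3)
  expect_equal(nrow(ms3$molecules), 0)
  expect_equal(nrow(ms3$rejects), 0)
})

test_that("missing file and missing smiles column are fatal", {
  expect_error(parse_molecules(file.path(tempdir(), "no_such.csv")), "not found")
  p <- write_mol_csv(data.frame(structure_text = "CCO"))
  expect_error(parse_molecules(p), "smiles")
})

test_that("SMI and multi-record CSV inputs are read", {
  p <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol_a", "c1ccccc1 mol_b"), p)
  ms <- parse_molecules(p)
  expect_equal(ms$molecules$id, c("mol_a", "mol_b"))

  # one molecule, two colocalization records on two rows
  p2 <- write_mol_csv(data.frame(
    id = c("m1", "m1"), smiles = "CCO", role = "probe",
    organelle = "mitochondria",
    coloc_dye = c("MitoTracker Green", "MitoTracker Red"),
    coloc_r = c(0.9, 0.7)))
  ms2 <- parse_molecules(p2)
  expect_equal(nrow(ms2$molecules), 1)
  expect_equal(nrow(ms2$coloc), 2)
})

test_that("standardization canonicalizes, keys, and keeps salt fragments", {
  ms <- standardize_and_key(c(a = "c1ccccc1", b = "C1=CC=CC=C1"))
  expect_equal(ms$molecules$inchikey[1], ms$molecules$inchikey[2])
  expect_equal(nchar(ms$molecules$inchikey[1]), 27)

  salt <- standardize_and_key(c(s = "C[N+](C)(C)C.[Cl-]"))
  expect_match(salt$molecules$canonical_smiles, "\\.")
  expect_match(salt$molecules$canonical_smiles, "N\\+", fixed = FALSE)

  again <- standardize_and_key(c(a = "c1ccccc1", b = "C1=CC=CC=C1"))
  expect_identical(ms$molecules, again$molecules)
})

test_that("deduplication is within-label, order-stable and idempotent", {
  mk <- function(smi, org, id) data.frame(
    id = id, smiles = smi, role = "probe", organelle = org,
    set = NA_character_, stringsAsFactors = FALSE)
  raw <- rbind(mk("c1ccccc1", "mitochondria", "a"),
               mk("C1=CC=CC=C1", "mitochondria", "b"),
               mk("c1ccccc1", "lysosome", "c"))
  ms <- standardize_and_key(
    orgprobe:::new_molecule_set(raw,
      data.frame(id = character(), dye = character(), r = numeric()),
      data.frame(id = character(), smiles = character(), reason = character())))
  dd <- deduplicate(ms)
  # same structure twice under mitochondria collapses; the lysosome copy stays
  expect_equal(nrow(dd$molecules), 2)
  expect_setequal(dd$molecules$organelle, c("mitochondria", "lysosome"))
  expect_equal(dd$molecules$id[dd$molecules$organelle == "mitochondria"], "a")
  expect_identical(deduplicate(dd)$molecules, dd$molecules)

  empty <- ms
  empty$molecules <- ms$molecules[0, ]
  expect_equal(nrow(deduplicate(empty)$molecules), 0)
})

test_that("unkeyed records cannot be deduplicated", {
  lib <- fixture_library()
  expect_error(deduplicate(as_molecule_set(lib)), "keyed")
})

test_that("colocalization labeling follows the mean-threshold rule with dye filtering", {
  mk_set <- function(coloc) {
    mols <- data.frame(id = "m1", smiles = "CCO", role = "probe",
                       organelle = "mitochondria", set = NA_character_,
                       canonical_smiles = "CCO", inchikey = "KEY1",
                       stringsAsFactors = FALSE)
    orgprobe:::new_molecule_set(mols, coloc,
      data.frame(id = character(), smiles = character(), reason = character()))
  }
  lab <- function(coloc) label_colocalization(mk_set(coloc))$coloc_label

  expect_equal(lab(data.frame(id = "m1", dye = "MitoTracker Red", r = 0.85)), "good")
  expect_equal(lab(data.frame(id = "m1", dye = "MitoTracker Red", r = 0.8)), "good")
  expect_equal(lab(data.frame(id = "m1", dye = "MitoTracker Red", r = 0.799999)), "weak")
  expect_equal(lab(data.frame(id = "m1", dye = "MitoTracker Red", r = c(0.7, 0.9))), "good")
  expect_equal(lab(data.frame(id = "m1", dye = "LysoTracker Red", r = 0.95)),
               "not_applicable")
  expect_error(lab(data.frame(id = "m1", dye = "MitoTracker Red", r = 1.2)),
               "corrupt")
  expect_error(label_colocalization(mk_set(
    data.frame(id = "m1", dye = "MitoTracker Red", r = 0.9)), threshold = 1.2))
})

test_that("raising any coefficient never flips good to weak", {
  set.seed(11)
  for (i in 1:25) {
    r <- runif(sample(1:4, 1), -1, 1)
    mols <- data.frame(id = "m", smiles = "CCO", role = "probe",
                       organelle = "mitochondria", set = NA_character_,
                       canonical_smiles = "CCO", inchikey = "K",
                       stringsAsFactors = FALSE)
    mkset <- function(rv) orgprobe:::new_molecule_set(
      mols, data.frame(id = "m", dye = "MitoTracker Red", r = rv),
      data.frame(id = character(), smiles = character(), reason = character()))
    before <- label_colocalization(mkset(r))$coloc_label
    expect_true(before %in% c("good", "weak"))
    j <- sample(seq_along(r), 1)
    r2 <- r; r2[j] <- min(1, r2[j] + runif(1, 0, 0.5))
    after <- label_colocalization(mkset(r2))$coloc_label
    if (before == "good") expect_equal(after, "good")
  }
})

test_that("task tables follow the membership rules", {
  mk <- function(id, smi, role, org) data.frame(
    id = id, smiles = smi, role = role, organelle = org,
    set = NA_character_, stringsAsFactors = FALSE)
  raw <- rbind(mk("p1", "CC[P+](c1ccccc1)(c1ccccc1)c1ccccc1.[Br-]", "probe", "mitochondria"),
               mk("n1", "c1ccc2ccccc2c1", "np_compound", "mitochondria"),
               mk("p2", "CCN1CCOCC1", "probe", "lysosome"))
  ms <- standardize_and_key(orgprobe:::new_molecule_set(raw,
    data.frame(id = character(), dye = character(), r = numeric()),
    data.frame(id = character(), smiles = character(), reason = character())))
  tabs <- build_task_tables(ms)
  expect_equal(nrow(tabs$b_pvsc), 2)
  expect_setequal(tabs$b_pvsc$label, c("probe", "np_compound"))
  expect_equal(nrow(tabs$b_mvsp), 2)
  expect_setequal(tabs$b_mvsp$label, c("mitochondria", "other"))
  expect_equal(nrow(tabs$m_pvsp), 2)
  expect_equal(nrow(tabs$b_mcol), 0)

  # empty input -> four empty tables
  empty <- ms; empty$molecules <- ms$molecules[0, ]
  tabs0 <- build_task_tables(empty)
  expect_true(all(vapply(tabs0, nrow, 0L) == 0))

  # organelle without role is rejected with a reason
  raw2 <- rbind(raw, mk("x1", "CCO", NA, "nucleus"))
  ms2 <- standardize_and_key(orgprobe:::new_molecule_set(raw2,
    data.frame(id = character(), dye = character(), r = numeric()),
    data.frame(id = character(), smiles = character(), reason = character())))
  tabs2 <- build_task_tables(ms2)
  rej <- attr(tabs2, "rejects")
  expect_equal(rej$id, "x1")
})

test_that("no task table holds a duplicate (inchikey, label) pair and rows reconcile", {
  tabs <- fixture_tasks()
  for (t in tabs) {
    expect_false(any(duplicated(paste(t$inchikey, t$label))))
    expect_true(all(t$label %in% attr(t, "labels")))
  }
  m <- fixture_curated()$molecules
  probes <- sum(m$role == "probe" & !is.na(m$organelle))
  expect_equal(nrow(tabs$b_mvsp), probes)
  expect_equal(nrow(tabs$m_pvsp), probes)
})
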