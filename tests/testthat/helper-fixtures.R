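# Shared fixtures, built in code and cached for the session so expensive
# chemistry (featurization, cascade training) runs once.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# small curated synthetic library shared by io/cascade tests
fixture_library <- function() memo("lib", generate_library(synthetic_spec(n = 200, seed = 3)))

fixture_curated <- function() memo("curated", {
  deduplicate(standardize_and_key(as_molecule_set(fixture_library())))
})

fixture_tasks <- function() memo("tasks", build_task_tables(fixture_curated()))

fixture_maccs <- function() memo("maccs", {
  tab <- fixture_tasks()$b_mvsp
  featurize(stats::setNames(tab$smiles, tab$inchikey), "maccs")
})

# a small fitted cascade (MACCS at every level for speed)
fixture_cascade <- function() memo("cascade", {
  cfg <- cascade_config(families = c(b_pvsc = "maccs", b_mvsp = "maccs",
                                     m_pvsp = "maccs", b_mcol = "maccs"))
  suppressWarnings(fit_cascade(fixture_curated(), cfg, seed = 3))
})

# write a molecule CSV and return its path
write_mol_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a minimal cascade_result data frame for screening tests
fake_cascade_result <- function(df) {
  base <- data.frame(id = df$id, smiles = df$id, set = NA_character_,
                     l1_label = "probe", l1_p_probe = 0.9,
                     l2_label = "mitochondria", l2_p_mito = 0.9,
                     l3_label = "mitochondria", l3_p_max = 0.9, l3_p_mito = 0.9,
                     l4_label = "good", l4_p_good = 0.9,
                     disagreement = FALSE,
                     terminal = df$terminal %||% "mitochondria/good",
                     stringsAsFactors = FALSE)
  base$inchikey <- df$id
  class(base) <- c("cascade_result", "data.frame")
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a
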