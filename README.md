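# orgprobe

Multilevel machine-learning prediction of organelle-targeted fluorescent
probes, for cheminformaticians and probe chemists who want a quantitative
screen before synthesis.

Fluorescent probes that light up a specific subcellular compartment are
designed mostly from intuition — cationic, lipophilic molecules tend to end
up in mitochondria, amines in lysosomes — and the intuition fails often
enough to waste synthesis effort. `orgprobe` turns the question into a
cascade of four classifiers over SMILES structures:

1. **b_pvsc** — probe vs ordinary compound (the gate);
2. **b_mvsp** — mitochondria vs any other organelle;
3. **m_pvsp** — six-organelle multiclass (Golgi, ER, lysosome, membrane,
   mitochondria, nucleus), run for *every* predicted probe so it can
   overrule level 2 (conflicts are flagged, not hidden);
4. **b_mcol** — among mitochondria probes, good vs weak imaging
   colocalization, where *good* means the mean Pearson coefficient r̄
   against the MitoTracker dye pair satisfies r̄ ≥ 0.8.

Around the cascade the package provides the full framework: SMILES
curation (canonicalization, InChIKey deduplication within labels, salt
fragments retained because counterions are predictive), MACCS/ECFP4/2D
featurization through OpenBabel, variance/|r| > 0.95 correlation feature
selection, from-scratch SMOTE balancing with auditable parent pairs, a
ten-algorithm × feature-family comparison grid under a shared stratified
80/20 + 5-fold CV protocol, exact TreeSHAP + gain-importance interpretation
with top-k consensus ranking, ADMET-style property screening, and a seeded
synthetic probe-library generator with planted, recoverable structure so
everything is testable without any external data.

## Worked example

Generate a synthetic probe library, curate it, compare models on the
mitochondria-vs-other task and interpret the fitted model:

```r
library(orgprobe)

spec    <- synthetic_spec(n = 600, seed = 7)
lib     <- generate_library(spec)
curated <- deduplicate(standardize_and_key(as_molecule_set(lib)))
curated
#> molecule_set: 687 molecules, 542 colocalization records, 0 rejects
#>   keyed: 687 / 687

tabs <- build_task_tables(curated)
tab  <- tabs$b_mvsp
X    <- featurize(setNames(tab$smiles, tab$inchikey), "maccs")
grid <- grid_compare(list(maccs = X), tab$label,
                     algorithms = c("lightgbm", "random_forest",
                                    "logistic_regression"),
                     seed = 7, positive = "mitochondria", task = "b_mvsp")
grid
#> eval_grid [b_mvsp] : 3 cells, seed 7
#>  family           algorithm cv_acc cv_auc test_acc test_auc
#>   maccs            lightgbm  0.940  0.955    0.967    0.965
#>   maccs       random_forest  0.946  0.948    0.975    0.963
#>   maccs logistic_regression  0.948  0.963    0.967    0.955
#> best cell (test acc, tie-break cv acc): maccs / random_forest
```

Accuracies sit in the mid-0.9s because the synthetic classes are separable
by construction up to the 5% label noise; on real literature collections
the confusable classes push this lower. Interpreting the boosted
mitochondria model recovers the structure the generator planted:

```r
fit    <- train_classifier(X, tab$label, "lightgbm", seed = 7)
report <- attribution_report(fit, X)
report
#> attribution_report (class: mitochondria )
#>   feature mean_abs_shap        gain rank_shap rank_gain
#>  MACCS134     2.6460953 0.755483526         1         1
#>   MACCS49     0.8920052 0.099996173         2         2
#>   ...
#> top15 consensus: 13 features
#> heteroatom fraction of SHAP top-50: 0.38
```

MACCS134 (halogen — the halide counterions of the cationic anchors) and
MACCS49 (charge) head both rankings with positive direction: exactly the
charge-plus-counterion signature the generator plants in its mitochondria
class, and the same signature mechanistic work attributes to real
mitochondrial accumulation (cations pumped in by the membrane potential).

The fitted cascade runs prospective libraries end to end:

```r
cascade <- fit_cascade(curated, seed = 7)
designs <- generate_design_sets(spec)         # 70/451/21/37/54 molecules
res     <- predict(cascade, designs)
flow    <- cascade_flow(res)                  # Sankey-ready level accounting
```

and `screen_candidates(res, load_property_table("admet.csv"))` ranks the
`mitochondria/good` terminals by toxicity, synthetic accessibility and
logP, with per-rule pass flags and a manual `keep` override.

A thin command-line wrapper over these functions ships in
`inst/cli/orgprobe.R` (subcommands `simulate`, `curate`, `featurize`,
`grid`, `cascade`, `screen`).

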