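# cropgraph

Graph-based suitability evaluation for crop variety trials.

## The problem

Multi-environment variety trials record, for each variety-by-site
combination, a panel of phenotypic traits (disease incidence, lodging,
plant architecture, yield components — 15 in all) and growth-period
climate summaries (mean and variance of 12 variables), after which an
expert labels the record **continuing test** (keep trialling the variety
at that site) or **termination test** (abandon it). `cropgraph` casts
this decision as semi-supervised node classification: each record is a
node, nodes are connected to their *k* nearest neighbours by **chord
distance** between direction-normalized feature rows,

d(u, v) = ‖u/‖u‖ − v/‖v‖‖ = √(2 − 2 cos θ) ∈ [0, 2],

and a from-scratch **graph convolutional network** (input + 4 hidden + output
layers; H⁽ˡ⁺¹⁾ = ReLU(Â H⁽ˡ⁾ W⁽ˡ⁾) with the renormalized operator
Â = D̃^(−1/2)(A + I) D̃^(−1/2), log-softmax output) is trained
transductively with negative log-likelihood on a small **label budget**
(50–2000 labelled nodes out of 10,000) using hand-written Adam. A
two-head graph attention variant and eight classical baselines (KNN,
logistic regression, SVM, naive Bayes, decision tree, random forest, a
six-layer MLP, an RBF network) run behind one fit/predict contract for
comparison under a five-metric, 20-repeat protocol (accuracy, precision,
recall, F1, rank AUC; positive class = "continuing test").

Because trial archives of this kind are not public, the package includes
a first-class synthetic generator: labels come from a latent linear
score over standardized features, with loadings calibrated in closed
form so every feature's point-biserial correlation with the label hits a
configurable target profile (relative change of yield, RCY, dominant at
r ≈ 0.346), plus site-clustered climate columns, injected outliers and
missing cells.

## Worked example

```r
library(cropgraph)

tab <- generate_trial_table(synthetic_config(n_records = 2000, seed = 42))
tab
#> trial_table: 2000 records x 39 features, 14 sites, 50.0% positive, 780 missing cells

clean <- screen_outliers(tab)      # |z| > 4 cells -> NA, then mean-impute
clean$report
#> preprocess_report (mode raw): 390 outlier cells flagged, 1170 cells imputed

std <- standardize(clean$table)
correlation_report(std)
#> correlation_report on 2000 records; top features by |r|:
#>   feature       r  abs_r rank flagged
#> 1     RCY  0.3302 0.3302    1    TRUE
#> 2     ARH -0.1608 0.1608    2    TRUE
#> 3     VRH -0.1229 0.1229    3    TRUE
#> ...

X <- feature_matrix(std)
g <- build_knn_graph(X, k = 10)
g
#> trial_graph: 2000 nodes, 12037 undirected edges (mean degree 12.0)

# transductive training: the whole graph is visible, 1000 labelled nodes
# (drawn from the 1600-record training partition) contribute to the loss
fit <- train_gcn(g, X, tab$label, budget_nodes,
                 train_config(budget = 1000, hidden = 32, epochs = 60, seed = 1))
pred <- predict_gcn(fit$params, g, X)
#> test accuracy 0.650  precision 0.617  recall 0.755  F1 0.679  AUC 0.706
```

The correlation screen recovers the configured profile (RCY first by a
wide margin, humidity/sunshine/temperature features next); the
transductive classifier reaches ~0.65 test accuracy from 1000 labels on
this 2000-record dataset — close to the ceiling implied by the
generator's calibrated signal strength, and above the tabular baselines
trained on the same labels.

Full experiment suites mirror the study design:

```r
cfg <- experiment_config(synth = synthetic_config(n_records = 2000, seed = 1),
                         n_reps = 20, hidden = 32, epochs = 60,
                         budgets = c(50, 100, 400, 700, 1000, 1600))
run_table1(cfg)   # GCN accuracy: preprocessing mode x label budget
run_table2(cfg)   # 10 models x 5 metrics, repeat-averaged
run_table4(cfg)   # paired ablation: all features vs. RCY removed
```

Each suite writes CSVs plus a manifest (config, seeds, hash) when
`out_dir` is set; `rerun_manifest()` reproduces the CSVs bit-identically.

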