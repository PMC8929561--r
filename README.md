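# psnet — protein structure networks with interaction timelines

`psnet` builds protein structure networks whose edges carry **per-frame
interaction timelines** from structure ensembles (multi-model PDB files, or
per-frame interaction series exported by MD trajectory analysis), and scores
residues for allosteric relevance. It is aimed at structural
bioinformaticians who want to go beyond single-structure contact graphs:
instead of reducing an interaction to one scalar, every edge keeps the full
history `X[t]` of the interaction across the ensemble.

## The scores

For an edge `(i, j, k)` (nodes `i, j`, interaction type `k`) with timeline
`X_ijk`, the **edge neighbour correlation factor** is

    ECF(i,j,k) = Σ_(n,m,l) I(X_ijk ; X_nml)

summed over the edges sharing an endpoint with `(i, j)` (parallel edges of
another type included once, the edge itself excluded), where `I` is the
plug-in mutual information in bits over the joint histogram of per-frame
states. The **node correlation factor** `NCF(i) = Σ_(j,k) ECF(i,j,k)` sums
the ECF of a node's adjacent edges: residues whose interactions carry
information about their immediate environment score high. The **difference
NCF** (DNCF) replaces each `I(X;Y)` with `I(X;Y) − I(X̂;Ŷ)`, where the
hatted pair comes from a location-matched reference ensemble (e.g.
ligand-free vs ligand-bound), highlighting residues whose coupling *changes*
upon binding.

For single structures the package provides **betweenness centrality** (BC)
and **characteristic path length centrality** (`CPLC_i = L − L_i`, the
change of mean shortest-path length on deleting node `i`), both min-max
normalised, on the collapsed simple graph.

Prediction quality against binary residue labels is measured with ROC and
precision–recall curves integrated by the trapezoidal rule
(`evaluate_scores()`), including threshold selection at the top-left ROC
corner and a parameter grid-search harness.

## Worked example

Extract a scheduled contact from a generated multi-model ensemble, then
recover a planted coupled hub by NCF:

```r
library(psnet)

toy <- generate_toy_ensemble(n_residues = 4, n_frames = 6, switch_period = 1, seed = 1)
rec <- extract_contacts(toy$ensemble, cutoff = 5)
rec$timeline[[1]]
#> [1] 1 0 1 0 1 0          # the designed square-wave contact schedule

hub <- generate_hub_network(n_nodes = 8, frames = 2000, coupling = 0.8, seed = 42)
s <- ncf(hub$network)
round(sort(s, decreasing = TRUE), 3)
#> A:1:ALA:CB A:2:ALA:CB A:8:ALA:CB A:7:ALA:CB A:6:ALA:CB A:3:ALA:CB A:5:ALA:CB A:4:ALA:CB
#>      0.625      0.313      0.313      0.001      0.001      0.001      0.000      0.000
```

The hub (`A:1`, whose two ring edges are coupled copies of one master
timeline) scores ~0.63 bits — twice its neighbours, which each touch one
coupled edge; nodes with only independent edges sit at the finite-sample
bias floor. Evaluating NCF against the nodes that actually carry coupled
edges:

```r
lab <- reference_set(names(s),
                     as.integer(names(s) %in% c("A:1:ALA:CB", "A:2:ALA:CB", "A:8:ALA:CB")))
ev <- evaluate_scores(s, lab)
c(ev$rocAUC, ev$prAUC)
#> [1] 1 1                  # the three coupled nodes outrank all others
optimal_threshold(ev$roc)$threshold
#> [1] 0.3127508            # lowest score that still captures all positives
```

Typical real-data flow: `read_pdb_ensemble()` (or `parse_timeseries()` on
per-frame interaction series) → `build_network()` →
`aggregate_to_groups()` → `filter_network()` → `ncf()` / `dncf()` /
`cplc()` → `evaluate_scores()` against a label table. Timelines travel in a
documented line-oriented text format via `write_aif()` / `read_aif()`, and
`inst/cli/psnet.R` wraps the same functions as shell subcommands
(`convert`, `score`, `centrality`, `stats`, `evaluate`, `simulate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the package end to end on generated inputs — toy-ensemble extraction
through the exchange format into residue networks and NCF, the planted-hub
recovery experiment, centralities, and a ROC evaluation — and writes the
results JSON to `--out`. All randomness derives from `--seed`.

## Vignette

`vignettes/timeline-networks.Rmd` documents the model and its assumptions,
the estimator conventions (plug-in MI and its bias, disconnection handling
in CPLC, ROC/PR anchoring), what the synthetic generators do and do not
emulate, and known limitations.
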