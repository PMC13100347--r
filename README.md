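# tmegraph

Tissue-compartment spatial graphs for predicting pathologic complete
response (pCR) to neoadjuvant chemotherapy from H&E whole-slide tile
maps.

## What it does, and for whom

About a third of HER2+ breast cancer patients do not reach pCR after
neoadjuvant chemotherapy, and the spatial organization of the tumor
microenvironment on routine H&E slides — how tumor, stroma and
tumor-infiltrating lymphocytes (TILs) are arranged at the mesoscale —
is predictive of who will. `tmegraph` is for computational-pathology
researchers who want that organization modelled *interpretably* rather
than through an end-to-end black box.

Starting from a tile-level tissue map (a **TTA-image**: each retained
87.5 µm tile labelled tumor / stroma / iTIL / sTIL / necrosis), the
package:

1. builds one spatial graph per tissue compartment — affinity
   propagation (AP) exemplars as nodes (similarity
   `s(i,k) = −‖x_i − x_k‖²`, shared preference `P`), undirected
   K-nearest-neighbour edges (`K = 4`, `P = −50` by default);
2. summarizes each graph into a **91-dimensional descriptor**: six
   social-network-analysis metrics — node degree, clustering
   coefficient, closeness centrality, degree centrality, Katz
   centrality, community structure — each as a 10-bin histogram plus
   mean, SD, max, min, median (15 × 6 = 90), plus the network density
   `NED = 2m/(n(n−1))`;
3. trains a per-compartment tile-level MLP on 1,024-dim frozen-encoder
   embeddings under weak (slide-level) supervision and aggregates tile
   scores into **DLPS** features (mean, SD per compartment; 10 per
   patient);
4. assembles a **99-dimensional** per-compartment vector (91 SNA + 2
   DLPS + 6 clinical covariates: ER/PR status and percentage, CEP17,
   HER2/CEP17 ratio), selects features by cross-validated LASSO and
   classifies with a grid-searched MLP (stratified 5-fold CV);
5. ships the evaluation toolkit (rank AUC, F1/PPV/recall/NPV, DeLong
   comparison of correlated AUCs, Mann–Whitney/chi-square screening
   with BH-FDR, Spearman association with residual infiltration size)
   and the sensitivity (`K × P`) and training-size ablation harnesses;
6. includes a **synthetic-cohort generator** (tile maps with
   group-dependent TIL clustering, class-conditional Gaussian
   embeddings, clinical covariates with a group-shifted HER2/CEP17
   ratio) so the whole pipeline runs and is tested without any slide
   data.

See `vignettes/tissue-graph-modeling.Rmd` for the full methods
account.

## Worked example

```r
library(tmegraph)

# a synthetic cohort: 60x60 tile grids, pCR prevalence 0.42
coh  <- simulate_cohort(100, sim_config(), seed = 7)
y    <- cohort_labels(coh)

# stroma graph of one patient
g <- build_tissue_graph(coh$patients[[1]]$tta, "STROMA")
g
#> tissue_graph [STROMA]: 43 nodes, 93 edges (from 601 tiles; K=4, P=-50)

v <- extract_sna_features(g)
round(v[c("ND_mean", "CL_mean", "CC_mean", "NED")], 3)
#> ND_mean CL_mean CC_mean     NED
#>   4.326   0.564   0.191   0.103

# fit the stroma model on 80 patients, evaluate on the held-out 20
train <- coh; train$patients <- train$patients[1:80]
test  <- coh; test$patients  <- test$patients[81:100]
fit <- fit_response_model(train, "STROMA", c("sna", "clinical"),
                          config = model_config(seed = 1))
fit
#> pcr_model [STROMA | sna+clinical]: n = 80, 18/97 features selected
#>   classifier: MLP (64), L2 = 1e-04, CV AUC = 1.000
evaluate(predict(fit, test), cohort_labels(test))
#> AUC 1.000 | F1 1.000 | PPV 1.000 | recall 1.000 | NPV 1.000
```

The printed node/edge counts describe the stromal architecture graph
of the first patient; `ND_mean` is the average exemplar degree,
`NED` the overall graph density. The fitted model reports how many of
the 97 available features (91 SNA + 6 clinical here) LASSO kept and
the cross-validated AUC of the chosen classifier; `evaluate()` scores
the held-out patients. At the generator's default 60×60 scale the
planted effect (responders carry heavier, more tightly clustered TIL
infiltrates) is strong enough for near-perfect separation; the
acceptance harness works on smaller 36×36 grids where recovery is
non-trivial. None of this reflects real-slide performance.

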