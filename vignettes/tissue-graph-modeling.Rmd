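---
title: "Tissue-compartment graph modelling of treatment response: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-compartment graph modelling of treatment response: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pathologic complete response (pCR) to neoadjuvant chemotherapy in HER2+
breast cancer is the absence of residual invasive carcinoma at surgery
(ypT0/Tis, ypN0). Roughly a third of patients do not respond, and the
spatial organization of the tumor microenvironment (TME) on routine
H&E slides — how tumor, stroma and lymphocytic infiltrate are arranged
at the mesoscale — carries signal about who will. `tmegraph` models
that organization explicitly: instead of treating a slide as a bag of
tiles, it builds one spatial graph per tissue compartment and converts
each graph into a fixed-length, interpretable descriptor that a small
classifier can use alongside deep tile scores and clinical covariates.

# Pipeline

## From raster to tile map

Slides are partitioned into non-overlapping square tiles of 175 px at
0.5 µm/px (87.5 µm per side) — large enough to capture mesoscale
architecture, small enough to treat a tile as one tissue class. Tissue
is segmented by Otsu's threshold on the grayscale histogram; pixels
*below* the threshold count as tissue because H&E tissue is darker than
glass. Tiles with less than 20% tissue are discarded (a tile at exactly
20% is retained — only "less than" fails). Partial tiles at the image
edge are dropped rather than padded, so no tile mixes tissue with
out-of-image padding.

Retained tiles are labelled by a sequential binary scheme: tumor vs
stroma first; then necrosis *within* tumor (tested before lymphocytes
because necrotic debris mimics intratumoral lymphocytes); then
intratumoral TILs (iTILs) among the remaining tumor tiles; then
stromal TILs (sTILs) among stroma. Each stage is a pluggable scoring
function returning a probability, with 0.5 as the positive cutoff —
the package does not ship trained tissue CNNs, and the synthetic
generator provides ground-truth labels directly. The result is a
*TTA-image* (tissue type annotation image): a 2-D grid assigning every
tile exactly one of background, excluded, tumor, stroma, iTIL, sTIL,
necrosis. The TIL compartment is the union of iTIL and sTIL tiles, so
`|TIL| = |iTIL| + |sTIL|` always.

## Tissue graphs

For each of the five compartments (tumor, stroma, iTILs, sTILs, TILs)
the compartment's tile coordinates are clustered by affinity
propagation (AP) in tile units, with similarity the negative squared
Euclidean distance and a shared preference `P` on the diagonal. The AP
exemplars become graph nodes; each node connects to its `K` nearest
neighbours, the directed KNN relation symmetrized by union so boundary
nodes stay connected. Defaults are `K = 4`, `P = -50`: `P = -50`
corresponds to absorbing tiles within about 7 tile widths (~600 µm),
and the sensitivity harness (`sensitivity_grid()`) evaluates
`K ∈ {4, 5, 6}` × `P ∈ {-100, -50, -20}`. More negative preferences
produce fewer exemplars and coarser graphs; exemplar count is
monotone in `P` on any fixed tile set.

Numerical choices worth knowing:

* a seeded jitter of magnitude 1e-6 is added to the off-diagonal
  similarities to break exact grid symmetries; results are
  deterministic given `(points, P, seed)`;
* messages are damped (0.9) with convergence declared after 50
  iterations of a stable exemplar set, counted only after a
  100-iteration burn-in — under heavy damping the exemplar sign
  pattern looks stable long before the messages have actually
  propagated; non-convergence returns the current exemplars with a
  warning rather than failing a batch run;
* after convergence a medoid refinement pass alternately reassigns
  tiles and re-picks each cluster's exemplar as the member maximizing
  the within-cluster similarity sum. On clustered configurations this
  lands on the exhaustively optimal exemplar subset (the test suite
  checks tiny cases against full enumeration); on unstructured uniform
  point sets message passing can settle in a local optimum — an
  inherent property of AP, not a defect of the implementation;
* KNN distance ties break toward the lower node index after a
  canonical row-major sort of tiles, so graphs are invariant to input
  tile order.

Empty compartments yield a valid zero-node graph flagged `empty`; a
single tile yields one node and no edges.

## SNA features (91 per graph)

Six node-level metrics are computed on each graph: node degree (ND),
local clustering coefficient (CL), closeness centrality (CC), degree
centrality (DC), Katz centrality (KC) and community structure (CS),
plus the graph-level network density NED = 2m/(n(n−1)). Each
node-level metric is summarized by a 10-bin histogram plus mean,
population standard deviation, maximum, minimum and median — 15 values
per metric, 6 × 15 = 90, plus NED: a 91-dimensional vector in a fixed,
named order (`ND_hist_0 … NED`).

Conventions chosen where a convention was needed:

* histograms are binned over the per-graph `[min, max]` range and
  emitted as frequencies (counts/n), so graphs of different sizes are
  comparable; an all-equal metric collapses to frequency 1 in bin 0;
* the standard deviation is the population (n-denominator) form, which
  is defined for single-node graphs;
* closeness uses the component-size-scaled convention
  `CC(v) = ((n_c−1)/(n−1)) · ((n_c−1)/Σd)` because KNN graphs can be
  disconnected; isolated nodes score 0;
* Katz solves `(I − αA)x = β·1` with `β = 1` and
  `α = min(0.1, 0.85/λ_max)` by default, guaranteeing convergence of
  the underlying walk series; the result is scaled to unit Euclidean
  norm, and an `α` beyond the spectral bound is an error;
* CS assigns each node its community's size divided by `n`, with
  communities from greedy (CNM) modularity maximization implemented
  with an explicit smallest-member-index tie-break and the coarsest
  partition preferred on equal modularity. Because that tie-break is
  index-based, CS is relabel-invariant only up to modularity-gain
  ties; the other five metrics and NED are exactly invariant under
  node permutation.

Empty graphs produce an all-zero vector flagged invalid rather than an
error, so cohort-level matrices keep one row per patient.

## Deep tile scores (DLPS)

Tile embeddings (1,024-dimensional, from any frozen encoder — the
encoder is an interface, not part of the package) are scored by a
lightweight MLP (1024 → 256 → 64 → 1, ReLU, dropout 0.25, sigmoid)
trained per compartment under weak supervision: every tile inherits
its patient's slide-level pCR label. Training uses Adam (learning rate
1e-4, batch 512) with a stratified 80/20 patient-level split and early
stopping on validation loss (patience 20, at most 500 epochs),
deterministic given the seed. Tile scores are aggregated per
compartment into mean and population standard deviation; the TIL entry
pools the iTIL and sTIL tile scores rather than training a sixth
model. Five compartments × 2 = 10 DLPS values per patient; an empty
compartment contributes (0, 0) and a missing flag. The MLP engine is
a small in-package implementation (BLAS matrix ops) because no
installed package offers multi-hidden-layer training with Adam,
dropout and early stopping.

## Hierarchical integration and classification

Each compartment model sees a 99-dimensional vector: 91 SNA features,
the compartment's 2 DLPS values, and 6 shared clinical covariates (ER
status and percentage, PR status and percentage, CEP17, HER2/CEP17
ratio) in a fixed documented order. Compartments are modelled
*independently* — features from different compartments are never mixed
into one model, avoiding cross-compartment collinearity and keeping
attributions tissue-specific.

Fitting (`fit_response_model()`): features are z-scored, LASSO
(L1-penalized logistic regression, penalty chosen by stratified
5-fold cross-validation) selects the nonzero-coefficient features,
and an MLP classifier is grid-searched over hidden sizes
{(32), (64), (64, 16)} × L2 {1e-4, 1e-3, 1e-2} by mean stratified
5-fold CV AUC, then refit on the full training data. Inside every CV
fold of the evaluation harnesses, standardization and LASSO are refit
on the fold's training part only, so no selection information leaks
into validation folds. If CV-optimal shrinkage removes everything, the
smallest penalty retaining at least one feature is used; if nothing
survives at all, the classifier falls back to the full feature set.
All randomness (folds, initializations, subsampling) is seeded.

Evaluation reports AUC by the rank (Mann–Whitney) formulation with 0.5
credit for ties, and F1/PPV/recall/NPV at a 0.5 threshold (no
operating point is tuned). Correlated AUCs are compared with the
DeLong test (via pROC; a zero-variance difference returns p = 1 with a
warning). Univariate screening uses the Mann–Whitney U test (normal
approximation, tie-corrected) for continuous features and the
chi-square test for categorical ones — for 2×2 tables the continuity
correction is applied only when an expected count is below 5 — with
Benjamini–Hochberg FDR adjustment. Feature-vs-RIS associations use
Spearman rank correlation (average ranks, t-approximation p).

# The synthetic cohort generator

The generator is first-class code, not a test fixture: it emulates the
structure the pipeline consumes so that every stage is exercisable
without slide data.

* **Tissue geometry.** One tumor disc (core-needle biopsies typically
  present a single focus per fragment) placed uniformly on the grid
  interior, with a surrounding stromal band. Necrosis is sprinkled
  inside tumor at rate 0.04.
* **Planted spatial effect.** iTIL/sTIL tiles are placed by a
  clustered parent/offspring (Matérn-style) process whose intensity
  and cluster scale depend on the response group. Defaults: responders
  carry a heavier infiltrate (iTIL rate 0.14 vs 0.04, sTIL 0.25 vs
  0.06 of eligible tiles) in tight clusters (scale 1.5 vs 7 tiles) —
  the clustered-vs-dispersed contrast that makes stromal architecture
  predictive. A per-patient lognormal dispersion latent multiplies the
  group's cluster scale.
* **Embeddings.** Isotropic unit-variance Gaussians per tile whose
  mean shifts along a fixed random direction per compartment by
  `embedding_effect` (default 0.5 SD) for responders.
* **Clinical covariates.** ER/PR Bernoulli with mild group shifts,
  lognormal CEP17, and a HER2/CEP17 ratio whose log-mean is 0.4 higher
  in responders. Residual infiltration size (RIS) is 0 for pCR
  patients and lognormal otherwise, positively coupled to the same
  dispersion latent that shapes the tile map — so feature-vs-RIS rank
  correlations have recoverable signal by construction.
* **Cohort defaults.** n = 150 with pCR prevalence 0.42, echoing a
  development cohort of comparable size.

What the generator does *not* emulate: staining and scanner variation,
tile misclassification noise, adipose/artifact regions, correlated
(non-isotropic) embedding structure, multifocal disease, or any
relationship between clinical covariates and spatial structure beyond
the RIS coupling. Passing the recovery tests therefore shows that the
pipeline can extract a planted mesoscale signal end-to-end — not that
real slides carry such signal, which only the original cohorts can
show.

# Problem sizes used in the test and acceptance harnesses

The package's own harnesses run on scaled-down instances chosen to
keep a full run on one CPU comfortable: recovery and null experiments
use 36×36 grids (tumor radius 7, stromal band 5) with n = 200 patients
split 80/20, 20 replicate seeds each; the sensitivity grid uses n = 60
and the single-configuration classifier; the ablation uses n = 200
with fractions 20–80% averaged over repeated subsampling seeds; DLPS
demonstrations use 20×20 grids with 12 patients. Only grid and cohort
sizes are scaled; the planted effect parameters are the generator
defaults.

# Known limitations

* AP is an approximate maximizer; oracle-exactness is only guaranteed
  (and only asserted) on clustered configurations.
* CS is not exactly relabel-invariant at modularity ties (above).
* The tile-level classifiers behind TTA-image construction are out of
  scope; the labelling contract is exercised with oracle chains and
  synthetic ground truth.
* Clinical binaries are z-scored along with everything else before
  LASSO; with 0/1 variables this equals centering plus a scale factor
  and keeps the single-scaler code path simple.
* The per-compartment reading of "tissue-specific MLP classifiers" is
  adopted for DLPS: one tile scorer per compartment, trained on that
  compartment's tiles only.
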