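---
title: "Methods: a receptor-informed cascade for molecular odor prediction"
author: "odorcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a receptor-informed cascade for molecular odor prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Predicting what a molecule smells like from its 2D structure alone has a
hard ceiling: enantiomers such as d- and l-menthol share every
achirality-blind descriptor yet smell noticeably different. Perception,
however, is not computed on the structure — it is computed on the
pattern of olfactory receptors (ORs) the molecule activates. This
package mirrors that biology with a cascade of three models:

1. **Model 1 — binding.** A binary classifier over joint
   (molecule descriptor, receptor descriptor) vectors decides whether a
   molecule binds each receptor of a fixed panel. A sample is a
   (molecule, receptor) pair; a panel of $R$ receptors and $M$
   molecules gives $M \times R$ samples (3843 for the 63×61 reference
   scale). The measured target is log(EC50), the log of the
   half-maximal effective concentration, with the convention that 0
   encodes "no binding" and any value $> 0$ is a binder. The encoding
   admits no negative values, and an unmeasured grid cell is an error
   rather than an implicit 0 — "unmeasured" must never be conflated
   with "non-binding".
2. **Model 2 — binding strength.** A regressor trained *only on the
   binder pairs* predicts log(EC50) from the same joint descriptors.
3. **Model 3 — odor.** One binary classifier per *odor community*
   reads the molecule's activation profile — the ordered vector of
   log(EC50) across the panel — and calls the community present or
   absent.

At predict time the three steps chain: Model 1 screens all $R$ pairs
for a query molecule; Model 2 fills in log(EC50) for the predicted
binders only, every predicted non-binder is set to exactly 0, and
regression outputs are floored at 0 so they cannot collide with the
non-binding code; Model 3 reads the assembled profile. Every profile
entry therefore has exactly two possible sources: the constant 0, or a
floored Model-2 output.

## Descriptors

Molecular descriptors are computed from isomeric SMILES by the RDKit
backend (invoked through a bundled Python helper):
the full 2D physicochemical catalogue (~210 descriptors; columns with
non-finite values are dropped with a warning, and columns constant over
the training set are removed before modeling), Morgan circular
fingerprints (2048 bits, radius 2), the RDKit path fingerprint (2048
bits), and the 166 MACCS substructure keys (the backend's dummy leading
bit is dropped so the block is exactly the catalogue). Morgan hashing
is computed **with chirality folded into the hash**; the generator
default would assign enantiomers identical rows, making
receptor-mediated enantiomer discrimination impossible downstream.

Receptor descriptors come in six k-mer amino-acid-frequency variants —
overlapping k-mer counts for $k = 1, 2, 3$ (1AAF/2AAF/3AAF) and their
proportions (…perc) — plus a flattened one-hot of a pre-computed
multiple sequence alignment (21 states per column: 20 residues and the
gap). Design choices worth noting:

* k-mer vocabularies are the full $20^k$ lexicographic set, never the
  observed subset, so rows are comparable across panels and at
  train/predict time.
* Proportions divide by the window count $L - k + 1$ (they sum to
  exactly 1); a `percentScale` switch emits 0–100 instead.
* Non-canonical residues (X, B, Z) are rejected with the offending
  character and position, not silently remapped.
* The alignment itself is an input (tools such as MAFFT produce it);
  computing alignments is out of scope.

The cascade default uses Morgan + 1AAF for both binding models: one
shared featurization across the cascade and a joint design of ~2k
columns. The paper-scale alternative combinations (e.g. MACCS +
1AAFperc, or 3AAF's 8000-column composition) remain available through
`cascadeConfig()`.

## Odor communities

Free-text odor notes ("minty", "sweet", …) are too idiosyncratic to be
classification targets one by one. They are grouped by community
extraction on the co-annotation graph: nodes are labels, an edge joins
two labels iff at least one molecule carries both, the edge weight
counts such molecules. Partition quality is modularity,

$$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2m}\right)\delta(C_i, C_j),$$

and communities are found by agglomerative greedy maximization
(Clauset–Newman–Moore scheme): start from singletons, repeatedly merge
the community pair with the largest gain
$\Delta Q = 2\,(w_{cd}/2m - k_c k_d/(2m)^2)$, stop when no merge gains.
Ties are broken toward the lexicographically smallest community-id
pair, so results are identical across platforms. Isolated labels remain
their own communities. Labels are normalized only by trimming and
case-folding — relatedness is the graph's job, not string processing's.

Two deliberate choices:

* `graphModularity()` and `greedyModularityPartition()` default to the
  **unweighted** 0/1 adjacency, the form in which modularity is
  classically written; a `weighted` flag enables the weighted
  generalization.
* The **cascade's training path defaults to the weighted form**
  (`cascadeConfig(weightedGraph = TRUE)`). On label vocabularies of
  this size (≈23 nodes, ≈6 communities) the unweighted graph sits at
  the agglomerative resolution limit: a single stray co-annotation
  contributes several parallel weight-1 edges between one community
  pair and triggers a merge, whereas under weights one stray molecule
  cannot outweigh ten consistent ones. We measured partition recovery
  on synthetic studies collapse from near-perfect (weighted) to
  adjusted agreement 0.3–0.7 (unweighted) for exactly this reason.

A molecule's communities follow a majority rule: count its labels per
community and keep every community holding strictly more than 20% of
them, so a molecule with nine labels in one community and a stray label
elsewhere reads as the majority community only. If nothing clears the
threshold (a perfect many-way tie), the largest share wins, ties broken
toward the smallest community index — the rule's intent is that the
molecule has *some* majority community, not none.

Greedy modularity is greedy: on graphs with essentially no community
structure ($Q_{\max}$ near 0) or with communities of two nodes, the
merge sequence can land a few percent below the exhaustive optimum.
This is a property of the agglomerative scheme (the reference CNM
implementation in igraph shows the same gaps on the same graphs), and
the test suite checks optimality on structured families (planted
cliques with few cross edges) while checking faithfulness against the
reference implementation on unstructured ones.

## Class imbalance

Binder pairs are rare (≈8.7% at the reference scale), so Models 1 and 3
rebalance their *training folds only* by clustering undersampling:
k-means++ with $k$ = minority count runs on the standardized
majority-class rows, and from each cluster the one real sample nearest
its centroid is kept (ties toward the smallest index). The output is
exactly balanced, contains only original samples, and is reproducible
from the seed. Evaluation folds are never undersampled — metrics always
describe the natural class distribution. Undersampling is applied once
per outer-training fold; inner (hyperparameter) CV runs on the already
balanced outer-training set, which is the leakage-safe reading.

## Model selection and evaluation

Because the datasets are small, every model is selected and scored by
nested (double) cross-validation: 5 stratified outer folds give
untouched test sets; for each outer fold, hyperparameters are chosen by
5-fold inner CV on the outer-training data only; the refit model
predicts the outer test fold; metrics pool the out-of-fold predictions.
Outer-train/test index disjointness is asserted at run time. The method
panel covers the field's standard span — logistic regression, LDA,
naive Bayes, k-NN, linear/RBF SVM, decision tree, random forest and
gradient boosting for classification; OLS, PLS, ridge, LASSO, elastic
net, linear/RBF SVR, tree, forest, boosting and Gaussian-process
regression for regression — with a `"fast"` profile
({logistic, RF, XGB} / {ridge, RF, XGB}) for routine runs.
Hyperparameter grids are deliberately thin (log-scale steps of 3 in
$\log_2 C$, 5 in $\log_2\gamma$ and $\log_2\epsilon$, decades for
$\lambda$): at a few hundred training samples a 16×31 grid buys
variance, not accuracy. Grids are part of the method definitions and
can be overridden.

Classification metrics are accuracy, precision, recall and F-measure
(the standard harmonic mean); regression metrics are $r^2$, MAE and
RMSE. Zero-denominator ratios return 0 with an `undefined` flag instead
of NaN, so pooled tables never propagate NaN silently; a constant
observed vector makes $r^2$ NA (flagged) while MAE/RMSE are still
returned. Auxiliary specificity and balanced accuracy are also
reported: Model 1 selects its method by F-measure (the conventional
headline under heavy imbalance), while the per-community odor models
select by **balanced accuracy**. The reason is visible in the
extremes: at a community prevalence of ~0.2, selecting by F rewards
classifiers that over-call the community (accuracy sinks toward 0.6),
selecting by plain accuracy rewards never calling it at all (the
constant "absent" classifier wins), and balanced accuracy is the
criterion that requires being right on both sides.

## The synthetic study generator

No public dataset ships with the package; instead `generateStudy()`
emulates the statistical shape of a small molecule×OR screen, and the
whole pipeline is validated by recovery of planted ground truth. The
generator's defaults are the study conditions: 63 molecules × 61
receptors, ≈8.7% binders (333/3843), 23 odor labels in 6 communities,
binder log(EC50) spanning [3, 7] with Gaussian noise `noise_sd = 0.3`
(a value consistent with sub-0.5 RMSE regression being attainable but
not trivial), label corruption `label_noise_rate = 0.02`.

What is planted, and why it looks the way it does:

* **Molecules** come from a curated list of 218 real odorant SMILES
  (esters, terpenoids, aldehydes, pyrazines, thiols, lactones …), so
  cheminformatics featurization is meaningful; random SMILES strings
  are too often invalid. Configs larger than the list extend it with
  simple homolog series.
* **Receptors** are random canonical-alphabet sequences of GPCR-like
  length (290–330), drawn in composition families — each family
  perturbs the base amino-acid frequencies and strongly enriches one
  signature residue, the way OR subfamilies share composition bias.
* **Binding** follows chemotype × receptor-competence structure: six
  mid-prevalence Morgan bits mark binding chemotypes; one receptor
  family is the binding-competent pool; a pair binds iff the molecule
  carries any chemotype bit and the receptor is in the pool. Within
  the pool each receptor has bimodal sensitivities to the chemotypes
  (a strong set and a weak-but-nonzero set, plus one dedicated
  signature receptor per chemotype), which grades binding strength and
  gives every chemotype a receptor-level signature in the profile.
  The generator scans 200 seeded motif draws and keeps the most
  community-balanced draw that hits the target rate (±20%), covers
  ≥60% of molecules, and keeps chemotypes mostly exclusive (≤30%
  multi-chemotype molecules), as real chemical classes are.
* **Noise** enters twice, both controlled by `noise_sd`: Gaussian
  noise on binder log(EC50) values, and a detection flip rate
  $q = \tfrac12(1 - e^{-\sigma/4})$ (≈0.04 at the default) that flips
  pair status with the flip-in rate balanced to preserve the expected
  binder count. At $\sigma = 0$ the binder set is a deterministic
  function of the features; as $\sigma \to \infty$ it degrades to
  random — the test suite uses this to verify that saturating noise
  collapses learned performance to baseline (a leakage guard).
* **Odor truth**: a molecule's communities are the chemotypes it
  carries (equivalently, thresholded linear readouts of its noiseless
  profile via the pseudo-inverse of the pool sensitivities). Its
  observed label set is four labels drawn from the *dominant*
  community's pool (rotating so every label gets used), then corrupted
  at the label noise rate. Molecules that bind nothing carry no labels
  and no planted community, as in real screens where part of the panel
  has no odor annotation. Label sets deliberately reflect only the
  dominant community: in measured trials, secondary-community label
  draws at any rate we tried merge planted communities under greedy
  modularity (adjusted agreement 0.54–0.77), while the multi-community
  ground truth is kept in `true_assignments` for evaluation and the
  majority-share rule is exercised by direct unit tests.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: real OR sequence phylogeny, real
structure–affinity relationships (binding is planted on fingerprint
bits, not physics), assay-specific noise structure, label vocabulary
drift between annotators, and molecules whose odor arises from
receptors outside the panel. The generator targets statistical shape
only; green tests certify the machinery, not olfaction.

## Numerical and degenerate-input policy

* Merge gains are accepted only above `1e-12`; zero-gain merges are
  refused (Q must strictly increase).
* k-means++ falls back to a single nearest-initial-center assignment
  when a Lloyd iteration empties a cluster (every center is a real
  sample, so each cluster keeps at least its seed point).
* Methods that error on a given design (e.g. LDA when $p > n$) are
  dropped from the panel with a warning rather than aborting the run.
* A community with fewer than two molecules on either side gets no
  classifier and is reported as "not assessed" at predict time.
* All randomness flows from a single seed through a labelled
  seed-derivation scheme, so sub-generators are independently
  reproducible and identical seeds give byte-identical studies.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the generator at its
default scale (63×61 grid, 80 extra held-out molecules), train the
cascade with the fast method panel under 5×5 nested CV, and evaluate
50 held-out molecules end-to-end; property suites use 100–1000 random
cases per invariant and exhaustive partition enumeration up to six
nodes. These sizes were chosen so a full run completes comfortably on
a single CPU while leaving every statistical check adequately powered.

## Known limitations

* The cascade inherits Model-1 errors: a false-positive binder invents
  a profile entry, a false negative zeroes one; Model 3 is trained on
  measured profiles (as the underlying method prescribes) and is
  therefore sensitive to systematic Step-1/Step-2 drift.
* No applicability-domain estimation: a query far outside the training
  chemistry still receives a confident-looking profile.
* Linear SVM/SVR on wide unscaled binary designs can be slow to
  converge in libsvm; the fast profiles avoid them for the 2k-column
  binding designs and keep them where they shine (profile-width
  designs).
* The >20% majority rule can discard genuinely present minority
  communities when a molecule is annotated very unevenly.
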