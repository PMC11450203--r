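---
title: "Predicting clone-specific drugs and doses from single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting clone-specific drugs and doses from single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneRx)
```

## The problem

Advanced tumors are mosaics of genetically distinct malignant subclones
mixed with normal cells. A therapy that inhibits one subclone may leave
another intact, and a therapy that inhibits everything is toxic. cloneRx
implements a translational strategy for this setting: from a single
scRNA-seq count matrix of a patient sample, identify the malignant
subclones, describe each one by its differential expression against the
patient's own normal cells, and use a model pre-trained on public
perturbation/viability screens to rank drugs *and doses* that
selectively inhibit each subclone — then pair the top hits into two-drug
combination plans.

The package has three layers:

1. a **reference/model layer**: assembling a training corpus that links
   drug perturbation signatures to dose-interpolated viability outcomes,
   and a dose-aware gradient-boosted regressor of percent inhibition
   with conformal confidence;
2. a **patient layer**: QC, normalization, clustering, marker typing,
   expression-derived CNV, ensemble malignant-vs-normal calling, broad
   subclone detection, and clone-versus-normal signatures;
3. a **pharmacometrics layer**: the assay mathematics used to validate
   such predictions (plate-control normalization, 4PL fits, ZIP synergy
   on dose matrices, DSS, ROC/AUC with DeLong comparison).

Everything is testable offline because the package ships its own
generative model of both the reference database and the patient sample.

## The response model

### Training corpus

Each training row describes one (drug, cell line, dose) perturbation:

- the **signature**: log fold changes over a fixed landmark gene panel
  (default 200 genes; the real-world analogue uses ~1000 landmarks, 200
  keeps tests fast and loses nothing structurally);
- the **fingerprint**: a fixed-length binary structure descriptor
  (default 256 bits synthetic; 1024+ in real ECFP4 mode via
  `fingerprint_from_smiles()`);
- **log10 dose**;
- the target: **percent inhibition**, obtained by interpolating the
  drug's viability curve in that cell line at the perturbation dose.

Interpolation is linear in log10-dose on the viability scale, with no
extrapolation: a perturbation dose outside the measured span of the
matching curve is skipped and counted, never invented. Interpolated
viability `v` becomes the bounded regression target `100 - v`, clipped
to [0, 100] (growth stimulation above 100% viability maps to zero
inhibition). We deliberately do not re-fit a sigmoid through the curve
points at this stage; raw-point interpolation is the most conservative
reading, and curve fitting lives where it belongs, in the
pharmacometrics layer.

### Regressor and uncertainty

`fit_inhibition_model()` fits gradient-boosted regression trees
(xgboost, histogram splits, single-threaded so a seed fixes the result).
Hyperparameters are chosen by randomized search — 8 draws from a grid
over tree count (100/200), depth (4/6), learning rate (0.1/0.3),
minimum leaf weight (1/5/20), feature fraction (0.5/0.8) and row
subsample (0.8/1) — scored by grouped 3-fold CV RMSE. Folds are always
grouped by (drug, cell line) pair: rows of one pair are near-duplicates
across doses, and splitting them across folds would leak. The chosen
configuration is then assessed by repeated grouped cross-validation
(3 repetitions × 10 folds); the pooled out-of-fold absolute residuals
are kept as the conformal calibration set, and the model is refit on the
full table. The trimmed search budget is a deliberate choice for
single-CPU reproducibility; the search/CV/calibration contract does not
depend on it.

Uncertainty is split-conformal and global: the interval half-width is
the ceiling((n+1)·0.9)-th order statistic of the calibration residuals,
and `confidence = 1 - halfwidth/100`. Predictions with confidence below
0.8 are discarded (`conformal_filter()`), and predicted doses above
1 µM are discarded (`apply_dose_cap()`) — high doses inhibit normal
cells too, so the cap is a selectivity device, not a performance one.
We read the published exclusion rule ("nonconformity score < 0.8") as
"confidence < 0.8 excluded", the only direction compatible with
discarding *low-confidence* predictions; this interpretation is applied
once, here, and nowhere re-interpreted.

### Why the synthetic reference has target classes

The generator organizes drugs into target classes (default 10 classes
over 50 drugs). A class owns a module of 15 landmark genes with signed
effects, a transcriptional responsiveness factor, and a structural
fingerprint template from which its member drugs deviate by 10% bit
flips. A perturbation signature is the class module scaled by
responsiveness × fractional inhibition, plus Gaussian noise; viability
follows a per-drug Hill curve scaled by a per-cell-line sensitivity.

The class structure is not decoration. If every drug had a private
module, the booster could read inhibition directly off the signature
magnitude and ignore the fingerprint entirely — and then a fixed
patient signature would receive the *same* prediction for every drug,
making ranking meaningless. Shared fingerprint bits within a class and
class-level responsiveness make the fingerprint informative and force
the model to learn signature × structure interactions, which is exactly
the mechanism that drug ranking for a patient signature relies on. The
synthetic patient plants, for each malignant clone, the module of one
class (amplitude comparable to a strong perturbation response), so the
drugs of that class are the ground-truth matched treatments — the
end-to-end recovery tests measure their enrichment at the top of the
ranking.

What the generator does *not* emulate: batch effects, doublets, ambient
RNA, cell-cycle structure, inter-drug correlations beyond class
membership, and assay-specific viability artifacts. Green tests
therefore demonstrate that the machinery is correct and the mechanism
learnable, not that the model transfers to any particular real screen.

## The patient pipeline

`call_clones()` chains the steps; each is exported and testable alone.

- **QC** (`qc_filter`): detected-gene bounds (default 200–6000,
  configurable — published per-sample bounds vary) and a mitochondrial
  UMI fraction cutoff, 10% by default, 20% customary for organoids.
- **Normalization** (`lognormalize`): per-cell scaling to 10,000
  counts, then log1p.
- **Clustering** (`cluster_cells`): top variable genes, PCA, a shared
  nearest-neighbour graph, Louvain communities. Deterministic under a
  seed. The implementation computes exact neighbours from distances,
  appropriate up to a few thousand cells.
- **Marker typing** (`marker_score`): specificity-weighted standardized
  marker expression per cluster; a marker listed for every cell type
  gets weight zero; a cluster whose best score falls below
  (cluster size)/4 is "Unknown". Built-in panels: the synthetic
  generator's markers, an AML blast/T-cell panel, and a PAX8+ ovarian
  panel (`default_marker_db()`).
- **CNV profiles** (`infer_cnv_profiles`): a deliberately simplified
  analogue of HMM-based CNV callers with the same contract — per-cell
  smoothed, reference-centred relative expression along genome order,
  plus arm-level segment means. Genes below mean expression 0.1 are
  dropped (the conventional 10x-data cutoff). Three numerical details
  matter and were decided after watching the naive version fail on its
  own synthetic data:
  1. *Depth-conditional centring.* log1p-normalized expression drifts
     nonlinearly with sequencing depth, so each gene is centred on a
     quadratic-in-log-depth fit over the reference cells rather than a
     flat reference mean; otherwise clustering groups cells by depth
     and calls the shallow ones aneuploid.
  2. *Per-cell mean centring* removes residual library-composition
     offsets (the median is pinned at the zero-count mode in shallow
     cells and does not).
  3. The moving-average window defaults to about a third of the typical
     arm gene count, capped at the conventional 101 genes: a window
     wider than an arm smears arm-level events away. Profiles are
     winsorized at ±3 reference SD.
- **Malignancy ensemble** (`call_malignant_ensemble`): majority vote of
  three classifiers, mirroring the marker-based / segmentation-based /
  clustering-based tool trio it replaces: (i) the marker vote of the
  cell's cluster; (ii) an aneuploidy-score vote, where Ward clades of
  CNV profiles are scored by centroid mean-squared arm mean against a
  depth-matched bootstrap null built from the reference cells —
  clade-level pooling is essential, since a single cell's arm means sit
  only ~2 SD from zero at realistic noise; (iii) two-way k-means on arm
  means with the near-zero cluster called diploid, kept as the weakest
  voter. Reference (known-normal) cells are anchored by marker-typed
  normal clusters, the synthetic counterpart of using T cells as the
  known-normal population.
- **Subclones** (`detect_subclones`): Ward clustering on arm-level
  means of the malignant cells, cut into two clades — automated stand-in
  for the published visual tree reading. A split only counts if the top
  merge height is at least twice the next one; a homogeneous population
  merges at near-constant heights (observed ratio ≈ 1.1 versus ≈ 6 for
  planted clones), and forcing k = 2 there would invent subclones.
  Clades under 5% are "minor"; equally sized clades are ordered by
  lower mean intra-clade distance. The emitted Newick tree uses branch
  lengths proportional to clone fractions — an abundance diagram, not a
  molecular clock.
- **Signatures** (`compute_signature`): per gene, log2 of the ratio of
  (mean de-logged expression + 1) between clone and normal cells, a
  two-sided Wilcoxon rank-sum p-value and BH q-value. Genes expressed
  in under 10% of both groups or with |log2FC| < 0.25 are excluded —
  the standard defaults of the cited single-cell DE tooling, adopted
  because no parameters are published. `landmark_signature()` maps the
  result onto the model's landmark order (missing landmarks → 0).

When the malignant fraction falls below 10%, fewer than 40 malignant
cells are found, or the subclone split is degenerate, the pipeline
switches to monotherapy mode: one pooled malignant-versus-normal
signature, top-20 ranked drugs — mirroring practice on samples with
small tumor-cell populations, where subdividing the malignant
compartment adds noise rather than signal.

## Therapy design

`rank_for_clone()` predicts over the drug library × dose grid (default
0.01–1 µM, half-log steps), applies the confidence filter and dose cap,
keeps each drug's best surviving dose (ties to the lower dose), and
sorts. `design_combinations()` enumerates the top-k (default 6) of each
clone's list, drops pairs sharing a drug, and ranks by the unweighted
mean of the two predicted inhibitions — no pair-scoring formula is
published, and the symmetric mean is monotone in both components, which
is all the ranking requires. Each drug carries a dose bracket note (one
dilution step below and above the predicted dose) for assay design. An
optional selectivity filter drops drugs predicted ≥ 50% inhibition on a
user-supplied normal-cell signature; it is off by default because that
readout is experimental practice, not part of the computational
contract.

## Pharmacometrics

- `percent_inhibition()`: 100·(DMSO − raw)/(DMSO − total-kill),
  unclipped so over-killing stays visible; errors if the controls are
  degenerate.
- `fit_hill()`: 4PL least squares in an algebraic parameterization that
  evaluates to the bottom asymptote at dose 0, multi-started from a
  deterministic grid (every positive dose × slopes 0.5/1/2/4), with
  soft asymptote bounds [−10, 110]. Flat data short-circuits to a
  zero-slope fit; total failure falls back to a monotone log-dose
  interpolant, flagged.
- `zip_score()`: Bliss-referenced delta — 4PL-fitted margins, expected
  fractional effect f1 + f2 − f1·f2, observed minus expected averaged
  over interior cells (optionally a dose region), ×100. This is a
  simplified variant of the original potency-shift formulation: it is
  exactly zero under Bliss independence from its own margins, which is
  the null the validation uses, and > 10 reads as synergy in the
  published convention. Margins with fewer than three points are used
  raw (a 4PL is not identifiable there).
- `dss()`: normalized area of the fitted curve above a 10% activity
  threshold over a log10-dose window — the threshold-integral reading
  of "normalized AUC"; the finer distinctions between published DSS
  variants are not resolvable from a one-line description and are not
  attempted.
- `roc_auc()` / `delong_test()`: standard rank-statistic AUC and paired
  DeLong comparison (via pROC); identical score vectors return p = 1 by
  convention rather than NaN.

## Problem sizes, defaults and degenerate inputs

The shipped study conditions are: reference 50 drugs × 20 cell lines ×
8 doses (log-spaced 0.001–10 µM), viability noise SD 5, signature noise
SD 0.15; patients with 600 cells × 2000 genes, clone fractions
0.4/0.35/0.25, each clone carrying one arm gain (×1.5) and one arm loss
(×0.5) and one planted class module. These sizes make the full suite
(including one model fit) run in minutes on a single CPU while keeping
every mechanism — interpolation, grouped CV, conformal coverage at
n = 2000, clade pooling, enrichment testing — at a scale where its
statistics are meaningful.

Degenerate inputs are contracts, not surprises: zero-count cells error
in normalization; all-cells-removed QC errors; missing normal reference
errors; under-sized groups error in DE; empty signatures are refused by
the ranker; an all-filtered prediction set raises rather than silently
returning nothing; homogeneous malignant populations degrade to
monotherapy mode.

## Known limitations

- The CNV analogue has no HMM states and no genome segmentation beyond
  arms; focal events narrower than the smoothing window are invisible.
- Conformal intervals are global, not locally adaptive; confidence does
  not vary across chemical space.
- The neighbour search in clustering is exact and quadratic in cells;
  beyond ~10⁴ cells an approximate-neighbour backend would be needed.
- Synthetic fingerprints encode class membership, not chemistry; the
  real-SMILES mode exists but inherits whatever bias the 4096-bit
  folding introduces.
- Monotherapy/combination mode switching is rule-based (fraction floor,
  cell floor, merge-height ratio); borderline samples near those
  thresholds deserve manual review, which is the published stance too.
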