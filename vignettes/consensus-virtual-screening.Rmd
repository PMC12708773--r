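---
title: "Consensus fingerprint-based virtual screening for xanthine oxidase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus fingerprint-based virtual screening for xanthine oxidase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Xanthine oxidase (XO) catalyses the oxidation of hypoxanthine and
xanthine to uric acid; its inhibitors (allopurinol, febuxostat) are the
mainstay treatment for gout and hyperuricemia.  Plant extracts rich in
polyphenols and hydrolysable tannins often inhibit XO, and untargeted
LC-QToF-HRMS annotation of such extracts yields dozens of candidate
metabolites — far too many to assay blindly.  `xovscreen` implements a
ligand-based virtual screening pipeline that prioritises those
candidates with an ensemble of fingerprint-based classifiers trained on
a curated library of known XO actives and inactives, and supplies the
exact-mass arithmetic used to annotate the metabolite tables in the
first place.

## The pipeline

1. **Curation.** A labelled SMILES table is parsed with OpenBabel;
   records that cannot be encoded are removed and counted, and
   duplicate structures are collapsed on the canonical SMILES computed
   from the parsed graph (first occurrence wins).  Input spelling never
   matters; stereo layers are retained, so stereoisomers stay distinct
   compounds.  Conflicting labels on one structure are an error rather
   than a silent choice.
2. **Fingerprints and diversity.** Five encoding schemes are supported:
   MACCS-167 and ECFP4/ECFP6 folded to 1024 or 2048 bits.  Bits are
   binary presence indicators.  Structural diversity is profiled with
   the Tanimoto coefficient Tc = |A∩B| / |A∪B| over all unordered
   distinct pairs; a library in which most pairs fall below Tc = 0.4 is
   structurally diverse, which is the regime where a similarity-based
   applicability domain is informative.
3. **Split.** A two-stage stratified draw removes a test partition of
   ⌈0.15 n⌉ records, then an equally sized validation partition, leaving
   the remainder (70%) for training.  Largest-remainder apportionment
   keeps per-class proportions within one compound of the global
   balance.  For n = 483 this gives 337/73/73.
4. **Models.** One gradient-boosted tree classifier (XGBoost,
   `binary:logistic`) per scheme, selected by grid search on validation
   accuracy **subject to** an overfit-spread constraint: any
   hyperparameter point whose train/validation accuracy difference
   exceeds 5 points is discarded before selection.  The test partition
   is never consulted during selection; `stability_report()` exposes
   the three-way spread afterwards.
5. **Applicability domain and consensus.** A screening candidate is
   in-domain iff its average molecular weight lies in 200–700 Da and
   the mean Tc to its five nearest training compounds (ECFP4-1024) is
   at least 0.4.  In-domain candidates are voted on by all five models
   at probability threshold 0.5; at least 3 of 5 active votes make a
   consensus active.  Decoy validation spikes known actives back into
   the screen and checks each model recovers them.
6. **Mass annotation.** Theoretical negative-mode adduct m/z values
   ([M−H]⁻, [M+Cl]⁻, [M+HCOO]⁻, [2M+Na−2H]⁻) are computed from
   molecular formulas with an embedded isotope-mass table, and ppm
   errors against measured values as (measured − theoretical) /
   theoretical × 10⁶.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| AD weight window | 200–700 | Da | drug-like metabolite range; below it similarity is dominated by trivial fragments, above it the training library has no support |
| AD neighbours k | 5 | compounds | mean over a handful of neighbours is robust to a single coincidental match |
| AD similarity floor | 0.4 | Tc | conventional "same series" threshold for ECFP4-1024 |
| decision threshold | 0.5 | probability | no calibration is performed, so the natural cut |
| spread constraint | 0.05 | accuracy | flags memorisation; 5 points is large enough to survive 73-record validation noise |
| consensus majority | 3 of 5 | votes | strict majority of the five schemes |
| grid axes | see `default_grid_axes()` | — | 11,340-point Cartesian product; `reduced_grid_axes()` is an 18-point subset spanning weak (5 trees, depth 2, η = 0.001) to strong (100 trees, depth 6, η = 0.1) learners |

The reduced grid is the default for simulation studies and the
command-line `train` subcommand; it exists so that the spread
constraint always has satisfiable candidates (a pure-noise library
rejects every strong learner) at a small fraction of the full grid's
cost.  The full grid remains available via `--grid full` or
`enumerate_grid()`.

## Numerical and convention choices

* **Metric orientation.** `classification_metrics()` uses the standard
  confusion-matrix orientation, precision = TP/(TP+FP) and recall =
  TP/(TP+FN).  A `"swapped"` orientation (denominators exchanged) is
  available because that variant occasionally appears in print;
  accuracy and F1 are identical under both.
* **AUC** is the Wilcoxon rank statistic with midrank tie handling, so
  a constant predictor scores exactly 0.5.
* **All-zero fingerprints.** Tc of two all-zero vectors is defined as
  1 (identical absence of features) with a warning; real encodings
  never produce this.
* **Tie-breaks in selection**: higher validation AUC, then fewer
  estimators, then lower depth, then grid order — so selection is
  deterministic.
* **Ion arithmetic** ignores the electron mass (hydrogen-atom
  arithmetic).  This reproduces the 0.00-ppm rows of the shipped
  annotation tables at three decimals; `include_electron = TRUE`
  switches to proton-mass arithmetic for sensitivity analysis.  Note
  the algebraic identity [2M+Na−2H]⁻ = 2·[M−H]⁻ + m(Na).
* **MACCS width.** The OpenBabel MACCS block is 256 bits with keys
  1–166 populated; the scheme takes the first 167 bits, preserving the
  fixed-dictionary semantics at the conventional 167-bit width.
* **ppm display**: errors are reported to two decimals, so relative
  deviations below 0.005 ppm display as 0.00.  The shipped tables'
  printed errors were computed by the original instrument software
  from full-precision measurements; recomputing from the 3-decimal
  printed m/z reproduces only the 0.00-ppm rows exactly, and the
  fixtures document one printing inconsistency (ellagic acid, 300.998
  vs the theoretical 300.999).

## What the synthetic generator emulates — and what it does not

`generate_library()` assembles molecules from 12 fixed scaffold
templates (aromatic and heteroaromatic cores first, aliphatic rings
last) and 12 substituent fragments, the first of which — a
galloyl-like ester — is the designated pharmacophore: a molecule is
active iff it carries it, after which labels are flipped independently
with probability `label_noise`.  Defaults are the study conditions
used throughout the tests: 400 molecules, 45% active (a mildly
imbalanced library), noise 0, 8 scaffolds, 8 substituents, seed 7.
The chemistry is deliberately polyphenol-flavoured so that
galloyl-bearing synthetic actives resemble the hydrolysable-tannin
space of the real application.

`generate_screening_set()` plants three candidate strata with known
applicability-domain outcomes: in-vocabulary copies of in-window
training molecules (pass), structures outside 200–700 Da (fail on
weight), and in-window but out-of-vocabulary exotics such as
perfluorohexane and 18-crown-6 (fail on similarity).

Passing tests on this generator demonstrates that the pipeline
*mechanics* are correct — encoding determinism, constraint
enforcement, vote arithmetic, domain filtering, seeded
reproducibility — and that a clean substructure signal is recoverable
(test AUC ≥ 0.9 across schemes at noise 0, AUC ≈ 0.5 at noise 0.5).
It does **not** demonstrate predictive validity on real XO chemistry:
the implanted rule is a single substituent, whereas real
structure–activity landscapes involve interacting features, activity
cliffs and assay noise that no fragment-vocabulary generator
reproduces.

One property of the null regime deserves a note: with 50% label noise
the five constraint-satisfying models vote close to independent coin
flips, so roughly a third of in-domain candidates still collect ≥ 3
active votes.  Majority consensus suppresses *model-specific* noise
but not *shared* noise, and a screening run should therefore always be
accompanied by the decoy-recovery check rather than trusted on vote
counts alone.

## Problem sizes

The test-suite and acceptance-script simulations use 400-molecule
libraries (plus one 483-record library for the split-size check), the
18-point reduced grid, 10-fold cross-validation on a 120-molecule
library, and 5 decoys — sizes chosen so a full run of every stage
completes in about two minutes on one core while leaving every
selection, filtering and voting code path exercised at realistic class
balance.

## Known limitations

* Fingerprint bit assignments follow OpenBabel's ECFP hashing and
  MACCS dictionary; absolute bit patterns (and hence exact Tc values)
  differ from other toolkits' encodings, although all Tanimoto and
  domain contracts hold within any one encoding.
* The AD similarity floor and weight window are fixed heuristics, not
  fitted; compounds near the boundary deserve manual review.
* No probability calibration, no alternative learners, no
  feature-importance analysis, no docking — scope ends at the
  consensus verdict.
* Mass annotation covers the four negative-mode adducts above;
  positive mode and isotope patterns are out of scope.
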