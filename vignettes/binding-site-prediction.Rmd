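---
title: "Predicting protein-protein binding-site residues from sequence: methods and design notes"
author: "wavePPBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein binding-site residues from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavePPBS)
```

# The problem

Protein-protein interfaces are patches of surface residues that lose
solvent accessibility when two chains associate. Determining them
experimentally requires a solved complex; this package predicts them from
the monomer sequence alone. The prediction target is binary and per
residue: is residue $R_i$ part of a protein-protein binding site (PPBS)?

Two properties make the problem statistically awkward. First, the signal is
local but contextual: whether a residue binds depends on the
physicochemical texture of its sequence neighbourhood, not on its identity
alone. Second, the classes are heavily imbalanced — in residue-level
benchmarks non-interface residues outnumber interface residues roughly 4:1
among surface residues and 9:1 among all residues — so naive training
yields classifiers that under-call binding sites, which are precisely the
interesting class.

# Ground-truth labeling

When per-residue accessible surface areas (ASA) are available (from DSSP or
PSAIA runs on structures; computing ASA is out of scope here, the package
consumes tables), labels follow two strict-inequality rules:

* **surface**: $\mathrm{ASA}(R_i \mid P) / \mathrm{ASA}_{\max}(R_i) > 0.25$,
  with $\mathrm{ASA}_{\max}$ the tabulated maximum ASA of the free residue
  (23 codes: the 20 standard amino acids plus the ambiguity codes B, X, Z);
* **interface**: a surface residue with
  $\mathrm{ASA}(R_i \mid P) - \mathrm{ASA}(R_i \mid PP) > 1\ \text{Å}^2$.

Interface $\Rightarrow$ surface by construction; `readS1Dataset()` rejects
tables violating this. Both thresholds are strict because the defining
inequalities are printed strictly; the boundary cases (exactly 25%, exactly
1 Å²) are therefore negative.

Benchmarks come in two modes: `surface` (only surface residues enter, the
4:1 regime) and `all` (every residue, the 9:1 regime). Positives are
identical between modes.

# Feature construction

## Windows

Each residue is represented by the window $[-\xi, +\xi]$ of the chain
centred on it, $\xi = 7$ by default (15-tuple segments; the default follows
the regime in which this representation was established, and is exposed in
`pipelineConfig(xi = )`). Near the termini the chain is mirror-extended:
the first $\xi$ residues are reflected in front of position 1 and the last
$\xi$ behind position $L$, so every residue — including terminal ones —
gets a full-length window:

```{r}
mirrorExtend("ACDE", 2)
extractWindow("ACDEFGHIKLMNPQRSTVWY", center = 1, xi = 7)
```

Chains shorter than $\xi$ are rejected rather than reflected repeatedly:
the extension rule defines a single reflection per terminus.

## Physicochemical encoding

Seven amino-acid scales encode a window into seven numeric series:
hydrophobicity (H1), hydrophilicity (H2), side-chain volume (V), polarity
(P1), polarizability (P2), solvent-accessible surface area (SASA) and
side-chain net charge index (NCI). Before use, each scale is standardized
to zero mean and unit SD **over the 20 amino-acid types** (not over the
dataset), which makes the scales comparable and the conversion idempotent:

```{r}
tab <- propertyTables()
round(colMeans(tab), 12)
```

The SD in the conversion uses the sample ($n-1$) convention; the choice is
immaterial to every stated property of the conversion (zero mean,
idempotency) and only fixes the overall scale.

Ambiguous residues fall back as B→D and Z→E (B denotes D-or-N, Z denotes
E-or-Q; aspartate/glutamate are the more common members), and X encodes as
0 — the standardized mean, i.e. the least-informative value. This fallback
is our choice; benchmarks rarely contain these codes.

## Stationary wavelet sub-bands

Each length-15 series is decomposed with a 4-level stationary (undecimated)
wavelet transform using the Haar (Db1) filter pair, giving five sub-bands:
the deepest approximation A4 and details D4, D3, D2, D1. The undecimated
transform keeps every band at the input length, so no sequence position is
privileged.

Two details of the transform are not determined by "Db1, five sub-bands"
alone and were fixed as follows:

* **Depth**: five sub-bands require exactly 4 levels ($1 + 4 = 5$).
* **Boundary handling**: the series (length 15) is padded on the right to
  the next dyadic length (16) by half-sample mirror reflection — the padded
  value duplicates the terminal sample, matching the same convention the
  chain-mirroring uses — and the à-trous recursion uses periodic wrap on
  the padded signal (the standard stationary-transform convention, e.g. in
  PyWavelets). The padded column is dropped from every band before return,
  restoring length 15. A plain linear ("periodic-free") convolution cannot
  produce equal-length bands at 4 levels from a length-16 signal (the
  level-4 upsampled filter spans 9 taps), which is why the periodic
  convention was adopted.

The test suite checks the transform against an independent
circulant-matrix implementation of the same convention.

Each sub-band $i$ is summarized by four statistics
$(\alpha_i, \beta_i, \gamma_i, \delta_i)$ = (max, mean, min, SD) of its
coefficients, ordered $\alpha_{1..5}, \beta_{1..5}, \gamma_{1..5},
\delta_{1..5}$ — $\Omega = 5 \times 4 = 20$ components per property and a
$7 \times 20 = 140$-component block per residue. $\delta$ is the
*population* SD (well-defined for bands of any size; the printed source of
the statistic list does not specify a convention). The band order is A4,
D4, D3, D2, D1 (coarsest first); any fixed order is equivalent for the
classifiers.

# Training-set optimization

Two treatments turn a skewed training set into an exactly balanced one.

**KNNC (K-nearest-neighbour cleaning).** Every negative with at least one
positive among its $K$ nearest neighbours is removed. Decisions are taken
in a single pass on the original set (the treatment is described as one
step, not a fixed point). The metric space is the full 140-component
feature block under Euclidean distance — the same representation the
classifiers see — and the neighbour pool contains both classes with self
excluded; both choices are ours, as the treatment's description names
neither the metric nor the pool. The scan over $K$ starts at the
imbalance-ratio heuristic

$$K^{(0)} = \mathrm{Int}\!\left[\frac{N^-}{N^+}\right],$$

which gives 3 for the 4:1 surface-residue regime and 8 for the 9:1
all-residue regime (`initialK(2828, 10943)`, `initialK(2828, 24614)`).

**IHTS (inserting hypothetical training samples).** The minority class is
augmented to exact balance with SMOTE-style interpolation: pick a random
minority member $x$, one of its 5 nearest same-class neighbours $x'$, and
emit $x + \lambda (x' - x)$, $\lambda \sim U(0,1)$. Of the admissible
hypothetical-sample generators, SMOTE was chosen for being deterministic
given a seed, parameter-light, and the field's default. Inserted samples
exist only as feature vectors — they correspond to no real peptide — and
are permanently flagged `hypothetical`, which is what lets the
cross-validation protocol keep them out of test folds. If cleaning leaves
the negatives as the smaller class, augmentation symmetrically fills up the
negatives: the contract is exact balance.

# The ensemble classifier

One random forest per property, each restricted to its own 20-component
slice, yields seven individual predictors $\mathbb{RF}^{(k)}$; they are
fused by voting. Each forest votes positive when its positive-class score
is $\geq 0.5$; the fused label is the majority of the 7 votes (odd count,
no ties), and the fused continuous score — used for ROC — is the mean of
the 7 scores. The fusion framework this follows admits weighted voting;
weights are equal here because no training procedure for them is specified,
and `pipelineConfig(voteRule = )` leaves a hook.

Forest hyperparameters are not dictated by the method: defaults are 100
trees, `mtry` $= \lfloor\sqrt{20}\rfloor = 4$, nodes grown to purity, all
seeded. The forest itself (CART, Gini impurity, bootstrap resampling) is
implemented in compiled code within the package because no tree-ensemble
package is available in the target environment; its behaviour is covered by
its own tests (separable Gaussians, uninformative features, seed
determinism).

# Evaluation

## Metrics

With $N^+$/$N^-$ the class totals, $N_+^-$ the positives called negative
and $N_-^+$ the negatives called positive, the package reports the
error-rate forms

$$\mathrm{Sn} = 1 - \frac{N_+^-}{N^+},\quad
  \mathrm{Sp} = 1 - \frac{N_-^+}{N^-},\quad
  \mathrm{Acc} = 1 - \frac{N_+^- + N_-^+}{N^+ + N^-},$$

and the matching MCC form, which are algebraically identical to the
classical TP/TN/FP/FN formulas (verified numerically on random confusion
tables in the tests). Misclassifying half of each class gives
$\mathrm{Acc} = 0.5$, $\mathrm{MCC} = 0$ — the random-guess anchor. A zero
factor in the MCC denominator yields MCC 0 with a warning (the standard
convention; the defining form does not address it). AUC is the trapezoidal
area under the ROC curve with tied scores grouped.

## Target cross-validation

Optimized training sets are fine to train on but wrong to validate on:
they lack removed experimental negatives and contain hypothetical
positives. The target protocol therefore:

1. splits positives and negatives each into 10 near-equal parts *before*
   any optimization (seeded; stratified by construction);
2. per fold, re-runs KNNC + IHTS on the training portion only and trains
   the full 7-forest ensemble on the balanced result;
3. scores the untouched experimental test fold;
4. pools all fold scores into one confusion table (micro-averaging — the
   protocol substitutes the scores of all 10 rounds jointly into the
   metric formulas) and one ROC curve.

Because the fold split depends only on the seed, a scan over $K$
(`scanK()`) reuses the identical partition, so the $\mathrm{Acc}(K)$ curve
reflects $K$ alone. Ties in the curve resolve toward the smallest $K$
(cheapest cleaning). The jackknife alternative is deliberately not
implemented; 10-fold is the protocol adopted for computational reasons in
the source methodology.

# The synthetic benchmark generator

`fixtureSpec()` / `simulateBenchmark()` produce seeded, fully labeled
benchmarks so every stage is testable without downloads. The generated
world:

* chains of uniform random composition over the 20 amino acids (real
  background composition is deliberately not mimicked — it is irrelevant to
  testing the machinery);
* interface residues laid out as contiguous patches (default 8 residues),
  separated by at least one window width so window labels stay
  unambiguous — mirroring the patch-like geometry of real interfaces;
* patch residues drawn from a softmax-biased distribution
  $p(\text{aa}) \propto \exp(\text{effectSize} \cdot z_{\text{aa}})$ over
  the designated properties' standardized values (default H1,
  effectSize 2), mixed with uniform draws at rate
  $1/(1 + \text{noiseSd})$; with the defaults (noiseSd 0.5) the mean
  standardized H1 of interface residues exceeds that of non-interface
  residues by $\approx 0.6$;
* every interface residue surface; other residues surface with
  probability 0.8; ASA values generated to round-trip *exactly* through the
  labeling rules (exposure ratio in (0.30, 0.90) for surface, (0.02, 0.24)
  for buried; burial > 1.5 Å² for interface, < 0.9 Å² otherwise).

Default sizes (30 proteins of 80–120 residues, positive fraction 1/6)
reproduce the ~3000-window, 1:5 regime used by the signal-recovery checks.

What a green synthetic test does **not** establish: performance on real
interfaces. The generator plants a compositional signal in exactly the
space the features measure; real interface signal is weaker, partly
structural, and correlated with composition in ways the generator does not
model. The synthetic results validate the machinery (features carry the
planted signal; balancing and CV are correct; the ensemble learns), not the
biological accuracy figures, which require the real 99-chain benchmark
tables.

```{r, eval = FALSE}
# the full synthetic signal-recovery run (~2 min):
bm <- simulateBenchmark(fixtureSpec(nProteins = 30, lengthRange = c(90, 110),
                                    positiveFraction = 1/6, seed = 101))
cv <- targetCrossValidation(bm, k = NA, config = pipelineConfig(seed = 7))
cv$metrics
```

# Degenerate inputs and numerical choices

* constant property scale → error (`standardizeProperty`), since the
  conversion divides by the SD;
* chains shorter than $\xi$ → error, not multiple reflection;
* series shorter than 2 → decomposition error;
* augmentation needing a class with fewer than 2 members → error (no
  neighbour to interpolate toward);
* `k = 0` disables cleaning; balanced input passes through augmentation
  unchanged;
* SD of a wavelet band clamps tiny negative round-off to 0 before the
  square root;
* all stochastic steps (fold split, bootstrap, interpolation) run off a
  single integer seed; per-fold and per-forest seeds are derived
  deterministically from it.

# Known limitations

* ASA computation from structure (DSSP/PSAIA) is out of scope; labels
  require precomputed tables.
* The published headline accuracies on the 99-chain benchmark depend on
  its supplementary data file, unstated forest hyperparameters and
  stochastic folds; the package reports full CV reports and
  $\mathrm{Acc}(K)$ curves for inspection rather than asserting those
  numbers.
* Only the Haar (Db1) wavelet and symmetric windows are supported, by
  design.
* Vote weights are equal; the weighted-fusion hook is unimplemented
  surface.
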