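---
title: "Cross-sequence learning for dual-input fracture classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sequence learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Orbital fractures in young patients are screened on plain radiographs, but
radiographs have a high false-negative rate and the definitive modality (CT)
carries radiation cost. A classifier that reliably identifies *normal*
orbits on the radiograph alone could spare many CT scans. OrbitCSL
implements a dual-input strategy for this task: each radiograph is presented
to the model twice — the full image and a region-of-interest (ROI) crop
restricted to the head/orbit area — and the two views are encoded by two
parallel vision-transformer (ViT) branches whose classification-token
features are concatenated and passed to a fully connected head with a
single fracture logit.

**Cross-sequence learning** is the training-time pairing rule at the core
of the package. Instead of always pairing an original with its *own* crop,
each training original is paired with a same-label crop chosen to have the
*lowest* cosine similarity on raw pixel values, and a crop, once chosen,
cannot be chosen again. Formally, walking originals in ascending dataset
order, original $i$ receives

$$j^\*(i) = \arg\min_{j \in C_i} \; \frac{x_i \cdot y_j}{\lVert x_i\rVert\,\lVert y_j\rVert},$$

where $x_i$, $y_j$ are the resampled raw-pixel vectors of original $i$ and
crop $j$, and $C_i$ is the set of crops with the same label as $i$ that
have not yet been used (excluding crop $i$ itself unless it is the last
candidate in its class). Because crops keep the label of their source image
the pair carries an unambiguous label, and the without-replacement rule
maximizes the diversity of (original, crop) combinations the fusion model
sees. At validation and test time pairing is always the identity: each
original with its own crop.

## What the phantom generator emulates — and what it does not

No public radiograph set accompanies this method, so the package ships a
synthetic phantom generator that preserves exactly the structure the method
needs: a global image, an informative ROI crop, and a localized class
signal. Each phantom contains a vertical background gradient, an elliptical
head with a skull outline, and two bright annular orbital rims; positives
carry a rim discontinuity — an intensity drop of amplitude
`fractureContrast` — over an angular window of the rim at the declared
fracture site. The geometry is deterministic; only the additive Gaussian
noise layer is seeded, and it is drawn *before* the label is consulted, so
a positive and a negative render of the same seed differ only inside the
declared fracture region. That property makes signal-locality tests exact.

Defaults mirror the clinical population the phantoms stand in for: 18%
fracture prevalence, and site probabilities equal to the cohort fractions
(floor 116/330, medial 91/330, superior 16/330, lateral 3/330, multiple
104/330). The published rounded percentages (35/28/5/1/32) sum to 101%, so
the generator uses the exact fractions, which sum to one and agree with the
rounded values. `fractureContrast` defaults to 0.4 with `noiseSd = 0.03`
— a visible but not trivial signal (the rim sits at intensity 0.85 on a
0–1 scale); desk-scale studies in the test suite use a strong signal
(contrast 0.7) so that a small CPU-trainable model can separate the
classes. What the phantoms deliberately do **not** model: bone texture,
projection overlap, patient positioning variance, scanner post-processing,
or any realistic fracture morphology. A green phantom suite therefore
demonstrates that the pipeline's machinery is correct — matching, fusion,
optimization, evaluation, localization — not that the architecture reaches
any particular accuracy on hospital radiographs.

## Conventions and parameters that matter

- **Boxes** are 0-based, half-open `(row_min, col_min, row_max, col_max)`,
  row-major — one convention everywhere (ROIs, saliency boxes, CSVs).
  Sample indices in matching plans are 1-based, as is idiomatic in R.
- **Similarity resolution** (default 64): originals and crops have
  different shapes, so both are resampled to a common square grid by
  bilinear interpolation before the cosine is taken. No standardization is
  applied — the similarity is on raw pixel values, so bright-field overlap
  drives the matching, which is the point: the *least* similar same-label
  crop gives the most diverse pair.
- **Greedy order and ties**: originals are processed in ascending index
  order and ties take the lowest crop index. Order changes the plan, so
  the order is fixed and recorded in plan provenance.
- **Self-pairing** is excluded unless a class is down to its last
  candidate; crops should come from other patients whenever possible, and
  the forced-last exception keeps every plan total.
- **Matching frequency**: the plan is computed once per run over the whole
  training split (a pre-training step); `replanEachEpoch` recomputes it
  each epoch, which only matters when augmentation changes the images.
- **Split protocol**: 7:1:2 train/tune/test at the sample level,
  stratified by label with largest-remainder rounding per class; negatives
  in train and tune are randomly subsampled to at most `negPosRatio`
  (default 1) negatives per positive — the test split always keeps the
  natural prevalence. A stratified k-fold driver is provided as the
  alternative protocol; its summary reports both pooled-score AUROC and
  the mean ± sd of per-fold AUROCs, labelled, since the two ways of
  combining folds differ.

## The model and its optimization

Each branch is a standard pre-norm ViT: linear patch embedding, a
prepended classification token, learned positional embeddings, `depth`
blocks of multi-head self-attention and a GELU MLP with residual
connections and layer normalization, and a final layer norm; the
classification-token row is the branch feature. Fusion is plain
concatenation — there is deliberately no cross-attention or other fusion
module — and the head is one hidden rectified layer and a single logit.
The forward and reverse passes are written in plain R matrix algebra and
the analytic gradients are verified against finite differences in the test
suite.

Two architecture profiles are built in. The **desk profile** (input 64,
patch 8, width 48, depth 2, 4 heads) is sized so that a from-scratch model
trains *reliably* on ~50 balanced training images and a complete
generate–match–train–evaluate–localize study on 200 phantoms runs in
minutes on one CPU — deeper, wider encoders at this data scale train
erratically from random initialization. The **full profile** (input 224,
patch 16, width 192, depth 12) is the conventional small-ViT shape for
full-scale runs. Optimization is decoupled-weight-decay Adam with a cosine
learning-rate schedule on mean binary cross-entropy, no pretraining, no
augmentation by default (a horizontal-flip flag exists but is off). The
desk defaults use a peak learning rate of 1e-3 over 40 epochs with batches
of 8: from random initialization the conventional fine-tuning rate of 1e-4
barely moves the parameters in so few updates; 400 epochs remains the
full-scale setting. Model selection takes the epoch with the best tuning
AUROC, with ties broken by lower tuning cross-entropy — the tuning split
of a desk-scale study is small (a handful of cases), its AUROC saturates
early, and the loss tie-break distinguishes among saturated epochs.

A property of this regime worth stating plainly: on desk-scale data the
model separates the classes in *ranking* long before the logit scale
grows — at initialization the classification token is dominated by its
input-independent components and near-uniform attention dilutes a
localized two-patch fracture signal by the patch count, so all
probabilities sit close to 0.5 while their ordering is already
near-perfect. Held-out AUROC is therefore the honest desk-scale
performance measure; the raw probabilities are uncalibrated, and every
operating point in the package (confusion metrics, localization boxes) is
taken from the tuning-set Youden cutoff rather than a fixed 0.5.

## Evaluation stack

All evaluation statistics are computed by the package itself and
cross-checked in the tests against independent oracles (closed-form
trapezoids, exhaustive threshold sweeps, permutation tests, and the pROC
package where it implements the same statistic):

- **AUROC** as the Mann–Whitney statistic (ties ½), identical to the
  trapezoidal area under the empirical ROC.
- **Youden cutoff** over observed thresholds (positive when
  score ≥ threshold), ties broken toward sensitivity — the screening
  application favors ruling out fractures.
- **Confidence intervals** for sensitivity/specificity are exact binomial
  (Clopper–Pearson). This choice is validated by arithmetic: the exact
  interval reproduces a published sensitivity interval at 13/31 to the
  printed precision, where Wilson or Agresti–Coull intervals are far off.
  For PPV/NPV a logit-transform interval is reported alongside the exact
  one, flagged per row, since predictive-value intervals vary across
  statistical software.
- **DeLong test** for paired AUROCs via per-case placement values;
  **McNemar's test** exact below 25 discordant pairs, continuity-corrected
  chi-square above (the conventional switch).
- **Reader studies**: five-point confidence scores (1 = definitely normal
  … 5 = definite fracture) give the AUROC directly as a rank statistic and
  are dichotomized at ≥ 4 for the confusion metrics; sessions are compared
  by DeLong (on the ordinal scores) and McNemar (sensitivity among
  truth-positives, specificity among truth-negatives). The reader table in
  this package treats the evaluated set as the internal test set.

Degenerate inputs are explicit everywhere: a zero-norm similarity vector,
a single-class label vector, or a zero-denominator ratio raises an error
or an `NA`-with-reason — never a silent 0.

## Localization

The reader-assistance overlay uses gradient-weighted class activation
mapping adapted to the ViT: the fracture logit is backpropagated to the
patch-token activations of the original-image branch and each token is
scored by the total magnitude of its gradient-weighted activation,
$\sum_d |A_{td} G_{td}|$ — its first-order contribution strength to the
logit — giving the patch-grid map, which is min-max normalized and
bilinearly upsampled. Two adaptation choices were settled empirically on
trained phantom models, where ground-truth fracture regions make
localization measurable. First, the *layer*: attribution is taken at the
patch-embedding tokens (the first block's input), where token content is
still spatially local; at deeper blocks self-attention has already mixed
the tokens and per-token attribution washes out (near-zero hit rates in
development runs). Second, the *weighting*: the classic formulation that
pools gradients into one weight per channel localized far worse on this
architecture than the per-token magnitude form (channel pooling lets a few
globally-aligned channels dominate every patch), so the per-token form is
the package's formulation. Saliency is computed on the original-image
branch only, because assistance is displayed on the original image.

A bounding box — the tight box of the largest 4-connected superlevel
component at threshold 0.5 — is emitted only when the model's score clears
the operating point; negative predictions get no box. An all-zero
(degenerate) map yields no box. The map is invariant to positive rescaling
of the logit. A documented limitation: on desk-scale training sets (a few
dozen positives) the saliency template concentrates on the *prevalent*
fracture sites — floor and multiple-site fractures localize reliably,
while rare sites (medial ~28%, superior ~5%, lateral ~1% of positives)
are often classified by diffuse evidence and their maps peak at the
common-site locations instead. The localization tests therefore assert
argmax-in-region accuracy for the common sites only.

## Problem sizes in the shipped studies

The test suite and the acceptance script run the complete pipeline on 200
phantoms (64-pixel images, 18% prevalence, contrast 0.7, 7:1:2 split,
1:1 balancing → 50 training images), the scale at which a from-scratch
desk-profile model separates the phantom classes; unit tests use a tiny
profile (16-pixel input, width 16, depth 2). These sizes are the package's
reference study conditions, chosen so the whole suite runs comfortably on
a single CPU.

## Known limitations

- The phantom task is far easier than radiography; held-out AUROC on
  phantoms says nothing quantitative about clinical performance.
- DICOM ingestion is not implemented; datasets enter as PNG + manifest
  CSV (images are min-max normalized on load).
- No learned similarity (the cosine is fixed), no Hungarian-assignment
  alternative to the greedy rule, no multi-reader multi-case variance
  components, and AUROC CIs use the DeLong normal approximation rather
  than bootstrap.
- Whether matching should be recomputed per epoch, and at what resolution
  similarity is best computed, are open questions surfaced as flags
  (`replanEachEpoch`, `similarityResolution`) with fixed, recorded
  defaults.
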