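---
title: "Semi-weakly supervised segmentation and iterative annotation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-weakly supervised segmentation and iterative annotation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Training a segmentation network for volumetric MRI requires per-pixel masks,
and drawing them is the bottleneck: a full segmentation mask takes an expert
roughly fifteen times as long as dragging a bounding box over the same tissue.
`swsal` implements a semi-automatic annotation workflow that gets a usable
pre-annotation model out of *very few* dense masks by combining three sources
of supervision, and then spends the remaining human effort where it matters
most:

1. **Sparse segmentation labels.** Every `(s_int + 1)`-th slice of each stack
   is fully annotated (`select_sparse_slices()`); adjacent MRI slices are
   anatomically similar, so densely annotating every slice is largely
   redundant.
2. **Bounding-box labels on all other slices**, converted to
   pseudo-segmentation masks by seeded region growing
   (`pseudo_labels_for_volume()`), then cleaned up by self-refinement.
3. **A simulated annotator in the loop** (`run_iasal()`): the model predicts
   every slice, slices whose predictions disagree with their neighbours are
   selected, corrected, and fed back into training, round after round, until
   the dataset is fully annotated.

Everything runs on synthetic phantom volumes, so no external dataset is
needed to exercise, test, or extend the pipeline.

## Model and losses

The backbone (`backbone_init()`) is a small U-Net-style encoder–decoder with
two heads: a segmentation head and an auxiliary edge head whose final feature
map is concatenated into the segmentation head's input (edge guidance). It is
deliberately tiny — a few thousand parameters — because the method is
backbone-agnostic: the losses and training schedule attach to any network
that outputs a segmentation map `Q` and an edge map `S` at input resolution.
Forward, backward, and the Adam optimizer are implemented directly on BLAS
matrix products (im2col convolutions, with an Rcpp kernel for the patch
gather/scatter), which keeps training deterministic, dependency-free, and
fast enough for CPU use at phantom scale.

Supervision on dense labels uses the *area loss*

$$L_{area} = L_{BCE}(G, Q) + \left(1 - \frac{2\sum G Q + \epsilon}{\sum G + \sum Q + \epsilon}\right),$$

a pixel-averaged binary cross-entropy plus a soft Dice term, and the *edge
loss*, a weighted cross-entropy on the edge map where the edge-positive term
carries weight $w_0 = \sum E / (WH)$ and the background term $w_1 = 1 - w_0$.
Two implementation notes:

* The printed forms of these cross-entropies in the source literature omit
  the leading minus sign; the implementation uses the standard negated
  (minimizable) form throughout.
* $w_0$ as defined assigns the *small* weight to the rare edge class — the
  opposite of conventional class balancing. The default follows that
  definition verbatim; `weighted_edge_loss(..., swap_weights = TRUE)` (and
  the `edge_weight_swap` backbone option) exchanges the weights for users who
  want conventional balancing. Whether the printed assignment is intentional
  cannot be resolved from the text, so both behaviours are provided.
* Both eps constants (`1e-6` Dice smoothing, `1e-7` log clip) are symmetric
  in the Dice numerator/denominator so that an empty label with an empty
  prediction scores a zero Dice-term loss rather than 1.
* Edge labels follow the 8-neighbour rule (`edge_from_mask()`): a foreground
  pixel is an edge pixel iff at least one of its 8 neighbours is background,
  with out-of-image neighbours treated as background so regions touching the
  border keep their edge.

## The three training stages

`swssl()` fits one binary network per tissue (tissues are treated as
independent binary problems) in three stages:

* **Stage A — sparse training** (`train_stage_sparse()`): minimizes
  `area + edge` loss on the sparsely annotated slices.
* **Stage B — box training with self-refinement** (`train_stage_bbox()`):
  trains on the region-grown pseudo-labels with the area loss only. The edge
  head is frozen — pseudo-edges derived from noisy pseudo-masks would
  mis-teach it — meaning: no edge loss term, no gradient into the edge
  parameters, and no gradient through the edge features into the
  segmentation head. After each of `refine_cycles` cycles, every slice's
  pseudo-label is replaced by the binarized (0.5) network prediction and
  training repeats; originally-empty slices stay empty so no tissue is
  hallucinated where no box was drawn. Stage B continues from the stage-A
  parameters: the refining network has seen the true sparse labels, which is
  what lets refinement distill that knowledge into the pseudo-labels.
* **Stage C — joint training** (`train_joint()`): starts from *freshly
  initialized* parameters (the earlier stages' contribution enters through
  the refined pseudo-labels) and each round `e` runs one pass over the
  pseudo-labelled slices with weight $\alpha = \max((E_{thres}-e)/E_{thres}, 0)$
  and one pass over the sparse slices with weight
  $\beta = \min(e/E_{thres}, 1)$. Early rounds are dominated by the plentiful
  pseudo-labels (high-level localization); by round $E_{thres}$ supervision is
  purely the exact sparse labels, suppressing the residual pseudo-label noise.
  Pseudo-edge labels participate here, derived from the refined pseudo-masks.

"Rounds" are epochs over the training set, which gives the $\alpha/\beta$
schedule a natural granularity; within a round the pseudo pass precedes the
sparse pass, and a pass whose weight is zero is skipped.

## Region growing from boxes

The box is the only localization information, so growth is confined to it.
Seeds are tissue-specific:

* **bone** (compact, bright): the integer centre of the box;
* **cartilage** (thin band): Canny edges are detected inside the box, the
  vertical extent between the top-most and bottom-most edge response is
  measured per column, and the seed is the vertical midpoint of the
  maximal-extent column. The Canny hysteresis thresholds are the 50th/90th
  percentiles of the *gradient magnitude* inside the box (percentiles of raw
  intensity would not be commensurable with a gradient map), with
  `sigma = 1` smoothing; all exposed in `grow_params()`. A box with no edge
  response falls back to the centre with a warning.

Growth admits 8-connected neighbours whose intensity lies within a tolerance
of the running region mean; when no neighbour qualifies, the tolerance is
relaxed by `tolerance_step` (default 0.02 on the `[0,1]` intensity scale,
starting at 0.05). This escalation guarantees the stop rule — region area at
least `0.8 ×` box area for bone, `0.6 ×` for cartilage — terminates on any
image: in the limit the region fills the whole box. The stop-rule phrasing in
the source ("greater than or equal to the boundary box area (0.8 ...)") is
grammatically ambiguous; it is interpreted as *area ≥ ratio × box area*, the
only reading under which both ratios make sense.

## The annotation loop

`run_iasal()` scores each slice by the mean Dice of its (binarized) predicted
mask against its two neighbours' masks (single neighbour at the stack ends;
already-annotated neighbours contribute their true labels; a single-slice
stack scores 0 so it is always corrected). Slices scoring below the round's
threshold `DiceTS` are selected; of the selected slices, every
`(interval+1)`-th is corrected by the simulated doctor (prediction replaced
by ground truth). `DiceTS` rises linearly to 1 over the rounds while the
correction interval steps down to 0, so corrections start sparse on the worst
slices and finish dense; the schedule constructor rejects configurations that
could never annotate everything, and the final scheduled round corrects all
remaining unannotated slices (a slice whose score is exactly 1 would
otherwise never be selected by the strict `score < DiceTS` rule). Retraining
between rounds uses all annotated slices with pure true-label supervision
(the joint machinery at $\beta = 1$), warm-starting from the current
parameters by default (`warm_start = FALSE` gives cold restarts). Defaults
`dice_ts_start = 0.7`, `n_rounds = 5`, `correction_interval_start = 3` cover
the endpoints the method prescribes (to 1, to 0); the per-round grid is a
free choice and is exposed in the schedule constructor.

Workload is accounted in equivalent segmentation slices,
`Seq = Ss + floor(Sbb/15)` (`equivalent_workload()`), using the standard
15:1 segmentation-to-box effort ratio; the exact rational value is attached
as an attribute since the floor is a reporting convention.

## The phantom generator

`generate_phantom()` emulates the statistical structure of sagittal knee MRI
stacks that the method relies on, without any MRI physics:

* **bone**: a single connected, star-convex region (a smoothly perturbed
  ellipse, radius about one fifth of the image) with bright interior;
* **cartilage**: a 2–6 px crescent hugging an arc on top of the bone
  boundary, thickest mid-arc — a band geometry in which any image column
  crosses the tissue once, the regime the per-column seed rule assumes;
* **inter-slice coherence**: centre, radius and orientation follow per-case
  random walks with step size `inter_slice_drift` (pixels), so adjacent
  slices are similar and similarity decays with slice distance; drift 0
  makes all masks of a case identical;
* **intensity realism**: class intensities (background 0.15, cartilage 0.45,
  bone 0.75) plus a smooth low-frequency bias field (amplitude 0.1, mimicking
  coil inhomogeneity), 0.7 px gaussian blur (partial-volume softening),
  per-slice brightness jitter, and additive gaussian noise
  (`noise_sigma = 0.08`), followed by per-case 0–1 standardization. These
  values were chosen once as a plausible DESS-like contrast/noise regime.

What the phantom does *not* emulate: tissue texture (marrow heterogeneity,
cartilage laminae), anatomical variability beyond smooth deformation,
multi-coil artifacts, or more than two tissues. Two consequences matter for
interpreting the test suite. First, the homogeneous tissues make seeded
region growing *unrealistically good* — raw bone pseudo-labels land very
close to the ground truth — so label self-refinement is evaluated at the
model level (does a refined-trained model beat an unrefined-trained model on
held-out cases?), which is also what the original experiments measured,
rather than by comparing label sets, where a small CNN cannot out-sharpen
near-perfect masks. Second, passing property tests on phantoms demonstrates
that the machinery behaves as designed under the assumed slice-coherence
structure — not that the method reaches any particular accuracy on real MRI.

## Desk-scale experiment sizes

The full-scale regime (hundreds of cases, 160 × 384 × 384 volumes, 1000
training rounds on GPUs) is far beyond a desk check. The package's default
phantom is 32 slices of 96 × 96; the property experiments in the test suite
run smaller still — 8 training, 2 validation and 2 test cases of 8 slices at
32 × 32, base channels 4, depth 2, batch size 2, tens to a couple of hundred
rounds, three fixed seeds — which keeps each three-seed experiment to a few
minutes on one CPU. Optimizer defaults follow the full-scale settings
(Adam, learning rate 5e-4, weight decay 1e-4, momentum 0.9, early-stop
patience 20); the experiments disable premature early stopping (patience =
round budget, keeping best-checkpoint selection) because at desk scale the
validation Dice can sit at zero for more than 20 of these very small rounds
before the thin cartilage class emerges, which would freeze training long
before convergence.

## Numerical and degenerate-input choices

* Predictions are clipped to `[1e-7, 1 - 1e-7]` before any logarithm; all
  losses are finite for any input.
* Dice between two empty masks is defined as 1 (agreement about absence);
  needed on slices without tissue.
* Binarization threshold 0.5 everywhere a mask is needed from probabilities.
* Boxes are inclusive `(rmin, cmin, rmax, cmax)`; 1-based inside R, 0-based
  in the on-disk JSON dialect.
* Inputs whose size is not a multiple of `2^(depth-1)` are zero-padded
  internally and cropped back, so the network is shape-agnostic.
* All randomness (phantom, initialization) flows from explicit integer
  seeds; fixed seed and thread count give bit-identical runs.

## Known limitations

* The backbone is a stand-in honouring the dual-head contract, not a
  reproduction of any published architecture; absolute Dice values at
  phantom scale are not comparable to full-scale results.
* Region growing assumes one roughly homogeneous tissue per box; heavily
  textured tissues would need a different homogeneity criterion.
* The simulated doctor corrects perfectly and instantly; real correction
  effort per slice varies with prediction quality, which the workload model
  (15:1, flat) ignores.
* Self-refinement can only help when the network generalizes across slices
  better than the raw pseudo-labels agree with the truth; on data where
  region growing is already near-perfect it is a no-op at best.
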