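---
title: "Connectivity-based cortical parcellation with graph neural networks"
author: "cortexGNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based cortical parcellation with graph neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Parcellating the cortex — assigning every vertex of the reconstructed pial
surface to one of K named anatomical regions — is naturally a *node
classification* problem: the triangular surface mesh defines an unweighted
graph (one node per vertex, one edge per unique triangle edge), and each
node carries a feature vector combining structural morphometry (the vertex
coordinates, cortical thickness in mm, signed mean curvature in 1/mm) with
a dense structural-connectivity profile: a length-642 vector of
conductance values to the vertices of the low-resolution fsaverage3 grid,
where high conductance means a strong white-matter connection. The
question the package is built to study is how much that connectivity
profile adds over morphometry alone.

Three architectures are implemented as explicit propagation rules with
analytic gradients:

* **GCN.** Each layer computes $H' = \sigma(S H W + b)$ with
  $S = \hat D^{-1/2}(A + I)\hat D^{-1/2}$ the symmetrically
  degree-normalized adjacency with self-loops: every node averages its
  neighborhood, degree-corrected.
* **GAT.** Per head $h$, attention logits over each target's
  neighborhood (self-loop included) are
  $e_{ij} = \mathrm{LeakyReLU}_{0.2}(a_{dst}^\top W h_i + a_{src}^\top W h_j)$,
  normalized by a softmax over $j \in N(i) \cup \{i\}$, and features
  aggregate as $h_i' = \sigma(\sum_j \alpha_{ij} W h_j)$. Heads are
  concatenated in hidden layers and averaged at the output, so every
  neighbor gets a learned degree of usefulness.
* **Graph U-Net.** An encoder interleaves GCN blocks with top-$k$ pooling
  (projection scores $y = H p / \lVert p \rVert$, keep the
  $\lceil \text{ratio} \cdot V \rceil$ best-scoring nodes, gate retained
  features by $\tanh y$, induce the subgraph); the decoder unpools by
  scattering features back to their recorded indices and adds skip
  connections, so the output has one logit row per original vertex.

The output layer always emits raw logits for K classes; the loss is the
mean per-vertex cross-entropy (the reference protocol does not state a
loss; this is the standard choice for node classification). Predictions
take the per-vertex argmax with ties broken toward the lower class index.

## Training protocol

`trainModel()` follows the reference protocol: Adam with starting learning
rate 0.01, 100 epochs, batch size 1 (subjects visited singly in a
shuffled order each epoch), fresh Gaussian noise added to the normalized
features at every visit (augmentation s.d. 0.01 by default — no value is
stated in the reference protocol, and 1% of the normalized feature range
is a gentle perturbation), and a reduce-on-plateau scheduler monitoring
the validation loss with factor 0.5 and patience 5 (also unstated
upstream; these are the common defaults). The final-epoch model is
evaluated — no early stopping is described in the protocol, so none is
performed. Training is bit-reproducible under the seed on a fixed BLAS.

`makeSplits()` reserves 8 subjects as the final validation set and
partitions the rest into 5 near-equal folds; with 97 subjects that is
18/18/18/18/17. `runAblation()` trains one model per fold (the fold is
the epoch-validation set), applies each fold's final model to the held-out
subjects, and reports mean ± s.d. of the holdout macro Dice across folds.
Whether the reference tables' spread is across folds or across subjects is
ambiguous, so both are emitted (`sdDice`, `sdSubjects`). Hemispheres are
separate experiments.

Dice is macro (region-averaged) per subject, then averaged: regions absent
from both prediction and truth are skipped, regions present in exactly one
score 0, and a designated unknown label can be excluded.

## The synthetic cohort

Real multimodal cohorts with restricted demographics cannot ship with a
package, so `generateCohort()` builds one with the statistical structure
the pipeline assumes:

* **Geometry.** Each hemisphere is an icosphere: subdivision 3 gives the
  642-vertex fsaverage3 resolution; radius 50 mm approximates brain
  scale. Each subject's mesh is the base sphere displaced radially by a
  smooth bump field, plus vertex noise (s.d. 0.5 mm) and a small rigid
  rotation (angle s.d. 0.05 rad), so coordinates are informative but not
  a lookup table.
* **Parcellation.** K = 35 regions per hemisphere (the Desikan–Killiany
  count) by geodesic Voronoi: K seed vertices, every vertex labeled by
  its hop-distance-nearest seed, ties to the lower seed index — which
  guarantees nonempty, connected parcels. Hop distance rather than
  weighted geodesics keeps this cheap; parcel geometry is not an
  evaluation surface. All subjects of a hemisphere share the atlas
  labeling (real silver-standard labels vary by subject; the shared
  labeling is the desk-scale emulation of their consistent topography).
* **Thickness.** $t_v = \text{base}(l_v) + \beta (\text{age} -
  \overline{\text{age}}) + u + \varepsilon_v$ with per-region baselines
  uniform in 1.5–4.5 mm, planted slope $\beta = -0.03$ mm/year (a
  literature-plausible magnitude of cortical thinning), subject offset
  $u \sim N(0, s^2)$ and vertex noise s.d. 0.3 mm. The offset s.d. is
  solved analytically so the *population* correlation between cohort-mean
  thickness and age is exactly the target (−0.35 by default):
  $r = \beta\,\mathrm{sd(age)} / \sqrt{\beta^2 \mathrm{var(age)} + s^2 +
  \sigma_t^2/V}$, with ages uniform on 22–35 years
  (sd 3.75, close to the 3.70 of a young-adult reference cohort).
  Thickness at or below zero is clipped at 0.1 mm and logged. Note the
  statistical consequence: detecting $\rho = 0.35$ at $n = 97$ with a
  two-sided $\alpha = 0.05$ Pearson test has power $\approx 0.94$, so
  roughly one cohort in sixteen will *correctly* fail to reach
  significance — a property of the planted effect size, not of the
  estimator.
* **Curvature.** A smooth radial bump field (per-region amplitudes of
  random sign, Gaussian kernel of width 2 hops) displaces vertices;
  curvature is $-0.3 \cdot f/\text{amp} - 1/\text{radius}$ plus noise, so
  outward bumps (gyral crowns) are negative and pits (sulci) positive,
  matching the field's sign convention.
* **Connectivity.** A symmetric nonnegative K × K region template with
  within-region strength (≈2.0 plus jitter) strictly above between-region
  strengths (uniform below 0.5); entry $(v, j)$ is the template value for
  $(l_v, l_j)$ plus Gaussian noise (s.d. 0.1, well under the
  within/between gap), clipped at zero. Rows therefore carry block
  structure that identifies the parcel — the mechanism by which
  conductance features dominate the ablation, as a nearest-centroid check
  on raw rows (≥ 90% label recovery) verifies. Diffusion physics is not
  simulated; connectivity is generated directly at region-block level.
* **Demographics.** Ages uniform 22–35; MMSE near ceiling on 28–30, which
  makes MMSE correlations null by construction; education on 12–21 years.
  Left/right records of one individual share demographics. The true
  distributions of the emulated cohort are not public; these are
  configurable defaults, not claims.

Everything derives from one master seed through a stated splitting rule
(`deriveSeed()`, all values below $2^{31}$), so any subject regenerates
independently.

What the generator does *not* emulate — realistic folding geometry,
per-subject label variability, registration error, biophysical diffusion,
longitudinal change — bounds what passing tests show: they demonstrate
that the pipeline's machinery (graph construction, propagation rules,
gradients, training dynamics, evaluation and downstream statistics)
behaves correctly and that planted signal is recovered, not that the
absolute Dice scores transfer to real data.

## Normalization and numerical choices

* Features are min-max normalized per column with extrema pooled over
  *all* vertices of *all* subjects, replicating the dataset-wide
  normalization of the reference protocol — which leaks test statistics
  into training. `fitOnTrain = TRUE` gives the leakage-free variant
  (scaler fitted on non-holdout subjects; unseen values clipped to
  [0, 1]). Coordinates are normalized per axis; whether the reference
  pooled the three axes is unstated.
* Constant columns map to 0 rather than dividing by zero; the scaler
  serializes to JSON and inverts exactly on non-constant columns.
* Activations default to ELU; self-loops are added inside both GCN and
  GAT propagation (the standard formulations); dropout exists but is off
  by default (unstated upstream).
* Degenerate statistics follow fixed conventions: a paired t-test with
  all-zero differences returns p = 1, a nonzero constant difference
  returns the machine minimum rather than 0; the Wilcoxon comparison
  drops zero differences, uses the exact distribution up to 25 pairs and
  the normal approximation with continuity correction above, and returns
  p = 1 when everything ties. Pearson p-values use the t transform with
  n − 2 degrees of freedom.
* The across-region cohort average weights regions equally (not by size);
  absent regions are NA, never zero, and are skipped by the tests or
  imputed by training-fold means in the age-prediction task.
* Hidden widths default to [512, 256] (GCN/GAT, 4 heads) and a narrower
  width-128, depth-3, ratio-0.5 Graph U-Net — the U-Net touches every
  pooled level, so its layers are kept narrower. Printed parameter counts
  of the reference models cannot be uniquely inverted to widths, so
  parameter counts are exposed (`countParameters()`) but not an
  evaluation target.

## Desk-scale experiment sizes

The packaged experiments (tests and `scripts/acceptance.R`) run the
benchmark at sizes a laptop CPU handles comfortably: 20-subject cohorts,
V = 642, K = 35, compact widths (GCN [64, 32]; GAT width 64 with 2
heads), 40 epochs, 4 holdout subjects and 2 folds; the 97-subject cohorts
used for the correlation and age-prediction analyses drop connectivity
generation, which the thickness-only analyses do not need. These are the
package's chosen problem sizes; all of them are parameters.

## Limitations

The synthetic benchmark is deliberately easy for connectivity — block
structure aligned with the label definition — so multimodal Dice
saturates near 1.0 at desk scale; the qualitative ordering
(coordinates < morphometry < multimodal) is the meaningful observable,
not the absolute values. Graph U-Net pooling under tied projection scores
breaks permutation equivariance (ties resolve toward lower indices);
scores are almost surely tie-free for continuous features. Training is
single-threaded dense linear algebra; GPU execution and very large meshes
are out of scope.
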