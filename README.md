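# cortexGNN

Multimodal connectivity-based cortical parcellation with graph neural
networks, in R.

Labeling every vertex of the reconstructed pial surface with one of K
anatomical regions (35 per hemisphere in Desikan–Killiany-style atlases)
is a node-classification problem on the mesh graph. This package builds
that pipeline end to end for researchers studying what structural
connectivity from diffusion MRI adds to surface segmentation over
structural morphometry alone: mesh → graph conversion, per-vertex feature
assembly, three graph architectures trained from scratch, Dice evaluation
with significance tests, and the downstream demographic analyses used to
compare segmentation sources. Because the multimodal cohorts this
workflow targets are access-restricted, the package ships a fully
synthetic cohort generator with the same statistical structure (642-vertex
fsaverage3 hemispheres, 35 Voronoi parcels, thickness with a planted
negative age effect, signed gyral/sulcal curvature, block-structured
nonnegative conductance maps), so every experiment here runs from nothing
but a seed.

## The model

The vertex graph is unweighted: one node per mesh vertex, one edge per
unique triangle edge. Per-vertex features are any subset of the (x, y, z)
coordinates, cortical thickness (mm), signed mean curvature (1/mm,
negative on gyral crowns), and the length-642 conductance connectivity
vector — up to d = 647 — min–max normalized across the cohort. Three node
classifiers are implemented as explicit propagation rules with analytic
gradients (no autograd framework):

- **GCN**: H' = σ(S H W + b), S = D̂⁻¹ᐟ²(A + I)D̂⁻¹ᐟ²;
- **GAT**: multi-head attention α_ij = softmax_j LeakyReLU(a_dstᵀWh_i +
  a_srcᵀWh_j) over each neighborhood incl. the self-loop, h'_i =
  σ(Σ_j α_ij W h_j), heads concatenated (hidden) or averaged (output);
- **Graph U-Net**: GCN blocks interleaved with top-k pooling
  (y = Hp/‖p‖, keep ⌈ratio·V⌉ nodes, gate by tanh y, induce the
  subgraph) and mirrored unpooling with skip connections.

Training follows the reference protocol: Adam (lr 0.01), 100 epochs,
batch size 1, fresh Gaussian feature-noise augmentation per epoch,
reduce-on-plateau scheduling on validation loss; evaluation holds out 8
subjects and cross-validates the remaining subjects five-fold, reporting
holdout macro Dice (2|P∩T| / (|P|+|T|) per region, averaged) as mean ±
s.d. across folds. Downstream, region-mean thickness/conductance are
correlated with age/MMSE/education (Pearson, Bonferroni threshold
α/35 = 0.0014), segmentation sources are compared by paired Wilcoxon
signed-rank on region-wise p-values, and age is predicted from the
length-70 two-hemisphere region vector with a small regressor menu
against the mean-baseline RMSE ≈ sd(age).

## Worked example

```r
library(cortexGNN)

mesh <- buildIcosphere(3)      # fsaverage3-resolution hemisphere
mesh
#> SurfaceMesh: 642 vertices, 1280 faces

cohort <- generateCohort(cohortParams(nSubjects = 10, seed = 1))
cohort
#> CorticalCohort: 10 subject records (left: 10)

res <- runAblation(
  cohort,
  specs   = list(featureSpec(TRUE, TRUE, TRUE, FALSE),   # structural
                 featureSpec(TRUE, TRUE, TRUE, TRUE)),   # + conductance
  configs = list(gat = modelConfig("gat", nClasses = 35,
                                   hidden = 64, heads = 2)),
  hyper   = hyperParams(epochs = 30, seed = 1),
  nHoldout = 2, k = 2)
print(res$table, digits = 3)
#>                               featureSet architecture meanDice  sdDice
#> 1             coords+thickness+curvature          gat    0.858 0.02028
#> 2 coords+thickness+curvature+conductance          gat    0.999 0.00129
#>   sdSubjects folds
#> 1   0.018285     2
#> 2   0.000239     2
```

Adding the conductance features lifts the holdout macro Dice of the GAT
from 0.858 to 0.999 on this 10-subject synthetic cohort — the qualitative
signature the pipeline exists to measure: connectivity carries the bulk
of the labeling information. The downstream analysis on the same cohort:

```r
tbl  <- regionFeatureTable(cohort, "thickness")
demo <- cohortDemographics(cohort)
correlateRegions(tbl, setNames(demo$age, demo$subject))$overall
#>   hemisphere      r     p  n
#> 1       left -0.116 0.749 10
bonferroniThreshold(0.05, 35)
#> 0.001428571
```

At n = 10 the planted negative thickness–age effect is present but not
detectable (p = 0.75) — as it should be; at the full cohort size of 97
the cohort-level correlation is recovered with p < 0.05 in the large
majority of seeds (see the acceptance script's recovery rate).

A thin CLI wraps the same functions for shell use:
`inst/cli/cortexgnn {simulate|train|downstream} --help`-style options are
documented in the script header.

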