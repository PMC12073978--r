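---
title: "Graph lesion-deficit mapping: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph lesion-deficit mapping: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the model it
fits, the parameters that matter, what the synthetic cohort generator
does and does not emulate, the numerical conventions, and the design
choices that were genuinely open.

## The inference problem

Lesion-deficit mapping asks which brain regions are necessary for a
cognitive function, given where focal damage co-occurs with impaired
test performance. The difficulty is that lesions are not random: strokes
follow vascular territories and tumours favour particular sites, so the
spatial pattern of damage carries strong structure of its own. A region
can appear "associated" with a deficit merely because it is habitually
damaged alongside the true substrate. Any credible method must therefore
model the dependence *between* locations, not just the marginal
association of each location with the score.

`gldmap` represents the lesioned brain as a layered graph. Nodes are
atlas parcels. An edge joins two parcels co-damaged in at least
`m_min` patients and carries two weights: the lesion channel
`w_les = support / n` (how often the pair is damaged together) and the
deficit channel `w_def`, the mean healthy-control-anchored deficit
z-score over the co-damaged patients. The mean — not the sum — is used
so that the deficit channel measures *how impaired* co-damaging patients
are, while *how often* the pair is hit lives entirely in the lesion
channel; the two kinds of information are deliberately separated so the
block model can disentangle them.

## Deficit scores

`deficit_scores()` computes `z = (hc_mean − score) / hc_sd` from the
healthy controls' moments, so `z` is in control standard deviations and
positive means impaired. Anchoring to controls rather than to the
patient sample keeps the permutation null honest: patient-anchored
scores would recentre themselves around whatever the lesioned sample
happens to contain. Age, a nuisance covariate, is regressed out of `z`
across patients by default (slope removed, control-anchored level kept);
lesion volume is not regressed by default, since the cohorts this
emulates show no volume-score correlation, but the damage matrix is
available for any additional adjustment upstream.

## The block model and its description length

Structure is inferred with a flat microcanonical stochastic block model
over both weight channels, scored in nats. For a partition into `B`
blocks:

* **Adjacency**: `-1/2 * sum_rs m_rs log(m_rs / (n_r n_s))`, the
  standard microcanonical entropy (diagonal counted twice in the
  symmetric sum, `0 log 0 = 0`), **plus** the cost of transmitting the
  block-pair edge-count matrix, `log C(B(B+1)/2 + E - 1, E)`. The second
  term matters: without it a partition into singletons encodes any
  graph's adjacency for free, and unstructured noise graphs shatter into
  spurious blocks. With it, Erdős–Rényi graphs with i.i.d. weights
  collapse to a single block, which is the behaviour a model-selection
  objective must have (this is asserted in the test suite over seeded
  repetitions, against exhaustive enumeration).
* **Weight channels**: each channel's weights are discretized into
  `n_bins = 8` global quantile bins. Quantile (not fixed-width) bins
  make the marginal bin distribution near-uniform for the graph they are
  computed on, so a graph pays for *conditional* (block-pair) structure
  only. Duplicate break points from tied weights are collapsed, so a
  constant channel has an effective alphabet of one symbol and costs
  nothing. Per block pair the channel pays the exact multinomial
  arrangement count `log(m_rs! / prod_q c_q!)` plus a composition prior
  `log C(m_rs + K - 1, K - 1)`. The exact count is used instead of the
  entropy approximation `m H` because the approximation over-charges
  large blocks for their weight heterogeneity and thereby biases model
  selection toward over-splitting.
* **Partition prior**: `N log B`, a uniform label prior.

Each graph is binned by its *own* quantiles. An earlier variant shared
the test graph's bin edges with the null graph; this is subtly
asymmetric — quantile bins maximize the marginal entropy of exactly the
graph they come from, so the null systematically looked cheaper to
encode — and was replaced after the asymmetry showed up as a negative
bias in null-calibration checks. With per-graph bins the test and null
graphs are exchangeable under no coupling, which is the property the
comparison needs.

The paper-scale machinery this emulates uses nested (hierarchical)
block-model priors from the network-inference literature. We commit
instead to the flat model above because it is fully specified by the
formulas in `description_length()`'s documentation, oracle-checkable by
exhaustive enumeration at small `N`, and sufficient for the
disentanglement logic; hierarchy is reported descriptively as the
agglomerative merge tree (`merge_newick()`), whose first level plays the
role of a first agglomerative grouping of communities.

## Fitting and the null comparison

`fit_sbm()` starts from `B = min(b_max, N)` blocks (singletons when
possible, otherwise a seeded balanced random assignment) and alternates
greedy best merges with sweeps of single-node reassignment, accepting
only strictly decreasing moves, down to one block; the best visited
state wins. Merge ties break on the smallest block-id pair; the seed
controls only the initial assignment and sweep order, so runs are
deterministic. The exhaustive oracle (`exhaustive_oracle()`, Bell-number
enumeration, guarded at `N <= 8`) exists purely as an independent check
of the optimizer; the test suite requires the fitter to attain the
oracle's optimum on 50 seeded random graphs.

`permute_null()` shuffles `z` across patients and rebuilds the graph:
the edge set, supports and lesion weights are identical by construction,
and only the deficit channel is decoupled from anatomy. Both graphs are
fitted with identical settings and compared with
`compare_models()`: `delta = S_null − S_test` in nats is the log
posterior odds in favour of the test model, reported as `e{delta}`.

## Backprojection, intervals, retention

`node_strengths()` projects edges back onto parcels: deficit strength is
the support-weighted mean of incident `w_def` (so better-attested edges
count more), lesion strength the plain mean of incident `w_les`.
`bootstrap_cis()` resamples patients with replacement, rebuilds the
graph and both strengths per replicate, and takes percentile intervals.
When the cohort is supplied (the default path in `gldm()`), each
replicate also resamples the healthy controls and recomputes `z` against
the resampled reference. This matters: the control mean is estimated
from a finite sample, and its error shifts *every* patient's z by the
same amount — a component of uncertainty that patient-only resampling
cannot see. Without it, false retentions concentrate in cohorts whose
control mean happens to be misestimated; with it, the false-retention
rate under a null generator sits at or below the nominal level (the test
suite measures this over seeded cohorts).

A parcel is retained when its deficit interval lies wholly above its
lesion interval (`def_ci_low > les_ci_high`). Two readings of
"intervals that do not cross the lesion weight distribution" were
possible — against the same parcel's lesion interval, or against one
global lesion-weight distribution; the per-parcel reading is stricter
and anatomically local, and is the default. The rule is directional
because `z` is signed (higher = worse): a parcel whose deficit weight is
significantly *below* its lesion weight is not evidence of necessity.
Percentile (not BCa) intervals are used: at the default 1000 replicates
the refinement matters little for a smooth functional, and percentile
intervals are transparent to verify.

## The synthetic cohort: what it emulates, and not

`make_parcel_scheme()` tiles an even-width grid into face-connected
parcels split at the sagittal midplane (default 16×16×16 voxels, 64
parcels); `sample_lesion()` grows unilateral focal lesions by seeded
random region growing; `simulate_cohort()` draws, per patient, a side
(Bernoulli 1/2), a volume (log-uniform between 1% and 15% of the
hemisphere, mimicking the spread of tumour and stroke volumes without
claiming a literature distribution), an age (uniform 20–75; the emulated
cohorts are age-matched, so no group-age structure is simulated), and a
score

```
s = clamp(mu0 - beta * load - gamma * (age - midpoint) + eps, 0, ceiling)
```

with `load` the mean damage fraction over the substrate parcels,
`eps ~ N(0, noise_sd)`. Defaults — 247 patients, 81 controls, a
substrate of all right frontal parcels, `beta = 30` score points at full
substrate damage, `gamma = 0.2` points/year, `noise_sd = 5` points,
`mu0 = 80` on a 0–100 scale — emulate a large reasoning-task cohort with
a right-frontal critical network. The deficit acts through mean damage
fraction (a smooth dose-response), not a binary hit, so recovery can be
tested at graded effect sizes; `eps` is stored in the emitted table so
the generator itself is independently checkable row by row.
`simulate_responses()` adds an item-level logistic layer
(`P(correct) = logistic(s_scale * (score/100 - difficulty))`) over the
constructed ART/DRT/baseline item banks, storing the generating
probability per row.

What the generator does **not** emulate: realistic vascular-territory or
tumour-growth lesion geometry, multi-lesion patients, registration and
segmentation error, non-uniform age structure, floor/ceiling clustering
in real psychometrics, or spatially heterogeneous parcel sizes of a real
atlas. Passing recovery tests on this generator therefore shows that the
inference machinery is sound under its assumed statistical structure —
not that real cohorts satisfy those assumptions.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau` (binarization) | 0.1 | fraction of parcel voxels | "substantive damage". A majority criterion (0.5) leaves focal lesions touching almost no parcel: damaged-parcel counts collapse, edge supports fall to 2–5 patients, and percentile intervals from so few co-damaged patients cannot control false retention (measured directly in development). 0.1 restores informative supports while still ignoring grazing damage. |
| `m_min` | 2 | patients | single-patient edges carry no co-occurrence information. |
| `n_bins` | 8 | quantile bins | enough resolution to expose block structure; composition costs keep it from overfitting. |
| `b_max` | 16 | blocks | agglomeration start; larger values cost time, not correctness, since the schedule descends to B = 1. |
| `n_sweeps` | 3 | sweeps/level | refinement effort per level; 2 suffices at 64 nodes in practice. |
| `n_boot` | 1000 | replicates | percentile intervals stable to well under 10% width change on doubling (asserted in tests). |
| `alpha` | 0.05 | — | 95% intervals, matching the retention rule's intent. |
| `lobe_threshold` | 0.70 | lesion-volume share | the frontal/posterior assignment rule is `>=` at 70% of lesioned voxels. |

## Numerical conventions and degenerate inputs

All description lengths are in nats. `0 log 0 = 0` throughout. DL
comparisons in the optimizer use strict inequality, so plateaus never
cycle; equality of distinct partitions at the same DL is accepted in the
oracle checks. Quantile bins use `findInterval(..., all.inside = TRUE)`;
a constant weight channel degrades to zero cost rather than an error.
Empty graphs (no pair reaching `m_min`) raise a coverage error carrying
the damage sparsity; empty lesions, empty blocks, misaligned grids and
singular ANCOVA designs are rejected with specific errors rather than
propagating NaN. Isolated parcels get `NA` strengths, are excluded from
CIs (replicate counts are reported), and are never retained. Percentages
are exact ratios times 100; the three-way Bonferroni threshold 0.05/3 is
carried at full precision and *reported* truncated to three decimals
(0.016), following the convention of the tables it mirrors.

Group statistics use Type-II sums of squares for the group term (no
interaction modelled): the F compares `score ~ age + group` against
`score ~ age`, which for these designs equals the classical ANCOVA table
and is what the normal-equations oracle in the tests recomputes. Post
hoc pairwise contrasts are taken from the full model's coefficient
covariance at the grand-mean age, then Bonferroni-thresholded. No
homogeneity-of-slopes test runs by default.

## Problem sizes in the test suite

The suite exercises the full study scale where the property under test
needs it: substrate recovery and false retention run on the default
64-parcel, 250-patient cohort with 1000 bootstrap replicates over ten
seeds each; null calibration fits 80 block models (20 seed pairs under
strong coupling and 20 under none) at the same scale; optimizer
correctness uses 50 exhaustive enumerations at up to 8 nodes; interval
coverage uses 200 simulated cohorts of 250 patients against closed-form
strengths. These sizes were chosen so each check has real statistical
teeth while the whole suite completes comfortably on a single CPU.

## Known limitations

* Parcel-level, not voxel-level: desk-scale tractability. A fine parcel
  scheme approximates, but does not reach, voxel resolution.
* Flat SBM with an agglomerative merge tree, not a nested posterior:
  model selection is point-estimate MDL, without posterior uncertainty
  over partitions. The reported intervals are over patients, not over
  block-model posteriors.
* The retention rule compares a z-scale deficit channel against a
  frequency-scale lesion channel; its discriminative power therefore
  rests on the bootstrap intervals, not on any natural commensurability
  of the two scales.
* Complete-case inputs: per-test missingness (and hence varying residual
  degrees of freedom across tests) is not modelled.
* The behavioural module takes registered masks as given; segmentation
  and normalization live upstream.
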