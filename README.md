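# gldmap — graph lesion–deficit mapping with layered stochastic block models

Focal brain lesions are natural experiments: where damage reliably
co-occurs with impaired performance on a cognitive test, the damaged
tissue is a candidate substrate of that function. Classical voxel-wise
lesion–symptom mapping tests each location independently and is blind to
the fact that lesions are spatially structured — vascular territories and
tumour sites damage whole constellations of regions together, so
univariate maps confound the substrate of the deficit with the anatomy of
the pathology. `gldmap` implements a graph formulation of the problem for
researchers in lesion–deficit inference: the brain is modelled as a
network whose nodes are atlas parcels and whose edges carry two weight
channels, and community structure is inferred jointly over both, so that
deficit-linked subnetworks can be disentangled from lesion co-occurrence
structure.

## The model

For patients *i = 1…n* with binary parcel damage *d<sub>ij</sub>* and a
healthy-control-anchored deficit score

&nbsp;&nbsp;*z<sub>i</sub>* = (mean<sub>HC</sub> − score<sub>i</sub>) / sd<sub>HC</sub>  (age regressed out; higher = worse),

every parcel pair (*j, k*) co-damaged in at least *m*<sub>min</sub>
patients becomes an edge with

- lesion weight *w*<sub>les</sub> = support / *n* (co-occurrence frequency), and
- deficit weight *w*<sub>def</sub> = mean *z* over the co-damaged patients.

A flat microcanonical stochastic block model with quantile-binned weight
channels is fitted by agglomerative minimum-description-length descent.
For a partition of the *N* parcels into *B* blocks the description length
in nats is

&nbsp;&nbsp;*S* = *S*<sub>adj</sub> + *S*<sub>les</sub> + *S*<sub>def</sub> + *N* ln *B*,

where *S*<sub>adj</sub> = −½ Σ<sub>rs</sub> *m*<sub>rs</sub> ln(*m*<sub>rs</sub>/*n*<sub>r</sub>*n*<sub>s</sub>) + ln C(*B*(*B*+1)/2 + *E* − 1, *E*)
and each weight channel pays the exact multinomial arrangement count of
its binned weights per block pair plus a composition prior. The same
graph with deficit scores permuted across patients — lesion anatomy
intact, behaviour decoupled — is fitted identically; the difference
Δ = *S*<sub>null</sub> − *S*<sub>test</sub> acts as the log posterior odds
that behaviour is coupled to network structure (reported as "e{Δ}").

Edge weights are backprojected to parcels (support-weighted mean deficit
strength, mean lesion strength), given percentile-bootstrap confidence
intervals (patients and controls resampled), and a parcel is *retained*
when its deficit interval lies wholly above its lesion interval — damage
there predicts deficit beyond what co-occurrence alone explains.

Because the patient data this method targets are not publicly
depositable, the package ships a synthetic cohort generator
(parcellated volumes, region-grown unilateral focal lesions, a hidden
right-frontal substrate with dose-dependent score loss, age and noise
covariates, item-level reasoning-task responses) that reproduces the
statistical structure the analysis assumes, with known ground truth for
validation.

## Worked example

```r
library(gldmap)

sch   <- make_parcel_scheme(c(16, 16, 16), n_parcels = 64, seed = 1)
truth <- ground_truth(sch, effect_beta = 30, noise_sd = 5)   # right frontal substrate
sim   <- simulate_cohort(sch, truth, n_patients = 250, n_controls = 80, seed = 42)
dm    <- damage_matrix(sim$masks, sch)

fit <- gldm(dm, sim$cohort, seed = 42)
print(fit)
#> Graph lesion-deficit map
#> Layered lesion-deficit graph: 64 nodes, 505 edges (250 patients)
#>   w_les in [0.008, 0.080]; w_def in [-1.238, 1.776]
#>   blocks: B = 5 (test), B = 4 (null)
#> Model comparison: test 2216 vs null 2382 nats
#>   delta = 166 nats; posterior odds e166 in favour of test
#>   retained parcels: 17 of 64

rec <- substrate_recovery(fit$map, truth)
#> Jaccard 0.74, sensitivity 0.88, specificity 0.94
```

The test model compresses the data 166 nats better than the
behaviour-permuted null — strong evidence that deficit scores are coupled
to network structure rather than to incidental lesion anatomy — and the
17 retained parcels recover the 16-parcel ground-truth substrate with
Jaccard 0.74. `plot(fit)` shows per-parcel deficit versus lesion strength
with the bootstrap intervals; `coef(fit)` returns the deficit strengths;
`export_parcel_map(fit$map, sch, "map.nii.gz")` writes the retained map
as a NIfTI volume.

The same analysis runs as a staged, config-driven pipeline
(`run_pipeline()`, `report()`, YAML via `default_config()` /
`read_config()`), or from a shell through the thin wrapper in
`inst/cli/gldmap.R`.

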