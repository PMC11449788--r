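# synmorph

Nanoscale synaptic morphology and point-pattern analysis for expansion
microscopy (ExM) and ExM-STED imaging.

## The problem

Tenfold physical expansion of brain tissue makes the postsynaptic density
(PSD) and its subsynaptic protein domains resolvable on ordinary confocal
and STED microscopes. Turning such images into biology requires a chain of
quantitative steps that this package implements as a tested, reusable R
library:

1. **Expansion quality control.** The distance between the presynaptic
   active zone (AZ) and the PSD, measured on line profiles across side-view
   synapses, acts as a local expansion ruler (~500 nm after expansion). Per
   animal, the mean AZ-PSD distance relative to its batch mean gives a
   *correction factor* that divides every downstream length-derived
   measurement (lengths by the factor, areas by its square, volumes by its
   cube).
2. **3D shape fingerprinting.** Probability maps of immunolabeled
   postsynaptic scaffolds (43 x 43 x 120 nm voxels) are thresholded at 0.2,
   segmented into 26-connected objects (border-touching objects excluded),
   reduced to a nine-feature shape descriptor — volume, surface area, volume
   ratio against the moment-equivalent ellipsoid, sphericity
   pi^(1/3)(6V)^(2/3)/A, and five moment invariants of the second central
   moment tensor — and filtered at a 200-voxel minimum volume
   (2 x 200^2 x 500 nm^3 / (43 x 43 x 120 nm^3) = 180.3, rounded to 200).
   The records are log-transformed, centered, scaled, projected onto PC1-3,
   clustered by CLARA with the Gap statistic (firstSEmax) selecting the
   number of clusters, and each scaffold receives a principal-curve
   *pseudotime* as an ordinal proxy for synaptic maturity.
3. **2D subsynaptic particle analysis.** Per-synapse two-channel STED
   images (25 nm pixels): rolling-ball background subtraction (10 px ball),
   maximum-intensity projection, rigid channel alignment by exhaustive
   correlation search, FindFoci-style particle detection (local maxima,
   descending-intensity region growing, saddle merging), basic particle
   properties, Manders colocalization coefficients, mean k-nearest-neighbour
   distance profiles, Ripley's K up to 500 nm (20 px) with isotropic edge
   correction and the summed CSR-deviation scalar, and centre-of-mass
   distances of overlapping particle pairs across channels.
4. **Statistics.** Chi-square tests of cluster composition with
   standardized-residual post-hocs (Bonferroni), a semi-parametric one-way
   MANOVA based on the modified ANOVA-type statistic (MATS)
   `Q_N = N (C ybar)' (C D C')^{-1} (C ybar)` with parametric-bootstrap
   p-values, mixed-design repeated-measures ANOVA for NND profiles
   (Benjamini-Hochberg post-hocs), and two-sample Wilcoxon rank-sum tests.

Because the original imaging data are not publicly accessible, a seeded
synthetic-data generator (`gen_profiles()`, `gen_scaffolds()`,
`gen_mosaics()`) emulates all three input data kinds with known ground
truth; every pipeline stage is validated by recovering the planted
parameters.

## Worked example

```r
library(synmorph)

# simulate line profiles at the two batch separations and derive factors
cfg <- sim_config(seed = 5)
prof <- gen_profiles(cfg)
qc <- summarize_expansion(measure_profiles(prof))
qc$batches
#>   batch mean_distance
#> 1     A      535.9408
#> 2     B      509.7025

# full synthetic run: QC -> shapes -> fingerprint -> particles -> stats
res <- run_pipeline("demo_run", default_run_config(seed = 42))
readLines("demo_run/report.txt")
```

The report of the seed-42 demonstration run prints, among others:

```
[expansion QC] batches: A = 536.6 nm, B = 510.5 nm
[fingerprint] cluster composition chi-square: X2 = 21.328, df = 6, p = 0.001602
[fingerprint] shape MANOVA: MATS = 90.101, p = 0 (alpha 0.01)
[particles] NND RM-ANOVA group effect: F = 68.102, p = 9.522e-07
```

i.e. the batch means recover the generator's 536.7 / 510.4 nm separations,
the planted genotype shift in scaffold morphology is detected by both the
composition chi-square and the shape MANOVA, and the planted spatial
difference between the two genotypes' particle mosaics shows up in the
nearest-neighbour analysis. The `log.txt` of each run records the filter
accounting (objects in = border-excluded + volume-excluded + analyzed).

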