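# sinusoidCT

Simulated propagation-based phase-contrast micro-CT and 3D morphometry
of hepatic sinusoids.

## The problem

Cavernous hemangioma of the liver (CHL), the most common benign liver
tumour, is built from abnormally dilated hepatic sinusoids — vascular
lacunae that grow from the normal 20–30 µm to hundreds of micrometres.
Synchrotron **in-line phase-contrast imaging** (ILPCI, also called
propagation-based imaging) resolves these lacunae in fixed tissue
without any contrast agent: the x-ray beam (16 keV, λ ≈ 0.7749 Å)
traverses the sample, picks up a phase shift
φ = −(2π/λ)∫δ dz and attenuation B = (2π/λ)∫β dz from the complex
refractive index n = 1 − δ + iβ, and free-space propagation over
z = 1 m converts phase gradients into intensity fringes on a 9 µm
detector. In the near field the intensity obeys the
transport-of-intensity relation I\_z ≈ e^(−2B)(1 − (λz/2π)∇²φ), so
tissue boundaries are strongly edge-enhanced. Combining ~10³
projections over 180° with filtered back projection (FBP) yields 3D
volumes in which each sinusoid can be segmented and measured:
minimum/maximum diameter, surface area, volume, and the volume
fraction of intraluminal thrombi.

`sinusoidCT` recreates this entire workflow in silico, with known
ground truth at every stage, so that the imaging model, the
reconstruction and the (deterministic, seeded) segmentation can be
validated quantitatively. For whom: people developing or teaching
phase-contrast CT analysis pipelines, and anyone who needs a
self-contained, reproducible test bed for 3D vascular morphometry.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic CHL phantom (δ/β volumes + ground-truth labels, mild/moderate/severe grades, thrombi) | `makeSinusoidPhantom()`, `addThrombus()`, `groundTruthMorphometry()` |
| Coherent optics: exit wave, Fresnel propagation, TIE approximation, virtual scan with flats/darks and Poisson noise | `projectRefraction()`, `fresnelPropagate()`, `tieIntensity()`, `acquireDataset()` |
| Detector corrections | `flatDarkCorrect()`, `ringCorrect()`, `smoothSinograms()`, `edgeEnhance()` |
| Parallel-beam FBP (Ram–Lak / Shepp–Logan / Hann) | `fbpSlice()`, `reconstructVolume()` |
| Seeded deterministic segmentation of lumina and thrombi | `segmentSinusoids()`, `segmentThrombus()` |
| Per-sinusoid morphometry and cohort summaries | `measureSinusoid()`, `measureAllSinusoids()`, `thrombusFraction()`, `summarizeMorphometry()` |
| One-command pipeline with YAML config, logging, manifests, CSV output, ground-truth comparison | `runPipeline()`, `compareToTruth()`, `defaultRunConfig()`, `readRunConfig()` |

Morphometric definitions: volume = voxel count × voxel volume;
surface area = marching-tetrahedra isosurface of the (smoothed) binary
mask; minimum diameter = largest inscribed ball (distance transform);
maximum diameter = maximum Feret (largest pairwise surface distance);
thrombus fraction = thrombus voxels / cavity voxels × 100, with the
thrombus counted as part of the cavity.

## Worked example

```r
library(sinusoidCT)

cfg <- defaultRunConfig()          # noiseless 64^3 demo, 90 angles
cfg$seed <- 5
cfg$phantom$nSinusoids <- 2L
cfg$phantom$diameterRange <- c(100, 180)
res <- runPipeline(cfg, outputDir = "demo_run")

res$summary
#>          descriptor         mean           sd             formatted
#> 1      min_diameter     130.3675 3.163247e+01          130.37±31.63
#> 2      max_diameter     264.9985 1.815540e+01          265.00±18.16
#> 3      surface_area  118841.9899 5.268360e+04    118841.99±52683.60
#> 4            volume 3655935.0000 2.465029e+06 3655935.00±2465029.39
#> 5 thrombus_fraction       0.0000 0.000000e+00             0.00±0.00

res$comparison$perLumen[, c("true_label", "dice", "rel_err_volume")]
#>   true_label      dice rel_err_volume
#> 1          1 0.9704945     0.05318544
#> 2          2 0.9696262     0.04458599
```

Two sinusoid lumina were generated, scanned, reconstructed, segmented
and measured: both are recovered with Dice ≈ 0.97 and volumes within
about 5% of the phantom's ground truth. The summary table is the
cohort "mean±SD" report (micrometre-based units: µm, µm², µm³;
thrombus fraction in percent). The run directory contains
`morphometry.csv` (one row per sinusoid), `summary.csv`, TIFF stacks
of every volume, a stage-by-stage `manifest.json` with file hashes,
`config.yaml` and `log.txt`; rerunning with the same config and seed
reproduces byte-identical CSVs.

A thin command-line front end is installed at
`inst/scripts/sinusoidct.R`
(`Rscript sinusoidct.R run --config cfg.yaml --out rundir`).

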