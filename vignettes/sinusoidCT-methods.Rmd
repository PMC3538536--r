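---
title: "Simulated in-line phase-contrast micro-CT of hepatic sinusoids: models and methods"
author: "sinusoidCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated in-line phase-contrast micro-CT of hepatic sinusoids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Cavernous hemangioma of the liver (CHL) is a benign tumour whose tissue
is dominated by abnormally dilated hepatic sinusoids — vascular lacunae
that in CHL reach diameters of hundreds of micrometres, against
20–30 µm in normal liver. Synchrotron in-line phase-contrast micro-CT
(propagation-based imaging, 16 keV, 9 µm detector pixels, 1 m
sample-to-detector distance) resolves these lacunae in formalin-fixed
tissue without contrast agent, and their 3D morphometry — minimum and
maximum diameter, surface area, volume, intraluminal thrombus
fraction — quantifies disease severity.

`sinusoidCT` recreates that study entirely in silico so that every
stage can be tested against known ground truth: a phantom generator
stands in for the tissue samples, a coherent-optics forward model for
the beamline, and deterministic algorithms for the interactive
segmentation used on real data. The package's own acceptance study
(`scripts/acceptance.R`) runs the complete chain and reports how well
the morphometry of a 20-lumen phantom is recovered.

# The phantom

`makeSinusoidPhantom()` builds paired 3D fields of the x-ray refractive
index decrement $\delta$ and absorption index $\beta$
($n = 1 - \delta + i\beta$) on an isotropic voxel grid (default 9 µm,
matching the detector pitch), with ground-truth integer labels for
every lumen. The tissue is a cylinder (the samples sit in cylindrical
holders); lumina are unions of randomly oriented ellipsoids and capsule
segments — the capsules supply the tortuous, canaliform class of
sinusoid — whose minimum-axis diameters are drawn uniformly from a
configurable range (default 120–400 µm, within the dilated-sinusoid
regime). Lumina are placed two voxels clear of the sample wall:
the lacunae of interest are intra-tumoral structures, and a wall-touching
cavity would be indistinguishable from the holder boundary in any
modality.

Severity grades control dilation and contact:

* **mild** — lumina pairwise non-adjacent (no 26-neighbourhood
  contact), modest elongation;
* **moderate** — contact allowed, stronger elongation, so lumina
  conglutinate;
* **severe** — strong elongation plus iterative dilation of the union
  until the lumen fraction of the tissue cylinder exceeds 0.55
  (lacunae dominate the tumour). Merged lacunae are relabelled as
  26-connected components.

Default optical constants at 16 keV are plausible soft-tissue-scale
values (parenchyma $\delta = 4\times10^{-7}$, $\beta = 2\times10^{-10}$;
lumen $3\times10^{-7}$ / $1.5\times10^{-10}$; thrombus
$4.5\times10^{-7}$ / $2.5\times10^{-10}$). No measured constants for
CHL tissue exist at this energy; only the presence of contrast matters
to the pipeline, and the constants are configuration, not physics
claims. `addThrombus()` converts the innermost fraction of a lumen
(by distance from its boundary) to thrombus material, so a spherical
lumen at fraction $f$ receives the concentric sphere of relative radius
$f^{1/3}$.

Everything is bit-deterministic in the seed. Ground truth for recovery
tests is produced by `groundTruthMorphometry()`, which applies the same
voxel-based descriptors as the measurement stage to the clean labels;
recovery errors therefore isolate imaging, reconstruction and
segmentation effects from voxelisation effects.

# Optics

The beam is modelled as ideal, monochromatic, parallel and fully
coherent. For each projection angle `projectRefraction()` forms the
exit wave from parallel-beam line integrals,
$$B = \frac{2\pi}{\lambda}\int \beta\, dz, \qquad
  \varphi = -\frac{2\pi}{\lambda}\int \delta\, dz ,$$
with $\lambda = hc/E$ (0.7749 Å at 16 keV). `fresnelPropagate()` then
propagates the complex wave $\psi = e^{-B + i\varphi}$ over the
sample-to-detector distance $z$ with the angular-spectrum kernel
$H(u,v) = \exp\!\left(-i\pi\lambda z (u^2+v^2)\right)$ and records
$I = |\psi_z|^2$. This exact propagator was chosen over the linearised
weak-object transfer function
$$\hat I_z = \delta_D - 2\hat B\cos(\pi\lambda z f^2)
            - 2\hat\varphi\sin(\pi\lambda z f^2)$$
for two reasons: at $z=0$ it reproduces the contact image $e^{-2B}$
exactly rather than $1-2B$, and at the phase steps the phantom implies
(several radians across a lacuna) the linear form produces negative
intensities that cannot drive Poisson counting statistics. The linear
transfer function is retained in the test suite as an independent
oracle, and the two agree closely in the weak-phase limit.
`tieIntensity()` implements the transport-of-intensity near-field
approximation
$$I_z \approx e^{-2B}\left(1 - \frac{\lambda z}{2\pi}\nabla^2\varphi\right),$$
whose Laplacian term is the textbook explanation of the edge
enhancement that makes sinusoid boundaries visible; tests verify
second-order convergence of the TIE image to the full propagator as
$z \to 0$ and the appearance of the paired overshoot/undershoot fringe
at the beamline geometry, against the closed-form 1D Fresnel
edge-diffraction solution (Fresnel integrals) as an independent
oracle.

`acquireDataset()` mirrors the acquisition protocol: 1200 projections
over 180° by default (tests and the acceptance study use 300 over 180°
to stay desk-scale), 20 flat fields, 10 dark fields, Poisson counting
noise on an open-beam level of `flatCounts` photons per pixel (default
5000 — the actual photon flux of the 75 ms exposures is not known, so
exposure is represented only through this level), Gaussian read noise
(SD 2 counts) and a dark-current offset. A smooth ±5% detector gain
map is available (`gainVariation`) and defaults to uniform.

# Detector corrections and reconstruction

`flatDarkCorrect()` forms relative transmission
$T = (P - \bar D)/(\bar F - \bar D)$ from pixelwise flat/dark means and
patches dead pixels from their 3×3 neighbours. `ringCorrect()` removes
stationary per-column offsets (the source of ring artifacts) by
subtracting, per detector pixel, the deviation of its angle-mean from a
running-median trend across columns. The trend window is deliberately
narrow (9 columns): genuine detector bias is a one-column defect,
whereas an object feature near the rotation axis also produces a
column-stationary trace — with a wide window that trace is mistaken for
bias and the feature is erased from the reconstruction. For the same
reason ring correction runs *before* Gaussian projection smoothing
(`smoothSinograms()`, default σ 1.5 px), which would smear one-column
bias beyond repair. `edgeEnhance()` provides unsharp masking for
display, after reconstruction.

`fbpSlice()` implements standard parallel-beam filtered back
projection: the band-limited Ram–Lak kernel ($h_0 = 1/4$,
$h_n = -1/(\pi^2 n^2)$ for odd lags) applied in the frequency domain
with zero padding to twice the detector width (Shepp–Logan and Hann
apodisations available), then linearly interpolated backprojection
about the centre column, scaled by $\pi/n_\text{angles}$. Transmission
is clamped to $10^{-6}$ before the logarithm. Phase fringes are
reconstructed as-is — no phase retrieval — so interfaces carry
bright/dark rims; these rims are not an artifact to remove but the
main signal the segmentation exploits. Oracle tests: an analytic
uniform-disc sinogram reconstructs with interior mean within 2% and
RMSE below 5% of the disc value; frequency-domain filtering equals
brute-force spatial convolution to $10^{-6}$.

# Segmentation

The study this package recreates segmented lumina interactively; the
replacement must be deterministic. The difficulty is that at realistic
photon counts the *interior* absorption contrast of a lumen is below
the per-voxel noise, while the *boundary* rims are strong; and the
parenchyma background carries slowly varying ripple that defeats any
single global threshold. `segmentSinusoids()` therefore works in a
detect-then-refine fashion:

1. **Support.** The sample is scanned in a cylindrical holder, so the
   tissue support is fitted as a cylinder to the largest connected
   component of an Otsu split (air vs tissue) of a heavily smoothed
   copy; smoothing makes the split immune to the rim dipoles, and the
   geometric fit is immune to the wall halos that break topological
   hole-filling.
2. **Seeds.** On a copy smoothed by `detectSigma` (default 2.5 voxels),
   voxels more than `detectK` (2.5) robust standard deviations — a
   quartile-based spread of the deep tissue core, so the parenchyma
   mode sets the scale — below the tissue median are candidate lumen
   interior. An opening of depth 2 removes thin rim shells, wall halos
   and noise filaments; components above four times `minVoxels`
   survive. Seeds are then shrunk to their distance-transform interior
   so that detection blur cannot push them past the true boundary.
3. **Refinement.** For each seed a local threshold is set halfway
   between the seed median and the local parenchyma median (midpoint
   thresholding; the antisymmetric rim dipole pins the midpoint
   crossing to the interface). Seeds merged across a thin septum by
   the detection blur are re-split on the thresholded mask. All seeds
   then grow by synchronous competitive dilation (26-connectivity,
   bounded iterations) inside the thresholded region — competing
   regions split contested bridge voxels instead of engulfing one
   another. Per label, a closing of depth 2 seals gaps in the captured
   shell and hole filling recovers the sparse interiors of large
   low-contrast lumina; intraluminal thrombi, which reconstruct
   *brighter* than parenchyma, thereby remain part of the cavity.
4. Components below `minVoxels` (default 27 = 3³) are discarded and
   labels are numbered by decreasing size.

On noise-free two-valued volumes the procedure reduces to exact
threshold recovery. `segmentThrombus()` then tests each lumen's
interior intensities for bimodality (Sarle's coefficient above 5/9)
and, where present, marks the denser Otsu class as thrombus.

# Morphometry

Definitions follow the descriptors reported for CHL sinusoids, which
the original analysis software left unspecified; the package uses two
complementary operationalisations that bracket the intuitive notions:

* **volume** — voxel count × voxel volume;
* **surface area** — marching-tetrahedra triangulation of the
  0.5-level isosurface of the binary mask after a 1-voxel Gaussian
  smoothing (raw-mask mode available); smoothing avoids the ~8%
  staircase overestimation of voxelised surfaces;
* **minimum diameter** — diameter of the largest inscribed ball, twice
  the maximum of the Euclidean distance transform;
* **maximum diameter** — maximum Feret diameter, the largest pairwise
  distance between surface voxel centres;
* **thrombus fraction** — thrombus voxels as a percentage of the full
  cavity (the thrombus counts as part of the sinusoid interior; the
  alternative, excluding it from the denominator, is not used).

`summarizeMorphometry()` reports the cohort mean and sample
(n−1 denominator) standard deviation per descriptor, rendered
"mean±SD" with two decimals, the format in which such studies report
e.g. minimum diameters of 205.66±60.10 µm. On a digital ball of radius
20 voxels the descriptors agree with the analytic sphere to 2%
(volume), 3% (area) and 5% (diameters).

# Problem sizes, tolerances, defaults

The package's own validation study (test suite and
`scripts/acceptance.R`) uses a 240³-voxel phantom (2.16 mm cylinder at
9 µm voxels) with 20 mild-grade lumina spanning 120–400 µm, scanned
with 300 projections over 180° at 5000 photons/pixel — a desk-scale
analogue of the beamline protocol chosen so a full run completes in
minutes on one CPU; the angular sampling is below the Nyquist
requirement for the detector width, which FBP tolerates gracefully for
these smooth objects. Under these conditions every lumen is recovered
with Dice ≥ 0.9 and the median absolute relative errors are ~1% for
volume and diameters and ~1% for surface area. The thrombus study uses
a single 300 µm lumen carrying a concentric thrombus of 16.86% cavity
fraction, the ratio reported for a real CHL thrombus, and recovers it
from the noisy reconstruction to within about 1.5 percentage points
(a slight systematic overestimate from the smoothed-field midpoint
boundary).

Numerical choices worth knowing: Fresnel propagation pads the wave
field twofold (unit amplitude) before the frequency-domain product;
transmission is clamped at $10^{-6}$ before the logarithm; Otsu
thresholds use 256 histogram bins; connectivity is 26-wise everywhere;
all RNG flows through per-stage seeds derived from one global seed, and
two runs with the same configuration produce byte-identical CSVs.

# What the simulation does and does not show

The generator reproduces the geometry and contrast *scale* of CHL
tissue, not its histology: there are no cell cords, no Kupffer cells,
no lobule architecture, no sub-resolution texture, and the optical
constants are plausible rather than measured. The beam is perfectly
coherent and monochromatic; partial coherence, detector blur and
polychromaticity — all of which damp real fringes — are out of scope, as
are phase retrieval and iterative reconstruction. Passing the recovery
tests therefore demonstrates that the pipeline's algorithms are
correct and unbiased at realistic noise for objects of this scale; it
does not certify performance on real beamline data, where fringe
visibility, sample inhomogeneity and segmentation ambiguity are less
favourable.

Known limitations: lumen-free *noisy* volumes can yield a few spurious
small components (the seed gate is calibrated to reject lumen-free
noise-free reconstructions; fully separating noise blobs from genuine
small lacunae at SNR ≈ 1 per voxel is not attempted); severe-grade
conglutinated masses segment as one labyrinthine component, which is
anatomically faithful but means per-lacuna statistics are only
meaningful for mild/moderate grades; and unsmoothed noiseless
reconstructions of very small volumes can over-grow lumina through
secondary fringe rings, which the default projection smoothing
suppresses.
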