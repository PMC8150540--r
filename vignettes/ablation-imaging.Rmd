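---
title: "Differential microwave imaging of thermal ablation: model, inversion and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential microwave imaging of thermal ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwablate)
```

## The monitoring problem

Microwave ablation (MWA) destroys liver tumours by heating tissue through
an interstitial applicator. As the treatment progresses, the heated zone
passes through characteristic dielectric states: healthy liver (high
permittivity and conductivity), coagulation necrosis (moderately lower),
and finally a carbonized core (much lower). Microwave imaging (MWI) aims
to follow this evolution in real time by measuring how the treated region
scatters low-GHz electromagnetic fields.

`mwablate` emulates, entirely in software, a bench experiment for such a
monitor: a linear array of 8 antennas immersed in a lossy coupling medium
(relative permittivity 23, conductivity 0.07 S/m — an effective model of
the abdomen that maximizes power transfer into the liver) faces a
nested-ellipsoid phantom whose two compartments (outer 60 × 40 × 40 mm,
inner 34 × 13 × 13 mm) are filled with stage-dependent tissue-mimicking
materials. Every antenna transmits in turn while all receive, giving an
8 × 8 scattering matrix per frequency at 600, 800, 1000, 1200 and
1400 MHz. Seven scenarios are modelled: the empty reference `s0` and the
stages `a` (pre-treatment), `b` (ongoing) and `c` (completed), each
without (`1`) or with (`2`) the 1.5 mm ABS shells a 3D-printed phantom
would require. The scientific question behind the shells: does the
plastic mould perturb the measurement enough to invalidate the phantom
experiment as a stand-in for an ex-vivo one?

## Forward model

### Dielectrics

Materials are evaluated as complex equivalent permittivities under the
engineering `exp(+j omega t)` time convention,

$$\varepsilon_{eq}(f) = \varepsilon_r(f)\,\varepsilon_0 -
  j\,\sigma(f)/\omega,$$

so passive media have a non-positive imaginary part. The coupling medium,
carbonized tissue (8.33, 0.39 S/m, a single-frequency literature value
treated as constant over the band) and ABS (3, 0.004 S/m) are
frequency-constant. Liver and necrosis dispersion in the 600–1400 MHz
band is shipped as editable two-point linear tables (liver 50 → 46 and
0.65 → 1.0 S/m; necrosis 42 → 38 and 0.55 → 0.85 S/m). These defaults are
deliberate placeholders at the magnitude measured dispersion data report
for those tissues; every numerical result the package tests is designed
to be insensitive to their exact values. Table materials refuse to
extrapolate outside their tabulated range — an out-of-band evaluation is
treated as a configuration error, not a guess.

### Incident fields

The reference device uses Vivaldi antennas characterized in a full-wave
solver; full-wave antenna modelling is out of scope here. Instead each
element is represented by an elementary electric dipole at the antenna
tip, polarized along the array axis, radiating in the homogeneous lossy
background with the full near- plus far-field terms ($1/r$, $1/r^2$,
$1/r^3$) and complex wavenumber $k = \omega\sqrt{\mu_0
\varepsilon_{eq}}$ on the decaying branch. Consequences to keep in mind:

* absolute signal levels are not comparable with a physical antenna
  array, and antenna crosstalk is absent, so the empty-reference
  acquisition is exactly zero and all information lives in differential
  data;
* within roughly a tenth of a wavelength of each tip the $1/r^3$ terms
  dominate and the first voxel layers of the region of interest see
  enormous field magnitudes — a point revisited under *Limitations*.

### Scattering and data

The region of interest (ROI), 120 × 102 × 102 mm, is discretized into a
node lattice with 3 mm pitch — 41 × 35 × 35 = 50,225 nodes, the linear
index running x-fastest. Under the distorted Born approximation (DBA) the
total field is replaced by the incident field, and the differential
scattering data between two treatment states become linear in the
contrast $\Delta x$ (the voxelwise change of complex permittivity):

$$\Delta S = K\,\Delta x, \qquad
K_{mn} = \frac{-j}{4\,\omega_f\,\varepsilon_{eq}^{CM}}\;
\mathbf{E}_i(r_n, p)\cdot \mathbf{E}_i(r_n, q)\;\Delta V,$$

with row $m$ enumerating (frequency $f$, transmitter $p$, receiver $q$)
— 5 × 8 × 8 = 320 rows — and the *bilinear* (non-conjugated) dot product
of the two incident fields, as reciprocity dictates. Two choices here
were genuinely open:

* **Voxel volume.** The kernel is a Riemann-sum discretization of a
  volume integral, so $\Delta V$ belongs in $K$; leaving it out would
  only rescale $\Delta x$, and since images are normalized magnitudes the
  choice is observationally equivalent — we include it so the contrast
  keeps physical units (F/m).
* **Band-wide contrast.** The linear system couples all five frequencies
  to a single unknown vector, implicitly assuming a
  frequency-independent contrast. Ground-truth contrasts are therefore
  evaluated once at a band-reference frequency (default 1 GHz); the
  synthetic forward data use the same convention, which keeps the
  linear-algebra identities between forward and inverse paths exact. The
  in-band dispersion of the placeholder tissue tables is a few percent,
  small against the contrast steps between stages.

### Inverse-crime mitigation and noise

"Measured" data are produced on a forward grid twice as fine (1.5 mm)
as the imaging grid by direct summation over the contrast support, so
the inversion never sees data generated by its own discretization; a
consistent mode (`refinement = 1`) exists for exact oracle tests, where
the refined sum reproduces the kernel product to machine precision.

Acquisition noise is i.i.d. circular complex Gaussian, calibrated per
frequency so the per-entry noise power is the per-entry signal power
times $10^{-\mathrm{SNR}/10}$ with SNR = 45 dB, matching the noise floor
of commercial vector network analyzers. Because the surrogate's `s0`
acquisition is identically zero, the experiment driver imposes a *common
noise floor*: the calibration power is the per-frequency mean scattered
power over the non-empty scenarios, applied to every acquisition
including the reference — the software analogue of a VNA whose noise
floor does not depend on what sits in the tank. All noise flows from the
single config seed through a documented substream scheme (one stream per
scenario), so identical configurations reproduce identical data bit for
bit.

## Inversion

The kernel is rank-deficient and severely ill-conditioned, so the system
is solved by truncated SVD: with $K = U\Sigma V^H$,

$$\Delta x_\nu = V\,\Sigma_\nu^{-1}\,U^H\,\Delta S
  = \sum_{i\le\nu} \frac{u_i^H \Delta S}{\sigma_i}\, v_i .$$

The SVD depends only on geometry, background and frequencies — never on
the scenario — so it is computed once (a thin LAPACK SVD of the
320 × 50,225 complex matrix, about 15 s on one core) and optionally
cached on disk keyed by a configuration hash. This is what makes the
imaging itself real-time: each reconstruction is two small matrix-vector
products.

The truncation index $\nu$ trades accuracy against noise amplification.
Candidates are the knees of the dB-normalized singular-value curve,
detected by comparing local slopes over a window on both sides of each
index (window 5, prominence 0.5 dB/index by default — the reference
analysis identifies knees visually, so the detector is parameterized
rather than canonical). The selected $\nu$ is the largest candidate
whose normalized singular value still sits at or above the expected
noise-to-differential-signal level (−15 dB by default: a 45 dB
measurement SNR over a differential signal 30 dB below the total signal
leaves −15 dB of noise on the differential). When no candidate
qualifies, the index where the curve crosses the noise level is used,
with a warning; a manual `nu` override is always available.

Image quality is judged against the best image the truncated basis can
express, the *ideal reconstruction*
$\Delta x_{ID} = V_\nu V_\nu^H\,\Delta x_{GT}$, via the normalized mean
square error over normalized magnitudes,
$\mathrm{NMSE} = \sum |I_{ID} - I|^2 / \sum |I_{ID}|^2$. On
Born-consistent noiseless data the TSVD solution *equals* the ideal
reconstruction for every $\nu$ — this identity is the central oracle of
the test suite, asserted to 10^-6 relative error with NMSE below
10^-10 — and the residual error is provably nonincreasing in $\nu$,
which the suite also checks.

## Localization metrics

Reconstructions are qualitative, so the detection summary thresholds the
normalized magnitude at 0.5, takes the connected supra-threshold
component containing the brightest voxel, and reports its bounding box,
extent and centroid, plus the offset of its near face from the phantom's
near face along the boresight (negative = biased toward the array — the
expected artefact of a one-sided acquisition). Analysis and display use
a crop (x ±60, y ±51, z 17–104 mm by default) that drops the voxel
layers adjacent to the antennas, where array artifacts dominate, mirroring
how the reference study presents its cross-sections.

## What the synthetic generator does and does not emulate

The generator reproduces the multistatic acquisition geometry, the
band, the stage-dependent phantom dielectrics with or without ABS
shells, Born scattering physics on an independent discretization, and
VNA-grade noise. It does **not** emulate: full-wave antenna behaviour
(aperture fields, matching, mutual coupling and crosstalk), quantitative
non-linear scattering (the data are Born-consistent by construction, so
DBA model error appears only through the grid refinement, not through
field distortion), temperature-dependent dielectric trajectories, or
irregular anatomy. Passing tests therefore demonstrate the correctness
and internal consistency of the imaging chain and its statistics — not
that a physical Vivaldi array would achieve the same image quality.

## Problem sizes used by the tests

The test suite runs the full chain on a desk-scale bundle (4 antennas,
2 frequencies, 11 × 9 × 9 nodes, spherical two-region phantom — a
32 × 891 kernel) where every identity can be checked in milliseconds,
and exercises the full 320 × 50,225 configuration once end to end for
the structural and localization checks. The acceptance script measures
the noise-injection calibration over 1000 realizations on the
desk-scale bundle.

## Known limitations

* **Near-field kernel dominance.** With elementary-dipole incident
  fields the kernel column norms span ~95 dB between the first ROI
  layer (3 mm from a tip) and the phantom depth, far more than aperture
  antennas would produce. The retained right-singular subspace
  concentrates near the array, so reconstructed — and even ideal —
  images decay monotonically with depth: after the standard near-array
  crop the brightest voxels sit on the crop face, the apparent target
  is biased toward the array by about 17 mm (a full-wave aperture-antenna
  version of this setup shows only 6–9 mm), and the supra-0.5 x-extent
  underestimates the 60 mm target at 42–54 mm. Sensitivity
  (column-norm) equalization flattens the singular spectrum to a shape
  close to the full-wave one but does not move the cropped maximum off
  the crop face. This is the main fidelity gap of the dipole surrogate;
  the package keeps the unweighted kernel as its default because that
  is the method under study.
* The singular spectrum of the dipole kernel decays much faster than a
  full-wave one, so the knee-above-noise rule selects a small
  truncation index (around 6 at the default settings) and the specific
  knee indices of the reference spectrum are not reproduced.
* The dipole surrogate carries no crosstalk, so absolute signal-level
  tables are reported against a common reference power rather than
  against the empty-reference norm (which is zero here).
* The `b–a` and `c–b` differential pairs use the empty-background
  incident field in the kernel, exactly as the reference processing
  does; for those pairs the DBA is known to be a coarser approximation.

## Worked example

```{r example, eval = FALSE}
cfg <- make_fixture("tiny")          # 4 antennas, 2 frequencies, 891 nodes
ex  <- run_experiment(cfg)           # simulate, invert and score all pairs
ex                                   # NMSE of each differential data set
ex$pairs[["b1-s0"]]$localization     # detection summary of one pair
render_slices(ex$pairs[["b1-s0"]]$image,
              crop = list(x = c(-15, 15), y = c(-12, 12), z = c(9, 30)))
```

The full-scale configuration is `experiment_config()` /
`make_fixture("full")`; on one core the whole ten-pair study, SVD
included, completes in a few minutes.
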