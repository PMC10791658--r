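---
title: "Methods: multimodal X-ray tomography on synthetic tissue phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal X-ray tomography on synthetic tissue phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mmtomo re-implements, at desk scale and on synthetic data, the analysis chain
of a combined SAXS-tensor-tomography / XRF-CT experiment on soft tissue: from
a raster-scanned rotation-and-tilt acquisition to maps of collagen
orientation, fibril diameter, and Fe/Zn concentration, and finally a
voxel-wise cross-correlation table linking them. This vignette records the
models, the tunable parameters, the numerical choices, and what the synthetic
world does and does not establish.

## The acquisition model

The beam travels along lab +x; the specimen rotates by $\omega$ about its own
z axis and the rotation stage tilts by $\alpha$ about the lab y axis, so lab
coordinates map into the sample frame by $R_z(-\omega)R_y(-\alpha)$. A scan
point is a (y, z) raster offset; line integrals through the voxel grid use
Joseph's method (trilinear interpolation sampled every half voxel). The
default desk-scale schedule is 51 rotations over [0°, 180°) at tilt 0 and 24
rotations over [0°, 360°) at each non-zero tilt (default tilts 0°, 9°, 18°,
27°, 36°, 45°); the published experiment's tilted-projection count is not
reproduced because its per-tilt grids are not stated, and the acquisition
count operation therefore takes the per-tilt schedule as configuration.

Three signals are simulated from a phantom:

* **Transmission** $T = e^{-\int \mu\, dl}$, noiseless (the beamstop diode
  integrates many photons).
* **SAXS**: each voxel carries the rank-2 tensor
  $A = \rho\,[(1-a)I/3 + a\,\hat e \hat e^{\mathsf T}]$; the detector segment
  at azimuth $\varphi$ (16 segments, measured counter-clockwise from detector
  +y; small-angle approximation, $q \perp$ beam) probes
  $u^{\mathsf T} A u$ along the segment direction rotated into the sample
  frame. The 5th-order q-bin carries this tensor signal directly; other
  q-bins are scaled by the voxel's collagen profile relative to its 5th-order
  value. Expected counts are flux × exposure × a detector constant × the
  line integral, attenuated by $T$ (self-attenuation), plus a flat
  background; noise is Poisson.
* **XRF** (tilt 0 only, detector at 90° in the horizontal plane): for each
  element and K line, the line integral of concentration weighted by the
  incident attenuation up to the emission point and the exit attenuation
  towards the detector, with the exit-path $\mu$ scaled by
  $(E_{beam}/E_{line})^3$ — a deliberate single-map approximation of the
  energy dependence of absorption that avoids a cross-section database. Line
  energies default to Fe 6.404/7.058 and Zn 8.639/9.572 keV with
  K$\beta$/K$\alpha$ = 0.135 and a 0.08 keV detector sigma.

## The collagen profile and the diameter fit

$$I(q) = s\,\Big[\tfrac{2J_1(qR)}{qR}\Big]^2 \sum_n \Big(\tfrac{\sin(\pi n f)}{\pi n}\Big)^2 G(q - 2\pi n/D;\ \sigma_p) + b$$

Cylinder radius $R$, axial period $D$ (default 65.45 nm, placing the 5th
order at q = 0.480 nm⁻¹), overlap fraction $f$ (default 0.53, which makes the
odd orders — including the 5th — strong), Gaussian axial reflections of
common width $\sigma_p$. This is a declared approximation of the structured
axial intensity used in the literature: Gaussian peaks with step-function
Fourier weights carry the same parameters of interest (D, 2R). Orders are
summed 8 peak-widths past the q-range, so adding more changes nothing at
double precision. An optional single Gaussian interference peak at
$4\pi/(a_{hex}\sqrt 3)$ stands in for hexagonal bundle packing; the full
paracrystalline lattice sum is out of scope.

The fit is bounded least squares with **variable projection**: for each trial
of the nonlinear parameters (D, R, f, $\sigma_p$), the best scale and
background follow from a weighted linear solve, so L-BFGS-B searches only
four dimensions, multi-started at R = 20, 25, 30 nm with the lowest
chi-squared kept. Residuals are weighted **relatively** (by the observed
intensity, floored at 0.1% of its maximum) because SAXS intensities span
decades — with absolute weights the first orders would dominate and the
diameter information in the form-factor envelope would be lost; this choice
is what makes the 5%-noise diameter-recovery criterion attainable. L-BFGS-B
code 52 (line-search failure at the precision limit of finite-difference
gradients) is treated as convergence; exhausting the iteration budget is
not. In the per-voxel diameter map the previous voxel's radius warm-starts
the next fit (fields are spatially smooth), with an automatic fallback to the
full multi-start when the fit quality degrades by more than a factor 25
against the running median.

## Reconstruction

**FBP.** Frequency-domain ramp filter, optionally windowed by a Hamming
window (parameter 0.54) — the common reading of a "Hamming filter"; linear
interpolation in the back-projection; detector coordinate
$t = x\sin\omega + y\cos\omega$, matching the forward projector. The
implementation is validated against an analytic uniform disc (interior
relative RMSE ≤ 0.10 at 60 angles) and against an independently coded oracle
(explicit DFT matrices, per-pixel loops) to ≤ 1e-6. One knife-edge exists by
construction: at exactly 90° the outermost ray lands on the domain boundary
within one ulp (cos(π/2) is 6e-17, not 0), where two correct interpolation
codes may round differently; the oracle tests avoid exact 0/90° multiples.

**Tensor tomography.** The rank-2 field minimises
$\sum_{p} \lVert P_p X M_p^{\mathsf T} - D_p \rVert_F^2$ over the six
per-voxel tensor components $X$, where $P_p$ is the sparse ray operator of
projection $p$ and $M_p$ maps components to per-segment probe coefficients.
Data are background-subtracted and divided by transmission (the
self-attenuation correction) and by the count scale. Gradient descent starts
from the isotropic field matching the FBP mean-scattering volume and uses an
**exact line search** — the objective is quadratic along the gradient, so the
optimal step has a closed form and the objective is non-increasing by
construction (the logged objective enforces this invariant in tests). No PSD
projection is applied by default, mirroring unconstrained band-limited
solvers; spherical orders above rank 2 are out of scope. Voxels whose
reconstructed tensor has non-positive mean probe intensity are masked, and
orientation is the top eigenvector canonicalised to z ≥ 0 (ties: y, then x).
The degree of anisotropy is std/mean of the probe intensity over a
deterministic Fibonacci-spiral direction set (10⁴ directions by default;
2/√5 for a uniaxial tensor, so values land on the familiar 0–0.894 scale).

**XRF-CT.** Per-spectrum fitting is also variable projection: the only
nonlinear parameter is the common Gaussian width (golden-section search);
areas and a linear background are a linear solve, with K$\beta$ tied to
K$\alpha$ by the table ratio (freeing it is an option; tying stabilises
low-count fits). The batched path estimates the width once on the summed
spectrum and solves all areas in one QR factorisation. Areas are normalised
by exposure × flux and corrected in sinogram space by
$T^{-(1+(E_b/E_l)^3)/2}$ — a geometric-mean path model: the incident beam is
attenuated over half its chord on average, the fluorescence over a comparable
exit path at scaled energy. The exact correction is unknowable from a single
transmission map (fluorescence exits sideways at a different energy); the
model is validated only by the property that correction reduces the
in-support RMSE of the reconstructed Fe map on 10/10 noise seeds. Whether the
original analysis corrected in sinogram or image space is unstated; this
package's choice is sinogram space, documented here rather than asserted as
the original's.

## The synthetic phantom

The phantom is a ~1.2 mm cylinder (default 32×32×40 voxels at 37.5 µm;
tests use 12–16 voxel grids) with:

* **Coupled fields.** Degree of anisotropy, fibril diameter (uniform marginal
  on [46, 54] nm), Fe and Zn (uniform marginals on arbitrary-unit ranges) are
  built from smooth Gaussian latent fields (white noise convolved with a
  Gaussian kernel, correlation length 2.5 voxels by default — a free texture
  knob, not a claim about tissue). A deterministic "lesion" bump contributes
  to every latent with per-field weights; the remaining noise components are
  **empirically whitened** (bump projected out, sample cross-correlation
  removed) and then mixed so the realised latent correlation matrix equals
  the target exactly per seed. Rank transforms map latents to uniform
  marginals, and the latent targets are pre-adjusted by the Gaussian-copula
  identity $\rho_{latent} = 2\sin(\pi\rho_{target}/6)$, so the realised
  Pearson correlations hit the configured targets to well within the ±0.05
  contract (measured: ≤ ~0.013 on 48³ grids). Infeasible target combinations
  (the implied noise correlation matrix not PSD) are rejected with an error.
  The default targets (0.81/0.77/0.88/0.70/0.84/0.89) emulate a strongly,
  positively coupled lesion with zinc most strongly tied to collagen
  alignment.
* **Orientation.** Inside the lesion, von Mises–Fisher around the configured
  axis with concentration $\kappa = 4a/(1-a)$ mapped from the local
  anisotropy; uniform on the sphere elsewhere. A smooth floor guarantees the
  aligned region reaches its configured anisotropy target (0.9 by default).
* **Attenuation.** 0.2 mm⁻¹ ± 20% texture: transmission ≈ e^-0.24 across the
  diameter — a realistic, mild self-absorption regime.

What a green test establishes: that the reconstruction and analysis chain
recovers orientations, diameters, element maps and correlations from data
generated by **this** signal model, at desk scale, with Poisson noise. What
it does not establish: anything about real tissue chemistry or histology,
detector artefacts (dead time, escape/sum peaks, Compton shape), beam-profile
effects, or the original study's specimen-specific numbers — its correlation
table, produced from one non-deposited sample, is emulated in design
(coupling targets, ranges) but not asserted as a reproduction target.

## Numerical choices and degenerate inputs

* Projector sampling at half-voxel steps; fields are zero outside the grid.
  A voxelised phantom sampled by trilinear interpolation is rotation
  invariant only in the continuum limit; the tests check symmetry to ~1e-3
  and its ~quadratic improvement under refinement rather than exact
  invariance.
* Transmission values must lie in (0, 1]; zero or negative transmission is an
  error, not a silent clamp.
* Empty azimuthal/q bins in pattern integration are flagged `NA`, never
  zero-filled; empty regions of interest raise errors.
* The 0–255 normalisation keeps real values (no integer rounding) and is
  affine, so Pearson correlations are exactly unchanged — which also makes it
  immaterial whether the correlation table is computed on raw or normalised
  maps (the suite demonstrates the invariance to 1e-12).
* "Collagen orientation" enters the correlation table as the scalar degree of
  anisotropy (a correlation needs scalars; the orientation *direction* is
  reported separately), computed in 3D over the masked volume, not per slice.
* Persistence is plain text (headered CSV volumes with 17-significant-digit
  values for exact round trips; JSON configs and manifests) rather than
  HDF5/TIFF: no binary-format bindings are required, and the round-trip and
  error contracts (unknown extension, missing voxel-size metadata) are kept.
* The run manifest records deterministic content fingerprints (length, keyed
  sum, absolute sum) per stage — sufficient for the reproducibility contract,
  with no cryptographic claim.

## Known limitations

* The tensor solver is plain gradient descent with an exact line search;
  200 iterations suffice at desk scale but large volumes would want a
  preconditioned or conjugate-gradient solver.
* The SAXS q-scaling ties each voxel's whole profile to its 5th-order tensor
  signal; cross-talk between density and anisotropy along a ray is therefore
  linear by construction, which is kinder than reality.
* The XRF exit path ignores the detector solid angle and in-plane offsets:
  one ray per scan point, perpendicular exit.
* Diameter fitting assumes the q-grid spans reflection orders 3–6 and at
  least 30 points; coarser grids are rejected rather than fitted badly.
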