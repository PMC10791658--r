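# mmtomo

Multimodal scanning X-ray tomography of soft tissue, as an R package: SAXS
tensor tomography of collagen orientation, collagen fibril diameter mapping,
X-ray fluorescence computed tomography (XRF-CT) of Fe and Zn with a
self-absorption correction, and voxel-wise cross-correlation of all the
reconstructed maps — together with a seeded synthetic phantom generator so
that the entire pipeline is testable without beamline data.

## Who this is for

Scanning-SAXS/XRF tomography combines two contrast mechanisms in one raster
scan of a rotating (and tilting) specimen: the small-angle scattering pattern
of each beam position carries the local nanostructure (here, collagen fibrils
with an axial D-period of ~65 nm and diameters of tens of nm), while the
fluorescence spectrum carries trace-element concentrations. Groups that run or
plan such experiments — or that develop reconstruction and analysis methods
for them — need a desk-scale, fully synthetic testbed in which every
reconstruction step can be checked against a known ground truth. That is what
this package provides.

## The model in brief

* **Collagen profile.** Fibrils are modelled as cylinders of radius R with an
  axially periodic step-function electron density of period D and overlap
  fraction f:
  `I(q) = s · [2J₁(qR)/(qR)]² · Σₙ (sin(πnf)/(πn))² G(q − 2πn/D; σ) + b`.
  The 5th axial reflection sits near q = 0.48 nm⁻¹ for D ≈ 65.45 nm, and the
  fitted diameter is reported as 2R.
* **Tensor signal.** Each voxel carries a rank-2 reciprocal-space map
  `A = ρ[(1−a)I/3 + a êêᵀ]` (density ρ, degree of anisotropy a, orientation
  ê); a detector segment at azimuth φ probes `uᵀAu` along the in-plane unit
  vector u, line-integrated along the beam. The tensor field is reconstructed
  by least squares over all rotations and tilts, and summarised per voxel by
  its principal eigenvector and the degree of anisotropy (std/mean of the
  probe intensity over the sphere, 2/√5 ≈ 0.894 for a perfect uniaxial
  tensor).
* **Scalar tomography.** Transmission, the mean-scattering map, the q-resolved
  volumes behind the "reverse analysis", and the element maps all use
  parallel-beam filtered back-projection with a Hamming-windowed ramp filter.
* **XRF.** Spectra are fitted with Gaussian Kα/Kβ peaks (Fe 6.404/7.058 keV,
  Zn 8.639/9.572 keV, Kβ/Kα = 0.135) over a linear background; areas are
  normalised by exposure and flux and corrected for self-absorption with
  `T^−(1+(E_beam/E_line)³)/2` before reconstruction.
* **Phantom.** A ~1.2 mm cylinder with smooth coupled fields (anisotropy,
  fibril diameter 46–54 nm, Fe, Zn) built from a Gaussian copula with exact
  empirical control of all pairwise Pearson correlations, a lesion where
  collagen is aligned (von Mises–Fisher orientations) and metals accumulate,
  and a textured attenuation map.

## Worked example

```r
library(mmtomo)

cfg <- pipeline_config(
  phantom  = phantom_config(grid = c(16L, 16L, 16L), voxel_size_mm = 0.075,
                            cylinder_diameter_mm = 1.14,
                            lesion_center_mm = c(0.1, 0.1, 0.15),
                            lesion_radius_mm = 0.35),
  geometry = scan_geometry(n_y = 16L, n_z = 16L, step_mm = 0.075,
                           tilts_deg = c(0, 27, 45),
                           n_rot_tilt0 = 24L, n_rot_tilted = 24L),
  seed = 11L, noise = "none", tensor_iter = 150L,
  roi = list(x = c(5, 12), y = c(5, 12), z = c(6, 11)))

res <- run_pipeline(cfg, out_dir = "mmtomo_out")
print(res$correlation)
```

Output from this exact configuration (the default phantom couples the four
fields with Pearson targets 0.81/0.77/0.88/0.70/0.84/0.89):

```
Pairwise cross-correlation over 384 voxels
            orientation diameter   fe   zn
orientation        1.00     0.64 0.78 0.83
diameter           0.64     1.00 0.57 0.77
fe                 0.78     0.57 1.00 0.88
zn                 0.83     0.77 0.88 1.00
```

The entries are voxel-wise Pearson correlations between the reconstructed
degree of collagen orientation, fibril diameter, Fe and Zn maps over the
masked region of interest: the pipeline recovers the designed positive
coupling, with zinc the most strongly associated with collagen alignment
(0.83 reconstructed against a generator target of 0.88) and every entry
within ~0.17 of its target despite reconstruction error at this tiny
16-cubed desk scale.
`mmtomo_out/` contains the maps as plain-text volumes, `correlation.csv`, and
a `manifest.json` with deterministic content fingerprints (re-running the same
config reproduces it bit for bit).

A command-line driver with the same functionality is installed at
`inst/cli/mmtomo-pipeline` (subcommands `simulate`, `reconstruct`, `xrf`,
`analyze`, `all`; flags `--config`, `--seed`, `--out`, `--log-level`).

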