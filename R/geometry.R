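## Acquisition geometry and the ray projector.
##
## Coordinate convention: the beam travels along lab +x; the sample rotates by
## omega about its own z axis and the whole rotation stage is tilted by alpha
## about the lab y axis (tilted-axis acquisition). A lab-frame point maps into
## the sample frame by R_z(-omega) R_y(-alpha). Scan offset y is the
## horizontal transverse direction, z vertical.

#' Scan geometry
#'
#' @param n_y,n_z raster steps across (horizontal) and along (vertical) the
#'   sample.
#' @param step_mm raster step = virtual spot size (mm); default 0.025 mm.
#' @param tilts_deg tilt angles; must include 0.
#' @param n_rot_tilt0 rotations at tilt 0, spread over [0, 180).
#' @param n_rot_tilted rotations at each non-zero tilt, over [0, 360).
#' @param beam a [beam_spec()]; default 12.4 keV.
#' @param detector_distance_m SAXS detector distance (m); default 5.08.
#' @param n_segments azimuthal segments on the SAXS detector; default 16.
#' @param q_edges q-bin edges (nm^-1); default 60 bins over [0.05, 1.2],
#'   resolving the collagen axial reflections needed by the fibril fit. (The
#'   instrumental range extends to 2.15 nm^-1; the default stops where the
#'   model profile carries diameter information, to bound memory.)
#' @param exposure_s exposure per point (s); default 0.1.
#' @param flux incident flux (photons/s).
#' @param saxs_sens,xrf_sens arbitrary detection calibration constants
#'   (counts per photon-mm of field); they set realistic count rates.
#' @param det_sigma_kev XRF detector energy resolution (Gaussian sigma, keV).
#' @param n_channels,gain_kev,offset_kev XRF channel axis definition.
#' @param line_table XRF emission lines: data.frame with columns `element`,
#'   `line`, `energy_kev`, `rel_int`.
#' @param rot0_deg,rot_tilted_deg optional explicit rotation schedules that
#'   override `n_rot_tilt0` / `n_rot_tilted`.
#' @return a `scan_geometry`.
#' @export
scan_geometry <- function(n_y = 32L, n_z = 40L, step_mm = 0.0375,
                          tilts_deg = c(0, 9, 18, 27, 36, 45),
                          n_rot_tilt0 = 51L, n_rot_tilted = 24L,
                          beam = beam_spec(12.4),
                          detector_distance_m = 5.08,
                          n_segments = 16L,
                          q_edges = seq(0.05, 1.2, length.out = 61),
                          exposure_s = 0.1, flux = 1e6,
                          saxs_sens = 0.025, xrf_sens = 1,
                          det_sigma_kev = 0.08,
                          n_channels = 1200L, gain_kev = 0.01,
                          offset_kev = 0,
                          line_table = default_line_table(),
                          rot0_deg = NULL, rot_tilted_deg = NULL) {
  if (!any(tilts_deg == 0)) stop2("tilt schedule must include 0 degrees")
  if (step_mm <= 0) stop2("step size must be positive")
  if (any(diff(q_edges) <= 0)) stop2("q_edges must be increasing")
  structure(as.list(environment()), class = "scan_geometry")
}

#' Default Fe/Zn K-line table
#'
#' Fe K-alpha 6.404, Fe K-beta 7.058, Zn K-alpha 8.639, Zn K-beta 9.572 keV,
#' with a K-beta/K-alpha intensity ratio of 0.135.
#'
#' @param kb_ratio K-beta to K-alpha intensity ratio.
#' @return data.frame with columns element, line, energy_kev, rel_int.
#' @export
default_line_table <- function(kb_ratio = 0.135) {
  data.frame(element = c("Fe", "Fe", "Zn", "Zn"),
             line = c("Ka", "Kb", "Ka", "Kb"),
             energy_kev = c(6.404, 7.058, 8.639, 9.572),
             rel_int = c(1, kb_ratio, 1, kb_ratio))
}

## rotation schedule per tilt
rotations_for_tilt <- function(geom, tilt) {
  if (tilt == 0) {
    geom$rot0_deg %||%
      seq(0, 180, length.out = geom$n_rot_tilt0 + 1)[seq_len(geom$n_rot_tilt0)]
  } else {
    geom$rot_tilted_deg %||%
      seq(0, 360, length.out = geom$n_rot_tilted + 1)[seq_len(geom$n_rot_tilted)]
  }
}

#' Number of acquired patterns or spectra
#'
#' XRF spectra are collected at tilt 0 only; SAXS patterns at every tilt.
#'
#' @param geometry a [scan_geometry()].
#' @param modality `"saxs"` or `"xrf"`.
#' @return integer count.
#' @export
count_acquired <- function(geometry, modality = c("saxs", "xrf")) {
  modality <- match.arg(modality)
  grid_pts <- geometry$n_y * geometry$n_z
  if (modality == "xrf") {
    return(geometry$n_rot_tilt0 * grid_pts)
  }
  n <- 0
  for (tilt in geometry$tilts_deg) {
    n <- n + length(rotations_for_tilt(geometry, tilt)) * grid_pts
  }
  n
}

## lab->sample rotation for (omega, alpha) in degrees
sample_rotation <- function(omega_deg, alpha_deg) {
  rot_z(-deg2rad(omega_deg)) %*% rot_y(-deg2rad(alpha_deg))
}

## Probed reciprocal-space unit vectors, one per azimuthal segment, in the
## sample frame. Segment k (1-based) has centre azimuth (k - 1/2) * 2pi/n
## measured CCW from detector +y (small-angle approximation: q perpendicular
## to the beam).
segment_directions <- function(n_segments, omega_deg, alpha_deg) {
  phi <- (seq_len(n_segments) - 0.5) * 2 * pi / n_segments
  u_lab <- cbind(0, cos(phi), sin(phi))
  R <- sample_rotation(omega_deg, alpha_deg)
  u_lab %*% t(R)
}

#' Ray projector for one projection
#'
#' Builds the sparse line-integral operator for a parallel-beam projection at
#' rotation `omega_deg` and tilt `alpha_deg`: a `n_y*n_z x n_vox` matrix `P`
#' such that `P %*% as.vector(field)` approximates the integral of the field
#' along each beam (Joseph's method: trilinear interpolation sampled every
#' half voxel along the ray), in units of field * mm.
#'
#' @param grid voxel counts `c(nx, ny, nz)`.
#' @param voxel_size_mm voxel edge (mm).
#' @param offsets_y_mm,offsets_z_mm transverse ray offsets (mm), typically the
#'   raster positions; rays are ordered y-fastest.
#' @param omega_deg,alpha_deg rotation and tilt (degrees).
#' @return a `dgCMatrix`.
#' @export
ray_projector <- function(grid, voxel_size_mm, offsets_y_mm, offsets_z_mm,
                          omega_deg, alpha_deg = 0) {
  vs <- voxel_size_mm
  R <- sample_rotation(omega_deg, alpha_deg)
  d <- as.numeric(R %*% c(1, 0, 0))
  oy <- rep(offsets_y_mm, times = length(offsets_z_mm))
  oz <- rep(offsets_z_mm, each = length(offsets_y_mm))
  n_ray <- length(oy)
  o <- cbind(0, oy, oz) %*% t(R)           # ray reference points, sample frame
  half_diag <- 0.5 * sqrt(sum((grid * vs)^2))
  step <- vs / 2
  t_s <- seq(-half_diag - step, half_diag + step, by = step)
  n_step <- length(t_s)
  ## all sample positions: (ray, step) pairs
  px <- rep(o[, 1], n_step) + rep(t_s, each = n_ray) * d[1]
  py <- rep(o[, 2], n_step) + rep(t_s, each = n_ray) * d[2]
  pz <- rep(o[, 3], n_step) + rep(t_s, each = n_ray) * d[3]
  ray_id <- rep(seq_len(n_ray), n_step)
  ## fractional voxel indices (voxel centres at (i - (n+1)/2) * vs)
  fx <- px / vs + (grid[1] + 1) / 2
  fy <- py / vs + (grid[2] + 1) / 2
  fz <- pz / vs + (grid[3] + 1) / 2
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  ii <- jj <- xx <- vector("list", 8)
  n1 <- grid[1]; n2 <- grid[2]; n3 <- grid[3]
  m <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    m <- m + 1
    i <- i0 + di; j <- j0 + dj; k <- k0 + dk
    w <- (if (di == 1) wx else 1 - wx) *
         (if (dj == 1) wy else 1 - wy) *
         (if (dk == 1) wz else 1 - wz)
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2 & k >= 1 & k <= n3 & w > 0
    ii[[m]] <- ray_id[ok]
    jj[[m]] <- i[ok] + (j[ok] - 1) * n1 + (k[ok] - 1) * n1 * n2
    xx[[m]] <- w[ok] * step
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n_ray, prod(grid)))
}

#' Build all projectors for a geometry
#'
#' One sparse operator per (tilt, rotation), with ray offsets centred on the
#' raster grid.
#'
#' @param grid voxel counts.
#' @param voxel_size_mm voxel edge (mm).
#' @param geometry a [scan_geometry()].
#' @return list of entries with `tilt`, `omega`, `P`.
#' @export
build_projectors <- function(grid, voxel_size_mm, geometry) {
  offs_y <- (seq_len(geometry$n_y) - (geometry$n_y + 1) / 2) * geometry$step_mm
  offs_z <- (seq_len(geometry$n_z) - (geometry$n_z + 1) / 2) * geometry$step_mm
  out <- list()
  for (tilt in geometry$tilts_deg) {
    for (omega in rotations_for_tilt(geometry, tilt)) {
      out[[length(out) + 1]] <- list(
        tilt = tilt, omega = omega,
        P = ray_projector(grid, voxel_size_mm, offs_y, offs_z, omega, tilt))
    }
  }
  out
}
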