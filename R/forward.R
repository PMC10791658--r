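## Forward simulation of the scanning acquisition: transmission,
## azimuthally-segmented SAXS sinograms over rotations and tilts, and XRF
## spectra with optional self-absorption.

## trilinear sampling of a 3D field at arbitrary points (0 outside the grid)
trilinear_sample <- function(field, px, py, pz, vs) {
  grid <- dim(field)
  fx <- px / vs + (grid[1] + 1) / 2
  fy <- py / vs + (grid[2] + 1) / 2
  fz <- pz / vs + (grid[3] + 1) / 2
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- numeric(length(px))
  n1 <- grid[1]; n2 <- grid[2]
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    i <- i0 + di; j <- j0 + dj; k <- k0 + dk
    w <- (if (di == 1) wx else 1 - wx) *
         (if (dj == 1) wy else 1 - wy) *
         (if (dk == 1) wz else 1 - wz)
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2 & k >= 1 & k <= grid[3] & w > 0
    if (any(ok)) {
      idx <- i[ok] + (j[ok] - 1) * n1 + (k[ok] - 1) * n1 * n2
      out[ok] <- out[ok] + w[ok] * field[idx]
    }
  }
  out
}

## per-voxel rank-2 scattering tensor components (n_vox x 6):
## A(v) = density * [(1 - a) I/3 + a e e']
phantom_tensor_components <- function(phantom) {
  dens <- as.vector(phantom$collagen_density)
  a <- as.vector(phantom$anisotropy)
  n_vox <- length(dens)
  e <- matrix(phantom$orientation, n_vox, 3)
  iso <- dens * (1 - a) / 3
  cbind(iso + dens * a * e[, 1]^2,
        iso + dens * a * e[, 2]^2,
        iso + dens * a * e[, 3]^2,
        dens * a * e[, 1] * e[, 2],
        dens * a * e[, 1] * e[, 3],
        dens * a * e[, 2] * e[, 3])
}

## q-bin index of the collagen 5th-order reflection (q = 2 pi 5 / D)
q5_bin <- function(q_edges, D_nm = 65.45) {
  q5 <- 2 * pi * 5 / D_nm
  b <- findInterval(q5, q_edges, rightmost.closed = TRUE)
  if (b < 1 || b > length(q_edges) - 1)
    stop2("5th-order reflection q=%.3f lies outside the q-bins", q5)
  b
}

## per-voxel relative q-profile W (n_vox x n_q), normalised to 1 at the
## 5th-order bin. Only the cylinder factor depends on the per-voxel radius;
## the axial reflection sum is shared.
voxel_q_weights <- function(phantom, q_mid, base_params, q5b) {
  ax <- collagen_profile(q_mid,
                         modifyList2(base_params, list(scale = 1, background = 0)))
  ## strip the shared cylinder factor to get the pure axial sum
  axial <- ax / cylinder_factor(q_mid, base_params$R_nm)
  Rv <- as.vector(phantom$fibril_diameter) / 2
  Rv[Rv <= 0] <- base_params$R_nm  # outside support; weight is irrelevant there
  C <- matrix(0, length(Rv), length(q_mid))
  for (jq in seq_along(q_mid)) C[, jq] <- cylinder_factor(q_mid[jq], Rv)
  W <- sweep(C, 2, axial, "*")
  W / W[, q5b]
}

modifyList2 <- function(p, vals) {
  out <- modifyList(unclass(p), vals)
  class(out) <- class(p)
  out
}

#' Simulate the transmission sinogram
#'
#' Beer-Lambert line integrals of the attenuation map, noiseless:
#' T = exp(-integral of mu along the beam).
#'
#' @param phantom a [generate_phantom()] result.
#' @param geometry a [scan_geometry()].
#' @param projectors optional pre-built [build_projectors()] output.
#' @return list with `transmission` (`n_proj x n_rays`), `proj_index`
#'   (data.frame of tilt, omega), `geometry`.
#' @export
simulate_transmission <- function(phantom, geometry, projectors = NULL) {
  if (is.null(projectors))
    projectors <- build_projectors(dim(phantom$mu), phantom$voxel_size_mm, geometry)
  mu_v <- as.vector(phantom$mu)
  Tm <- t(vapply(projectors,
                 function(pr) exp(-as.numeric(pr$P %*% mu_v)),
                 numeric(geometry$n_y * geometry$n_z)))
  list(transmission = Tm,
       proj_index = data.frame(tilt = vapply(projectors, `[[`, 0, "tilt"),
                               omega = vapply(projectors, `[[`, 0, "omega")),
       geometry = geometry)
}

#' Simulate the scanning SAXS acquisition
#'
#' Per-voxel signal model: rank-2 tensor `A(v) = density [(1-a) I/3 + a ee']`
#' with `a` the degree of anisotropy and `e` the orientation. The expected
#' segment intensity at the 5th-order q-bin is the beam line integral of
#' `u' A u` for the segment's probed direction `u`, attenuated by the sample
#' transmission, scaled by flux, exposure and the detector constant; other
#' q-bins are scaled by the per-voxel collagen profile. Counts are Poisson
#' unless `noise = "none"`.
#'
#' @param phantom a phantom.
#' @param geometry a [scan_geometry()].
#' @param seed RNG seed for the Poisson noise.
#' @param noise `"poisson"` or `"none"`.
#' @param profile_params base [collagen_params()]; the per-voxel radius comes
#'   from the phantom's diameter field.
#' @param background expected background counts per (segment, q-bin).
#' @param attenuate multiply the expectation by the beam transmission
#'   (self-attenuation; on by default).
#' @param projectors optional pre-built projectors.
#' @return an `azimuthal_sinogram`: `intensity` array
#'   `(n_proj, n_rays, n_segments, n_q)`, `transmission` `(n_proj, n_rays)`,
#'   `proj_index`, `q_edges`, `q_mid`, `q5_bin`, `geometry`, `background`.
#' @export
simulate_saxs_scan <- function(phantom, geometry, seed = 1L,
                               noise = c("poisson", "none"),
                               profile_params = collagen_params(D_nm = 65.45),
                               background = 2,
                               attenuate = TRUE,
                               projectors = NULL) {
  noise <- match.arg(noise)
  set.seed(as.integer(seed))
  grid <- dim(phantom$mu)
  if (is.null(projectors))
    projectors <- build_projectors(grid, phantom$voxel_size_mm, geometry)
  q_edges <- geometry$q_edges
  q_mid <- (head(q_edges, -1) + tail(q_edges, -1)) / 2
  q5b <- q5_bin(q_edges, profile_params$D_nm)
  Xc <- phantom_tensor_components(phantom)
  W <- voxel_q_weights(phantom, q_mid, profile_params, q5b)
  scale0 <- geometry$flux * geometry$exposure_s * geometry$saxs_sens
  n_ray <- geometry$n_y * geometry$n_z
  n_seg <- geometry$n_segments
  n_q <- length(q_mid)
  n_proj <- length(projectors)
  out <- array(0, dim = c(n_proj, n_ray, n_seg, n_q))
  Tm <- matrix(1, n_proj, n_ray)
  mu_v <- as.vector(phantom$mu)
  for (p in seq_len(n_proj)) {
    pr <- projectors[[p]]
    Tm[p, ] <- exp(-as.numeric(pr$P %*% mu_v))
    U <- segment_directions(n_seg, pr$omega, pr$tilt)
    M <- probe_coefficients(U)            # n_seg x 6
    probe <- Xc %*% t(M)                  # n_vox x n_seg
    att <- if (attenuate) Tm[p, ] else rep(1, n_ray)
    for (s in seq_len(n_seg)) {
      lam <- as.matrix(pr$P %*% (probe[, s] * W))  # n_ray x n_q
      out[p, , s, ] <- scale0 * att * lam + background
    }
  }
  if (noise == "poisson") {
    out[] <- rpois(length(out), lambda = pmin(out, .Machine$integer.max / 2))
  }
  structure(list(intensity = out, transmission = Tm,
                 proj_index = data.frame(
                   tilt = vapply(projectors, `[[`, 0, "tilt"),
                   omega = vapply(projectors, `[[`, 0, "omega")),
                 q_edges = q_edges, q_mid = q_mid, q5_bin = q5b,
                 geometry = geometry, background = background,
                 noise = noise, seed = as.integer(seed)),
            class = "azimuthal_sinogram")
}

#' Simulate the scanning XRF acquisition
#'
#' Expected spectrum per scan point: for each element and emission line, the
#' line integral of concentration weighted by the incident-beam attenuation up
#' to the emission point and the exit-path attenuation towards the detector
#' (placed at 90 degrees to the beam in the horizontal plane), spread over
#' channels as a Gaussian at the line energy, plus a flat background. The
#' exit-path attenuation uses the beam-energy mu scaled by
#' `(E_beam / E_line)^3`. XRF is acquired at tilt 0 only.
#'
#' @param phantom a phantom.
#' @param geometry a [scan_geometry()].
#' @param absorption apply self-absorption (`TRUE`) or not.
#' @param seed RNG seed.
#' @param noise `"poisson"` or `"none"`.
#' @param background expected background counts per channel.
#' @param conc_fields named list mapping element name to the phantom field
#'   holding its concentration.
#' @return an `xrf_scan`: `spectra` array `(n_rot, n_rays, n_channels)`,
#'   `true_areas` (expected line-integral areas per element,
#'   `n_rot x n_rays x n_element`), `energy_kev` channel centres,
#'   `calibration` (true gain/offset), `proj_index`, `geometry`.
#' @export
simulate_xrf_scan <- function(phantom, geometry, absorption = TRUE,
                              seed = 1L, noise = c("poisson", "none"),
                              background = 0.5,
                              conc_fields = list(Fe = "fe", Zn = "zn")) {
  noise <- match.arg(noise)
  set.seed(as.integer(seed))
  grid <- dim(phantom$mu)
  vs <- phantom$voxel_size_mm
  rots <- rotations_for_tilt(geometry, 0)
  offs_y <- (seq_len(geometry$n_y) - (geometry$n_y + 1) / 2) * geometry$step_mm
  offs_z <- (seq_len(geometry$n_z) - (geometry$n_z + 1) / 2) * geometry$step_mm
  oy <- rep(offs_y, times = length(offs_z))
  oz <- rep(offs_z, each = length(offs_y))
  n_ray <- length(oy)
  half_diag <- 0.5 * sqrt(sum((grid * vs)^2))
  step <- vs / 2
  t_s <- seq(-half_diag - step, half_diag + step, by = step)
  n_step <- length(t_s)
  lines <- geometry$line_table
  elements <- names(conc_fields)
  e_ch <- geometry$offset_kev + geometry$gain_kev * (seq_len(geometry$n_channels) - 1)
  scale0 <- geometry$flux * geometry$exposure_s * geometry$xrf_sens
  spectra <- array(0, dim = c(length(rots), n_ray, geometry$n_channels))
  true_areas <- array(0, dim = c(length(rots), n_ray, length(elements)),
                      dimnames = list(NULL, NULL, elements))
  exit_len <- seq(step, 2 * half_diag, by = step)
  for (ri in seq_along(rots)) {
    R <- sample_rotation(rots[ri], 0)
    d <- as.numeric(R %*% c(1, 0, 0))
    e_dir <- as.numeric(R %*% c(0, 1, 0))   # towards the detector
    o <- cbind(0, oy, oz) %*% t(R)
    px <- rep(o[, 1], n_step) + rep(t_s, each = n_ray) * d[1]
    py <- rep(o[, 2], n_step) + rep(t_s, each = n_ray) * d[2]
    pz <- rep(o[, 3], n_step) + rep(t_s, each = n_ray) * d[3]
    mu_s <- trilinear_sample(phantom$mu, px, py, pz, vs)
    mu_m <- matrix(mu_s, n_ray, n_step)
    ## incident attenuation up to each sample (midpoint cumulative rule)
    cums <- t(apply(mu_m, 1, cumsum)) * step - mu_m * step / 2
    T_in <- if (absorption) exp(-cums) else matrix(1, n_ray, n_step)
    ## exit-path mu integral from every sample point towards the detector
    if (absorption) {
      exit_int <- numeric(n_ray * n_step)
      for (s_m in exit_len) {
        exit_int <- exit_int + trilinear_sample(phantom$mu,
                                                px + s_m * e_dir[1],
                                                py + s_m * e_dir[2],
                                                pz + s_m * e_dir[3], vs)
      }
      exit_int <- matrix(exit_int * step, n_ray, n_step)
    } else {
      exit_int <- matrix(0, n_ray, n_step)
    }
    for (el_i in seq_along(elements)) {
      el <- elements[el_i]
      conc <- trilinear_sample(phantom[[conc_fields[[el]]]], px, py, pz, vs)
      conc <- matrix(conc, n_ray, n_step)
      el_lines <- lines[lines$element == el, , drop = FALSE]
      for (li in seq_len(nrow(el_lines))) {
        e_line <- el_lines$energy_kev[li]
        s_pow <- (geometry$beam$energy_kev / e_line)^3
        T_out <- exp(-s_pow * exit_int)
        area <- scale0 * el_lines$rel_int[li] *
          rowSums(conc * T_in * T_out) * step
        if (el_lines$line[li] == "Ka") {
          true_areas[ri, , el_i] <- rowSums(conc * T_in * T_out) * step
        }
        shape <- dnorm(e_ch, e_line, geometry$det_sigma_kev) * geometry$gain_kev
        spectra[ri, , ] <- spectra[ri, , ] + outer(area, shape)
      }
    }
    spectra[ri, , ] <- spectra[ri, , ] + background
  }
  if (noise == "poisson") {
    spectra[] <- rpois(length(spectra), lambda = spectra)
  }
  structure(list(spectra = spectra, true_areas = true_areas,
                 energy_kev = e_ch,
                 calibration = list(gain_kev = geometry$gain_kev,
                                    offset_kev = geometry$offset_kev),
                 proj_index = data.frame(tilt = 0, omega = rots),
                 geometry = geometry, absorption = absorption,
                 noise = noise, seed = as.integer(seed)),
            class = "xrf_scan")
}
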