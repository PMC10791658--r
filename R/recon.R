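## Scalar tomographic reconstruction (filtered back-projection with a ramp or
## Hamming-windowed filter) and rank-2 tensor tomography.

## frequency response of the reconstruction filter, on the fft frequency axis
## (cycles per sample)
fbp_filter_response <- function(n, filter) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  H <- abs(f)
  if (filter == "hamming") H <- H * (0.54 + 0.46 * cos(2 * pi * f))
  H
}

#' Filtered back-projection of one slice
#'
#' Parallel-beam FBP: each projection is ramp-filtered in the frequency domain
#' (optionally Hamming-windowed, window parameter 0.54) and back-projected
#' with linear interpolation. The detector coordinate of a sample-frame point
#' (x, y) at rotation omega is `t = x sin(omega) + y cos(omega)`, matching the
#' forward projector's convention.
#'
#' @param sinogram `n_det x n_angles` matrix of line integrals; detector bins
#'   are centred on the grid (offset `(i - (n+1)/2) * spacing`).
#' @param angles_deg rotation angles, one per column; at least 2.
#' @param filter `"hamming"` (default) or `"ramp"`.
#' @param spacing_mm detector bin spacing (mm).
#' @return `n_det x n_det` reconstructed slice on the same spacing, in units
#'   of (sinogram units) per mm.
#' @export
fbp <- function(sinogram, angles_deg, filter = c("hamming", "ramp"),
                spacing_mm = 1) {
  filter <- match.arg(filter)
  if (!is.matrix(sinogram)) stop2("sinogram must be a matrix")
  if (ncol(sinogram) != length(angles_deg))
    stop2("sinogram has %d columns but %d angles given",
          ncol(sinogram), length(angles_deg))
  if (length(angles_deg) < 2) stop2("need at least 2 angles")
  n_det <- nrow(sinogram)
  n_pad <- 2^ceiling(log2(2 * n_det))
  H <- fbp_filter_response(n_pad, filter)
  padded <- rbind(sinogram, matrix(0, n_pad - n_det, ncol(sinogram)))
  filt <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / n_pad
  filt <- filt[seq_len(n_det), , drop = FALSE] / spacing_mm
  offs <- (seq_len(n_det) - (n_det + 1) / 2) * spacing_mm
  xs <- matrix(offs, n_det, n_det)
  ys <- matrix(offs, n_det, n_det, byrow = TRUE)
  rec <- matrix(0, n_det, n_det)
  for (a in seq_along(angles_deg)) {
    w <- deg2rad(angles_deg[a])
    t_val <- xs * sin(w) + ys * cos(w)
    rec <- rec + matrix(approx(offs, filt[, a], xout = as.vector(t_val),
                               yleft = 0, yright = 0)$y, n_det, n_det)
  }
  rec * pi / length(angles_deg)
}

## tilt-0 projection selector
tilt0_index <- function(proj_index) which(proj_index$tilt == 0)

## reshape (n_proj0, n_ray) sinogram slab into per-slice FBP volume
fbp_volume <- function(sino2d, omegas, n_y, n_z, spacing_mm, filter) {
  vol <- array(0, dim = c(n_y, n_y, n_z))
  for (k in seq_len(n_z)) {
    cols <- (k - 1) * n_y + seq_len(n_y)
    slice_sino <- t(sino2d[, cols, drop = FALSE])  # n_y x n_rot
    vol[, , k] <- fbp(slice_sino, omegas, filter = filter,
                      spacing_mm = spacing_mm)
  }
  vol
}

#' Reconstruct the attenuation map from transmission data
#'
#' Applies FBP to -log(T) per vertical slice, using the tilt-0 rotations.
#'
#' @param transmission a [simulate_transmission()] result (or an
#'   `azimuthal_sinogram`, whose transmission block is used).
#' @param filter FBP filter.
#' @return a `scalar_volume` labelled "transmission-mu" on the
#'   `n_y x n_y x n_z` scan grid.
#' @export
reconstruct_mu <- function(transmission, filter = "hamming") {
  geom <- transmission$geometry
  Tm <- transmission$transmission
  if (any(Tm <= 0) || any(Tm > 1 + 1e-9))
    stop2("transmission values must lie in (0, 1]")
  i0 <- tilt0_index(transmission$proj_index)
  vol <- fbp_volume(-log(Tm[i0, , drop = FALSE]),
                    transmission$proj_index$omega[i0],
                    geom$n_y, geom$n_z, geom$step_mm, filter)
  scalar_volume(vol, geom$step_mm, "transmission-mu")
}

## data scale that converts counts to line-integral units
saxs_count_scale <- function(geometry) {
  geometry$flux * geometry$exposure_s * geometry$saxs_sens
}

## background-subtracted, transmission-corrected line-integral estimates at
## one q-bin: (n_proj, n_ray, n_seg)
corrected_saxs_data <- function(sinogram, q_bin) {
  d <- sinogram$intensity[, , , q_bin, drop = FALSE]
  dim(d) <- dim(sinogram$intensity)[1:3]
  d <- d - sinogram$background
  sweep(d, c(1, 2), sinogram$transmission * saxs_count_scale(sinogram$geometry), "/")
}

#' Mean-scattering volume at one q-bin
#'
#' FBP of the segment-averaged, background-subtracted and
#' transmission-corrected tilt-0 sinogram at the given q-bin (default: the
#' collagen 5th-order bin).
#'
#' @param sinogram an `azimuthal_sinogram`.
#' @param q_bin q-bin index.
#' @param filter FBP filter.
#' @return a `scalar_volume` labelled "mean-scattering".
#' @export
mean_scattering_volume <- function(sinogram, q_bin = sinogram$q5_bin,
                                   filter = "hamming") {
  geom <- sinogram$geometry
  d <- corrected_saxs_data(sinogram, q_bin)
  seg_mean <- apply(d, c(1, 2), mean)
  i0 <- tilt0_index(sinogram$proj_index)
  vol <- fbp_volume(seg_mean[i0, , drop = FALSE],
                    sinogram$proj_index$omega[i0],
                    geom$n_y, geom$n_z, geom$step_mm, filter)
  scalar_volume(vol, geom$step_mm, "mean-scattering")
}

#' Reconstruct a volume for every q-bin
#'
#' Segment-averaged FBP per q-bin; the input to the reverse analysis.
#'
#' @param sinogram an `azimuthal_sinogram`.
#' @param filter FBP filter.
#' @return list with `volumes` (one `scalar_volume` per q-bin) and `q_mid`.
#' @export
reconstruct_q_volumes <- function(sinogram, filter = "hamming") {
  vols <- lapply(seq_along(sinogram$q_mid), function(b)
    mean_scattering_volume(sinogram, q_bin = b, filter = filter))
  list(volumes = vols, q_mid = sinogram$q_mid)
}

#' Rank-2 tensor tomography
#'
#' Reconstructs a per-voxel symmetric rank-2 tensor field from the
#' azimuthally-segmented sinograms over all tilts at one q-bin, by minimising
#' the squared data misfit `sum_p || P_p X M_p' - D_p ||^2` over the six
#' per-voxel tensor components X. Plain gradient descent with an exact line
#' search along the gradient (the objective is quadratic in X), so the
#' objective is non-increasing by construction. The start is the isotropic
#' tensor field whose probe intensity matches the FBP mean-scattering volume.
#'
#' @param sinogram an `azimuthal_sinogram` over all tilts.
#' @param q_bin q-bin index (default: the 5th-order bin).
#' @param n_iter maximum iterations.
#' @param tol stop when the relative objective decrease falls below this.
#' @param projectors optional pre-built projectors (grid must be the
#'   `n_y x n_y x n_z` scan grid).
#' @return a `rank2_tensor_field`: `components` (`n_vox x 6`), `grid`,
#'   `voxel_size_mm`, `objective` (per-iteration log), `single_tilt` flag.
#' @export
reconstruct_tensor <- function(sinogram, q_bin = sinogram$q5_bin,
                               n_iter = 200L, tol = 1e-10,
                               projectors = NULL) {
  geom <- sinogram$geometry
  grid <- c(geom$n_y, geom$n_y, geom$n_z)
  if (is.null(projectors))
    projectors <- build_projectors(grid, geom$step_mm, geom)
  single_tilt <- length(unique(sinogram$proj_index$tilt)) < 2
  if (single_tilt)
    warning("single-tilt data: out-of-plane tensor components are degenerate",
            call. = FALSE)
  D <- corrected_saxs_data(sinogram, q_bin)
  n_proj <- dim(D)[1]
  stopifnot(n_proj == length(projectors))
  Ms <- lapply(seq_len(n_proj), function(p)
    probe_coefficients(segment_directions(geom$n_segments,
                                          projectors[[p]]$omega,
                                          projectors[[p]]$tilt)))
  Ps <- lapply(projectors, `[[`, "P")
  Pts <- lapply(Ps, Matrix::t)
  ## isotropic start from the mean-scattering FBP (floored at 0)
  v0 <- pmax(mean_scattering_volume(sinogram, q_bin)$values, 0)
  X <- cbind(as.vector(v0), as.vector(v0), as.vector(v0), 0, 0, 0)
  forward_all <- function(X) lapply(seq_len(n_proj), function(p)
    as.matrix(Ps[[p]] %*% (X %*% t(Ms[[p]]))))
  obj_log <- numeric(0)
  Fw <- forward_all(X)
  Rs <- lapply(seq_len(n_proj), function(p) Fw[[p]] - matrix(D[p, , ], ncol = geom$n_segments))
  f <- sum(vapply(Rs, function(r) sum(r * r), 0))
  for (it in seq_len(n_iter)) {
    obj_log <- c(obj_log, f)
    G <- matrix(0, nrow(X), 6)
    for (p in seq_len(n_proj))
      G <- G + 2 * as.matrix(Pts[[p]] %*% Rs[[p]] %*% Ms[[p]])
    FG <- forward_all(G)
    num <- sum(vapply(seq_len(n_proj), function(p) sum(Rs[[p]] * FG[[p]]), 0))
    den <- sum(vapply(FG, function(g) sum(g * g), 0))
    if (den <= 0 || !is.finite(den)) break
    eta <- num / den
    X <- X - eta * G
    for (p in seq_len(n_proj)) Rs[[p]] <- Rs[[p]] - eta * FG[[p]]
    f_new <- sum(vapply(Rs, function(r) sum(r * r), 0))
    if (f > 0 && (f - f_new) / max(f, .Machine$double.eps) < tol) {
      f <- f_new
      obj_log <- c(obj_log, f)
      break
    }
    f <- f_new
  }
  structure(list(components = X, grid = grid, voxel_size_mm = geom$step_mm,
                 objective = obj_log, single_tilt = single_tilt,
                 q_bin = q_bin),
            class = "rank2_tensor_field")
}

#' Principal orientation and degree of anisotropy of a tensor field
#'
#' Per voxel: the eigenvector of the largest eigenvalue, canonicalised so its
#' z-component is >= 0 (ties broken by y >= 0, then x >= 0), and the degree of
#' anisotropy (std/mean of the probe intensity over `n_dirs` deterministic
#' spiral directions). Voxels whose tensor has non-positive mean probe
#' intensity are masked out.
#'
#' @param field a `rank2_tensor_field`.
#' @param n_dirs sphere directions for the anisotropy measure.
#' @return list with `orientation` (`nx x ny x nz x 3` array), `anisotropy`
#'   (a `scalar_volume` with the validity mask).
#' @export
principal_orientation <- function(field, n_dirs = 10000L) {
  X <- field$components
  n_vox <- nrow(X)
  U <- sphere_directions(n_dirs)
  Mc <- probe_coefficients(U)            # n_dirs x 6
  mean_v <- numeric(n_vox); sd_v <- numeric(n_vox)
  block <- 1024L
  for (b0 in seq(1, n_vox, by = block)) {
    b1 <- min(b0 + block - 1, n_vox)
    V <- X[b0:b1, , drop = FALSE] %*% t(Mc)   # block x n_dirs
    m <- rowMeans(V)
    mean_v[b0:b1] <- m
    sd_v[b0:b1] <- sqrt(pmax(0, (rowSums(V^2) - n_dirs * m^2) / (n_dirs - 1)))
  }
  ok <- mean_v > 1e-12 * max(abs(mean_v))
  anis <- ifelse(ok, sd_v / pmax(mean_v, .Machine$double.xmin), 0)
  orient <- matrix(0, n_vox, 3)
  for (v in which(ok)) {
    A <- tensor_from_components(X[v, ])
    ev <- eigen(A, symmetric = TRUE)
    e1 <- ev$vectors[, 1]
    s <- sign(e1[3])
    if (s == 0) s <- sign(e1[2])
    if (s == 0) s <- sign(e1[1])
    if (s == 0) s <- 1
    orient[v, ] <- e1 * s
  }
  grid <- field$grid
  list(orientation = array(orient, dim = c(grid, 3L)),
       anisotropy = scalar_volume(array(anis, dim = grid),
                                  field$voxel_size_mm, "anisotropy",
                                  mask = array(ok, dim = grid)))
}
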