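## Seeded synthetic specimen generator. Produces a voxelised cylinder with
## smooth, mutually correlated fields (degree of anisotropy, fibril diameter,
## Fe, Zn) plus collagen density, orientation vectors and attenuation, so that
## parameter- and correlation-recovery can be tested without real data.
##
## Coupling design: each of the four analysis fields is built from a latent
## Gaussian random field z_i = sqrt(1 - beta_i^2) * (mixed smooth noise) +
## beta_i * B_i, where B_i is a standardised deterministic "lesion" bump and
## the noise mixing matrix is chosen so that the total latent correlation
## equals 2 sin(pi rho_target / 6) for every configured pair. A rank
## (empirical-CDF) transform then maps each latent to a uniform marginal over
## the configured range; with uniform marginals the Gaussian-copula identity
## Pearson(U_i, U_j) = (6/pi) asin(rho_latent / 2) makes the realised Pearson
## correlation hit the configured target.

#' Phantom configuration
#'
#' @param grid integer vector `c(nx, ny, nz)` of voxel counts.
#' @param voxel_size_mm isotropic voxel edge (mm). The default grid
#'   32 x 32 x 40 at 0.0375 mm makes the cylinder ~1.2 mm across.
#' @param cylinder_diameter_mm support cylinder diameter (mm).
#' @param cylinder_height_mm support cylinder height (mm); `NA` fills the grid.
#' @param lesion_center_mm centre of the aligned region / metal hotspot,
#'   relative to the grid centre (mm).
#' @param lesion_radius_mm Gaussian radius of the lesion bump (mm).
#' @param target_anisotropy anisotropy the aligned region must reach.
#' @param aligned_axis preferred collagen axis inside the aligned region.
#' @param diameter_range_nm fibril diameter bounds (nm), within [40, 70].
#' @param anisotropy_range degree-of-anisotropy marginal range, inside [0, 1].
#' @param fe_range,zn_range element concentration marginal ranges (arbitrary
#'   mass-fraction units, non-negative).
#' @param rho target pairwise Pearson correlations between the four fields, a
#'   named vector with entries `anis_diam`, `anis_fe`, `anis_zn`, `diam_fe`,
#'   `diam_zn`, `fe_zn`, all in (-1, 1). Defaults emulate a strongly and
#'   positively coupled lesion.
#' @param structure_weight per-field weight in [0, 1) of the deterministic
#'   lesion bump (named: anis, diam, fe, zn).
#' @param texture_scale_vox correlation length of the smooth noise, voxels.
#' @param mu_mm_inv mean linear attenuation inside the support (mm^-1).
#' @param mu_texture relative attenuation texture amplitude.
#' @param kappa_scale von Mises-Fisher concentration per unit a/(1-a).
#' @param seed default seed used when [generate_phantom()] is not given one.
#' @return a `phantom_config`.
#' @export
phantom_config <- function(grid = c(32L, 32L, 40L),
                           voxel_size_mm = 0.0375,
                           cylinder_diameter_mm = 1.2,
                           cylinder_height_mm = NA_real_,
                           lesion_center_mm = c(0.1, 0.1, 0.3),
                           lesion_radius_mm = 0.35,
                           target_anisotropy = 0.9,
                           aligned_axis = c(0, 0, 1),
                           diameter_range_nm = c(46, 54),
                           anisotropy_range = c(0.02, 0.95),
                           fe_range = c(0.02, 1),
                           zn_range = c(0.02, 1),
                           rho = c(anis_diam = 0.81, anis_fe = 0.77,
                                   anis_zn = 0.88, diam_fe = 0.70,
                                   diam_zn = 0.84, fe_zn = 0.89),
                           structure_weight = c(anis = 0.45, diam = 0.35,
                                                fe = 0.45, zn = 0.45),
                           texture_scale_vox = 2.5,
                           mu_mm_inv = 0.2,
                           mu_texture = 0.2,
                           kappa_scale = 4,
                           seed = 1L) {
  cfg <- structure(as.list(environment()), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$grid) == 3, all(cfg$grid >= 4))
  if (any(abs(cfg$rho) >= 1)) stop2("target correlations must lie in (-1, 1)")
  dr <- cfg$diameter_range_nm
  if (dr[1] < 40 || dr[2] > 70 || dr[1] >= dr[2])
    stop2("diameter range must be increasing and within [40, 70] nm")
  if (any(cfg$structure_weight < 0 | cfg$structure_weight >= 1))
    stop2("structure weights must lie in [0, 1)")
  need <- c("anis_diam", "anis_fe", "anis_zn", "diam_fe", "diam_zn", "fe_zn")
  if (!all(need %in% names(cfg$rho))) stop2("rho must name all six pairs")
  invisible(cfg)
}

## 4x4 target correlation matrix over (anis, diam, fe, zn)
rho_matrix <- function(rho) {
  M <- diag(4)
  dimnames(M) <- list(c("anis", "diam", "fe", "zn"),
                      c("anis", "diam", "fe", "zn"))
  M["anis", "diam"] <- M["diam", "anis"] <- rho[["anis_diam"]]
  M["anis", "fe"] <- M["fe", "anis"] <- rho[["anis_fe"]]
  M["anis", "zn"] <- M["zn", "anis"] <- rho[["anis_zn"]]
  M["diam", "fe"] <- M["fe", "diam"] <- rho[["diam_fe"]]
  M["diam", "zn"] <- M["zn", "diam"] <- rho[["diam_zn"]]
  M["fe", "zn"] <- M["zn", "fe"] <- rho[["fe_zn"]]
  M
}

## Smooth standard-normal random field: white noise filtered with a periodic
## Gaussian kernel via 3D FFT, then standardised over the whole grid.
smooth_gaussian_field <- function(dim, scale_vox) {
  w <- array(rnorm(prod(dim)), dim = dim)
  if (scale_vox <= 0) return(w)
  kern1 <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-0.5 * (d / scale_vox)^2)
    k / sum(k)
  }
  K <- outer(outer(kern1(dim[1]), kern1(dim[2])), kern1(dim[3]))
  f <- Re(fft(fft(w) * fft(K), inverse = TRUE)) / prod(dim)
  (f - mean(f)) / sd(f)
}

## voxel-centre coordinates (mm), origin at the grid centre
voxel_coords <- function(grid, vs) {
  ax <- function(n) (seq_len(n) - (n + 1) / 2) * vs
  list(x = ax(grid[1]), y = ax(grid[2]), z = ax(grid[3]))
}

#' Generate a synthetic multimodal phantom
#'
#' Builds a cylindrical specimen with coupled smooth fields (see the module
#' comments for the copula construction), a von Mises-Fisher orientation field
#' aligned inside the lesion and uniform elsewhere, and a textured attenuation
#' map. An error is raised when the configured pairwise correlations are
#' jointly infeasible (the implied noise correlation matrix is not positive
#' semidefinite).
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; overrides `config$seed` when given.
#' @return a `phantom` with arrays `collagen_density`, `anisotropy`,
#'   `fibril_diameter`, `fe`, `zn`, `mu`, `support` and an `nx x ny x nz x 3`
#'   `orientation` array; plus `voxel_size_mm`, `config`, `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = NULL) {
  validate_phantom_config(config)
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)
  grid <- as.integer(config$grid)
  vs <- config$voxel_size_mm
  co <- voxel_coords(grid, vs)
  X <- array(rep(co$x, times = grid[2] * grid[3]), dim = grid)
  Y <- array(rep(rep(co$y, each = grid[1]), times = grid[3]), dim = grid)
  Z <- array(rep(co$z, each = grid[1] * grid[2]), dim = grid)

  r_cyl <- config$cylinder_diameter_mm / 2
  h <- config$cylinder_height_mm
  if (!is.finite(h)) h <- grid[3] * vs
  support <- (X^2 + Y^2) <= r_cyl^2 & abs(Z) <= h / 2
  if (!any(support)) stop2("support cylinder is empty on this grid")
  ns <- sum(support)

  ## deterministic lesion bump, standardised over the support
  lc <- config$lesion_center_mm
  d2 <- (X - lc[1])^2 + (Y - lc[2])^2 + (Z - lc[3])^2
  B <- exp(-0.5 * d2 / config$lesion_radius_mm^2)
  Bs <- B
  Bs[support] <- (B[support] - mean(B[support])) / sd(B[support])

  ## latent correlation targets, adjusted for the rank/uniform marginals
  rho_t <- rho_matrix(config$rho)
  rho_lat <- 2 * sin(pi * rho_t / 6)
  diag(rho_lat) <- 1
  beta <- config$structure_weight[c("anis", "diam", "fe", "zn")]
  denom <- sqrt(outer(1 - beta^2, 1 - beta^2))
  rho_noise <- (rho_lat - outer(beta, beta)) / denom
  diag(rho_noise) <- 1
  ev <- eigen(rho_noise, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop2(paste("target correlations are infeasible with the configured",
                "structure weights: implied noise correlation matrix is not",
                "positive semidefinite (min eigenvalue %.3g)"), min(ev))
  L <- chol(rho_noise + diag(4) * 1e-10)

  ## Empirical whitening over the support: project the bump out of each raw
  ## smooth field and remove their sample cross-correlation, so that the
  ## realised latent correlation equals the target by construction (variance
  ## reduction; the fields stay smooth Gaussian textures).
  raw <- lapply(1:4, function(i) smooth_gaussian_field(grid, config$texture_scale_vox))
  sv <- as.vector(support)
  b_s <- Bs[support]
  Zs <- sapply(raw, function(a) {
    z <- as.vector(a)[sv]
    z <- z - mean(z)
    z <- z - b_s * sum(z * b_s) / sum(b_s * b_s)
    z / sd(z)
  })
  Cw <- chol(stats::cov(Zs))
  Zw <- Zs %*% backsolve(Cw, diag(4))            # empirically uncorrelated
  mixed_s <- Zw %*% L                            # exact noise correlation
  lat <- lapply(1:4, function(i) {
    full <- numeric(prod(grid))
    full[sv] <- sqrt(1 - beta[i]^2) * mixed_s[, i] + beta[i] * b_s
    full
  })

  ## rank transform over the support -> uniform -> configured range
  to_range <- function(z, rng) {
    u <- numeric(length(z))
    zi <- z[as.vector(support)]
    u[as.vector(support)] <- (rank(zi, ties.method = "average") - 0.5) / length(zi)
    rng[1] + u * (rng[2] - rng[1])
  }
  anis <- array(to_range(lat[[1]], config$anisotropy_range), dim = grid)
  diam <- array(to_range(lat[[2]], config$diameter_range_nm), dim = grid)
  fe <- array(to_range(lat[[3]], config$fe_range), dim = grid)
  zn <- array(to_range(lat[[4]], config$zn_range), dim = grid)

  ## guarantee the aligned region reaches the configured anisotropy target
  aligned <- support & d2 <= config$lesion_radius_mm^2
  ramp <- pmin(1, pmax(0, (B - exp(-0.5)) / (1 - exp(-0.5))))
  floor_a <- config$target_anisotropy * ramp
  anis[aligned] <- pmax(anis[aligned], floor_a[aligned])

  ## collagen density and attenuation from their own smooth latents
  dens_lat <- smooth_gaussian_field(grid, config$texture_scale_vox)
  density <- array(to_range(dens_lat, c(0.3, 1)), dim = grid)
  mu_lat <- smooth_gaussian_field(grid, config$texture_scale_vox)
  mu <- array(to_range(mu_lat,
                       config$mu_mm_inv * c(1 - config$mu_texture,
                                            1 + config$mu_texture)),
              dim = grid)

  ## orientation: vMF around the configured axis in the aligned region,
  ## uniform on the sphere elsewhere
  axis <- config$aligned_axis / sqrt(sum(config$aligned_axis^2))
  n_vox <- prod(grid)
  orient <- matrix(rnorm(3 * n_vox), n_vox, 3)
  orient <- orient / sqrt(rowSums(orient^2))
  ai <- which(as.vector(aligned))
  if (length(ai) > 0) {
    a_here <- pmin(anis[ai], 0.999)
    kappa <- config$kappa_scale * a_here / (1 - a_here)
    orient[ai, ] <- rvmf(length(ai), axis, kappa)
  }
  zero <- !as.vector(support)
  orient[zero, ] <- 0
  for (a in c("anis", "diam", "fe", "zn", "density", "mu")) {
    v <- get(a); v[!support] <- 0; assign(a, v)
  }
  odim <- c(grid, 3L)
  structure(list(
    collagen_density = density,
    orientation = array(orient, dim = odim),
    anisotropy = anis,
    fibril_diameter = diam,
    fe = fe, zn = zn, mu = mu,
    support = support,
    voxel_size_mm = vs,
    config = config,
    seed = seed), class = "phantom")
}

## von Mises-Fisher sampler on S^2 (inverse-CDF for the polar angle)
rvmf <- function(n, mu, kappa) {
  kappa <- pmax(rep_len(kappa, n), 1e-6)
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - w^2))
  ## orthonormal frame around mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  out <- outer(w, mu) + outer(r * cos(phi), e1) + outer(r * sin(phi), e2)
  out / sqrt(rowSums(out^2))
}

#' Extract ground-truth maps from a phantom
#'
#' Restricts the four analysis fields to a box region of interest, masked by
#' the support.
#'
#' @param phantom a [generate_phantom()] result.
#' @param roi list with integer ranges `x`, `y`, `z` (inclusive), or `NULL`
#'   for the full grid.
#' @return list of `scalar_volume`s `anisotropy`, `diameter`, `fe`, `zn`.
#' @export
phantom_ground_truth_maps <- function(phantom, roi = NULL) {
  grid <- dim(phantom$anisotropy)
  if (is.null(roi)) roi <- list(x = c(1, grid[1]), y = c(1, grid[2]),
                                z = c(1, grid[3]))
  for (ax in c("x", "y", "z")) {
    r <- roi[[ax]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      stop2("roi range for %s is empty or malformed", ax)
  }
  i <- roi$x[1]:roi$x[2]; j <- roi$y[1]:roi$y[2]; k <- roi$z[1]:roi$z[2]
  if (max(i) > grid[1] || max(j) > grid[2] || max(k) > grid[3] ||
      min(c(i, j, k)) < 1)
    stop2("roi exceeds the phantom grid")
  sub <- function(a, label) scalar_volume(a[i, j, k, drop = FALSE],
                                          phantom$voxel_size_mm, label,
                                          mask = phantom$support[i, j, k, drop = FALSE])
  list(anisotropy = sub(phantom$anisotropy, "anisotropy"),
       diameter = sub(phantom$fibril_diameter, "diameter"),
       fe = sub(phantom$fe, "Fe"),
       zn = sub(phantom$zn, "Zn"))
}
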