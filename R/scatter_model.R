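## Collagen small-angle scattering model: q-space conversions, the
## cylinder + axial-period profile, tensor anisotropy measures, azimuthal
## integration of 2D patterns, and the fibril-parameter fit.

HC_KEV_NM <- 1.239842  # hc, keV * nm

#' Beam specification
#'
#' @param energy_kev photon energy in keV.
#' @return a `beam_spec` with `energy_kev` and the derived `wavelength_nm`.
#' @export
beam_spec <- function(energy_kev = 12.4) {
  structure(list(energy_kev = energy_kev,
                 wavelength_nm = wavelength_from_energy(energy_kev)),
            class = "beam_spec")
}

#' X-ray wavelength from photon energy
#'
#' lambda = hc / E with hc = 1.239842 keV nm.
#'
#' @param energy_kev photon energy in keV, > 0.
#' @return wavelength in nm.
#' @export
wavelength_from_energy <- function(energy_kev) {
  if (any(!is.finite(energy_kev)) || any(energy_kev <= 0))
    stop2("energy must be positive and finite (got %s)", toString(energy_kev))
  HC_KEV_NM / energy_kev
}

#' Momentum transfer from scattering angle
#'
#' q = 4 pi sin(theta/2) / lambda.
#'
#' @param theta scattering angle in radians, in [0, pi).
#' @param wavelength_nm wavelength in nm, > 0.
#' @return q in nm^-1.
#' @export
q_from_angle <- function(theta, wavelength_nm) {
  if (any(wavelength_nm <= 0)) stop2("wavelength must be positive")
  if (any(theta < 0 | theta >= pi)) stop2("theta must lie in [0, pi)")
  4 * pi * sin(theta / 2) / wavelength_nm
}

#' Collagen fibril profile parameters
#'
#' Parameters of the 1D scattering model: cylinders of radius `R_nm` with an
#' axially periodic step-function electron density of period `D_nm` and
#' overlap fraction `f`, optionally packed on a hexagonal lattice of spacing
#' `a_hex_nm`.
#'
#' @param D_nm axial period (nm), in [55, 75].
#' @param R_nm fibril radius (nm), in [15, 40].
#' @param f overlap fraction in (0, 1); the collagen overlap/gap ratio makes
#'   odd reflection orders strong for f near 0.5.
#' @param scale non-negative intensity scale.
#' @param background non-negative additive constant.
#' @param peak_width_nm_inv Gaussian sigma of the axial reflections (nm^-1).
#' @param a_hex_nm optional hexagonal lattice spacing (nm); `NA` disables the
#'   interference peak.
#' @param hex_amp amplitude of the optional hexagonal peak.
#' @return a `collagen_params` list.
#' @export
collagen_params <- function(D_nm = 65, R_nm = 25, f = 0.53, scale = 1,
                            background = 0, peak_width_nm_inv = 0.02,
                            a_hex_nm = NA_real_, hex_amp = 0) {
  p <- structure(list(D_nm = D_nm, R_nm = R_nm, f = f, scale = scale,
                      background = background,
                      peak_width_nm_inv = peak_width_nm_inv,
                      a_hex_nm = a_hex_nm, hex_amp = hex_amp),
                 class = "collagen_params")
  validate_collagen_params(p)
  p
}

validate_collagen_params <- function(p) {
  if (p$D_nm < 55 || p$D_nm > 75) stop2("axial period D must lie in [55, 75] nm")
  if (p$R_nm < 15 || p$R_nm > 40) stop2("fibril radius R must lie in [15, 40] nm")
  if (p$f <= 0 || p$f >= 1) stop2("overlap fraction f must lie in (0, 1)")
  if (p$scale < 0 || p$background < 0) stop2("scale and background must be >= 0")
  if (p$peak_width_nm_inv <= 0) stop2("peak width must be > 0")
  invisible(p)
}

#' Cylinder cross-section form factor
#'
#' `[2 J1(qR) / (qR)]^2` for a homogeneous circular cylinder of radius R
#' probed perpendicular to its axis; its first zero sits at `q = 3.8317 / R`.
#'
#' @param q momentum transfer (nm^-1).
#' @param R cylinder radius (nm).
#' @return the dimensionless factor, 1 at q = 0.
#' @export
cylinder_form_factor <- function(q, R) cylinder_factor(q, R)

## internal alias used throughout
cylinder_factor <- function(q, R) {
  x <- q * R
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- (2 * besselj(x[nz], 1) / x[nz])^2
  out
}

besselj <- function(x, nu) besselJ(x, nu)

#' Model 1D SAXS profile of collagen fibrils
#'
#' I(q) = scale * C(q; R) * sum_n w_n(f) G(q - 2 pi n / D; sigma)
#'        + hex_amp * G(q - 4 pi / (a_hex sqrt(3)); sigma) + background,
#' with C the circular-cylinder cross-section factor [2 J1(qR)/(qR)]^2,
#' Gaussian axial reflections of common width, and step-function Fourier
#' weights w_n = sin^2(pi n f) / (pi n)^2. Orders are summed far enough past
#' the q-range that adding more changes nothing at double precision.
#'
#' @param q_grid strictly increasing positive q values (nm^-1).
#' @param params a [collagen_params()].
#' @return intensity vector, >= background everywhere.
#' @export
collagen_profile <- function(q_grid, params) {
  validate_collagen_params(params)
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0))
    stop2("q_grid must be strictly increasing and positive")
  sig <- params$peak_width_nm_inv
  n_max <- ceiling((max(q_grid) + 8 * sig) * params$D_nm / (2 * pi))
  acc <- numeric(length(q_grid))
  for (n in seq_len(n_max)) {
    w_n <- (sin(pi * n * params$f) / (pi * n))^2
    qc <- 2 * pi * n / params$D_nm
    acc <- acc + w_n * exp(-0.5 * ((q_grid - qc) / sig)^2)
  }
  out <- params$scale * cylinder_factor(q_grid, params$R_nm) * acc
  if (is.finite(params$a_hex_nm) && params$hex_amp > 0) {
    q_hex <- 4 * pi / (params$a_hex_nm * sqrt(3))
    out <- out + params$hex_amp * exp(-0.5 * ((q_grid - q_hex) / sig)^2)
  }
  out + params$background
}

#' Fit the fibril model to a 1D profile
#'
#' Bounded least squares of [collagen_profile()] against a measured profile,
#' with multi-start over initial radii (20, 25, 30 nm by default) and the
#' lowest chi-squared kept. The fibril diameter is reported as `2 R`.
#'
#' @param q q values (nm^-1); at least 30 points spanning reflection
#'   orders 3-6 are required.
#' @param intensity measured intensities.
#' @param init a [collagen_params()] used as the starting point (its `R_nm` is
#'   replaced by each multi-start value; `scale` and `background` are solved
#'   linearly, not searched).
#' @param lower,upper named bounds for the nonlinear parameters `D_nm`,
#'   `R_nm`, `f`, `peak_width_nm_inv`.
#' @param sigma per-point uncertainties for the chi-squared. The default
#'   `"relative"` weights by the observed intensity (multiplicative-error
#'   model: SAXS profiles span decades, and absolute residuals would be
#'   dominated by the lowest orders); a numeric vector gives absolute
#'   uncertainties.
#' @param multistart_R starting radii in nm; the lowest chi-squared start
#'   wins.
#' @param control L-BFGS-B control list (see [stats::optim()]).
#' @return a list with `params` (fitted [collagen_params()]), `diameter_nm`
#'   (= 2 R), `chi2_red`, `converged`.
#' @details The fit is a variable-projection bounded least squares: for each
#'   trial of the nonlinear parameters, the best `scale` and `background` are
#'   obtained by weighted linear least squares (clamped at 0), so only four
#'   parameters are searched with L-BFGS-B.
#' @export
fit_fibril_params <- function(q, intensity, init = collagen_params(),
                              lower = c(D_nm = 55, R_nm = 20, f = 0.2,
                                        peak_width_nm_inv = 0.005),
                              upper = c(D_nm = 75, R_nm = 35, f = 0.8,
                                        peak_width_nm_inv = 0.1),
                              sigma = "relative",
                              multistart_R = c(20, 25, 30),
                              control = list(maxit = 300, factr = 1e3)) {
  if (any(!is.finite(intensity))) stop2("intensities must be finite")
  if (length(q) < 30) stop2("need at least 30 q-points")
  q_lo <- 2 * pi * 3 / 75; q_hi <- 2 * pi * 6 / 55
  if (min(q) > q_lo || max(q) < q_hi)
    stop2("q-range must span reflection orders 3-6")
  if (identical(sigma, "relative")) {
    sigma <- pmax(abs(intensity), 1e-3 * max(abs(intensity), 1e-300))
  }
  nl_names <- c("D_nm", "R_nm", "f", "peak_width_nm_inv")
  w <- 1 / sigma
  base_at <- function(p) {
    prm <- modifyList2(init, c(as.list(setNames(p, nl_names)),
                               list(scale = 1, background = 0)))
    collagen_profile(q, prm)
  }
  ## weighted linear solve for (scale, background) given the base shape
  lin_solve <- function(base) {
    A <- cbind(base, 1) * w
    cf <- tryCatch(qr.coef(qr(A), intensity * w), error = function(e) c(0, 0))
    cf[is.na(cf)] <- 0
    pmax(cf, 0)
  }
  objfun <- function(p) {
    base <- base_at(p)
    cf <- lin_solve(base)
    r <- (cf[1] * base + cf[2] - intensity) * w
    sum(r * r)
  }
  p0 <- unlist(init[nl_names])
  best <- NULL
  for (R0 in multistart_R) {
    p0i <- p0
    p0i["R_nm"] <- R0
    p0i <- pmin(pmax(p0i, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      optim(p0i, objfun, method = "L-BFGS-B", lower = lower, upper = upper,
            control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(params = init, diameter_nm = NA_real_, chi2_red = NA_real_,
                converged = FALSE))
  cf <- lin_solve(base_at(best$par))
  prm <- modifyList2(init, c(as.list(setNames(best$par, nl_names)),
                             list(scale = unname(cf[1]),
                                  background = unname(cf[2]))))
  dof <- max(1L, length(q) - 6L)
  ## code 52 is L-BFGS-B stopping because the line search hit the precision
  ## limit of the finite-difference gradient -- a convergence, not a failure;
  ## exhausting maxit (code 1) is reported as non-convergence
  list(params = prm,
       diameter_nm = 2 * prm$R_nm,
       chi2_red = best$value / dof,
       converged = best$convergence %in% c(0L, 52L))
}

#' Symmetric rank-2 tensor from six components
#'
#' Components ordered (a11, a22, a33, a12, a13, a23).
#'
#' @param comp numeric vector of length 6.
#' @return a 3x3 symmetric matrix.
#' @export
tensor_from_components <- function(comp) {
  stopifnot(length(comp) == 6)
  matrix(c(comp[1], comp[4], comp[5],
           comp[4], comp[2], comp[6],
           comp[5], comp[6], comp[3]), 3, 3)
}

#' Probe a symmetric tensor along a direction
#'
#' Returns u' A u, the scattering intensity model of a rank-2 reciprocal-space
#' map probed along unit vector u.
#'
#' @param A 3x3 symmetric matrix.
#' @param u unit 3-vector (or `n x 3` matrix of unit vectors).
#' @return scalar (or vector) of probed intensities.
#' @export
tensor_probe <- function(A, u) {
  if (is.matrix(u) && ncol(u) == 3 && nrow(u) > 1) {
    return(rowSums((u %*% A) * u))
  }
  u <- as.numeric(u)
  drop(t(u) %*% A %*% u)
}

## Quadratic-form coefficient vector m(u) so that u' A u = m(u) . comp(A)
## with comp = (a11,a22,a33,a12,a13,a23).
probe_coefficients <- function(u) {
  if (!is.matrix(u)) u <- matrix(u, 1, 3)
  cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
        2 * u[, 1] * u[, 2], 2 * u[, 1] * u[, 3], 2 * u[, 2] * u[, 3])
}

#' Degree of anisotropy of a tensor
#'
#' Standard deviation of u' A u divided by its mean, over a deterministic
#' near-uniform (Fibonacci spiral) set of sphere directions. Zero for an
#' isotropic tensor; 2/sqrt(5) for a uniaxial diag(1,0,0).
#'
#' @param A 3x3 symmetric matrix.
#' @param n_dirs number of sphere directions (default 10^4).
#' @return non-negative scalar.
#' @export
anisotropy_degree <- function(A, n_dirs = 10000L) {
  u <- sphere_directions(n_dirs)
  v <- tensor_probe(A, u)
  m <- mean(v)
  if (abs(m) < .Machine$double.eps * 100)
    stop2("tensor has zero mean probe intensity; anisotropy undefined")
  sd(v) / m
}

#' Azimuthal integration of a 2D scattering pattern
#'
#' Radially integrates a detector image into `n_segments` azimuthal segments
#' and the given q-bins. Segment k covers azimuth [k, k+1) * 360/n degrees
#' measured counter-clockwise from the detector +y axis (image columns);
#' membership is by pixel-centre angle. Empty bins are returned as `NA` and
#' flagged, not zero-filled.
#'
#' @param image 2D matrix of counts; rows are detector z, columns detector y.
#' @param center beam centre `c(row, col)` in pixel units.
#' @param pixel_size_mm detector pixel pitch (mm).
#' @param distance_mm sample-detector distance (mm).
#' @param beam a [beam_spec()].
#' @param n_segments number of azimuthal segments (>= 1).
#' @param q_edges increasing q-bin edges (nm^-1).
#' @return list with `intensity` (`n_segments x n_bins` mean counts),
#'   `n_pixels` (same shape), `q_mid`, and `empty` (logical flags).
#' @export
integrate_pattern_2d <- function(image, center, pixel_size_mm, distance_mm,
                                 beam, n_segments, q_edges) {
  stopifnot(is.matrix(image), n_segments >= 1)
  if (any(diff(q_edges) <= 0)) stop2("q_edges must be strictly increasing")
  if (center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image))
    stop2("beam center lies outside the image")
  rows <- row(image) - center[1]   # detector z
  cols <- col(image) - center[2]   # detector y
  r_px <- sqrt(rows^2 + cols^2)
  theta <- atan(r_px * pixel_size_mm / distance_mm)
  q <- q_from_angle(theta, beam$wavelength_nm)
  phi <- atan2(rows, cols) %% (2 * pi)  # CCW from +y
  seg <- pmin(floor(phi / (2 * pi / n_segments)), n_segments - 1) + 1L
  qbin <- findInterval(q, q_edges, rightmost.closed = TRUE)
  keep <- qbin >= 1L & qbin <= (length(q_edges) - 1L)
  n_bins <- length(q_edges) - 1L
  idx <- (qbin[keep] - 1L) * n_segments + seg[keep]
  sums <- numeric(n_segments * n_bins)
  cnts <- numeric(n_segments * n_bins)
  tap <- tapply(image[keep], idx, sum)
  sums[as.integer(names(tap))] <- tap
  tap <- tapply(rep(1, sum(keep)), idx, sum)
  cnts[as.integer(names(tap))] <- tap
  mean_i <- matrix(sums / ifelse(cnts > 0, cnts, NA), n_segments, n_bins)
  list(intensity = mean_i,
       n_pixels = matrix(cnts, n_segments, n_bins),
       q_mid = (head(q_edges, -1) + tail(q_edges, -1)) / 2,
       empty = matrix(cnts == 0, n_segments, n_bins))
}

#' Write azimuthally integrated profiles to CSV
#'
#' Long format with columns `q_nm_inv`, `segment`, `intensity`, `sigma`
#' (Poisson counting error of the bin mean); empty bins are omitted.
#'
#' @param profiles an [integrate_pattern_2d()] result.
#' @param path output file.
#' @export
write_profiles_csv <- function(profiles, path) {
  n_seg <- nrow(profiles$intensity)
  df <- data.frame(
    q_nm_inv = rep(profiles$q_mid, each = n_seg),
    segment = rep(seq_len(n_seg), times = length(profiles$q_mid)),
    intensity = as.vector(profiles$intensity),
    sigma = sqrt(pmax(as.vector(profiles$intensity), 0) /
                   pmax(as.vector(profiles$n_pixels), 1)))
  df <- df[!as.vector(profiles$empty), ]
  data.table::fwrite(df, path)
  invisible(path)
}
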