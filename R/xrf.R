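## XRF spectrum processing: energy calibration, K-line peak fitting,
## normalisation, self-absorption correction, and element-map reconstruction.

#' Energy calibration from a reference spectrum
#'
#' Locates the strongest local maxima of the reference spectrum, refines each
#' centroid by parabolic interpolation, and fits a straight line
#' `energy = offset + gain * channel` (channels 0-based) through the located
#' peaks paired with the known line energies in increasing order.
#'
#' @param reference_spectrum counts per channel.
#' @param known_lines_kev at least two known line energies (keV).
#' @param min_prominence peaks below this fraction of the global maximum are
#'   ignored.
#' @return an `energy_calibration`: list with `gain_kev`, `offset_kev`.
#' @export
calibrate_energy <- function(reference_spectrum, known_lines_kev,
                             min_prominence = 0.05) {
  y <- as.numeric(reference_spectrum)
  n <- length(y)
  if (length(known_lines_kev) < 2) stop2("need at least 2 known lines")
  i <- 2:(n - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] >= min_prominence * max(y)
  peaks <- i[is_max]
  if (length(peaks) < 2)
    stop2("fewer than 2 peaks located in the reference spectrum")
  ## keep the strongest |known_lines| peaks, then order by channel
  ord <- order(y[peaks], decreasing = TRUE)
  peaks <- sort(peaks[ord[seq_len(min(length(peaks), length(known_lines_kev)))]])
  if (length(peaks) < 2) stop2("fewer than 2 usable peaks")
  ## parabolic refinement of each centroid
  delta <- 0.5 * (y[peaks - 1] - y[peaks + 1]) /
    (y[peaks - 1] - 2 * y[peaks] + y[peaks + 1])
  ch <- (peaks - 1) + delta               # 0-based channel coordinate
  lines <- sort(known_lines_kev)[seq_along(ch)]
  fit <- lm(lines ~ ch)
  gain <- unname(coef(fit)[2]); offset <- unname(coef(fit)[1])
  if (gain <= 0) stop2("calibration produced non-positive gain")
  structure(list(gain_kev = gain, offset_kev = offset),
            class = "energy_calibration")
}

## energy axis (keV) of a spectrum under a calibration (channels 0-based)
channel_energies <- function(n_channels, calibration) {
  calibration$offset_kev + calibration$gain_kev * (seq_len(n_channels) - 1)
}

## Design matrix of the linear sub-problem: one column per free area
## (K-beta tied to K-alpha by rel_int unless kb_free) plus linear background.
xrf_design <- function(e_win, sigma, line_table, gain_kev, kb_free) {
  elements <- unique(line_table$element)
  cols <- list()
  for (el in elements) {
    lt <- line_table[line_table$element == el, , drop = FALSE]
    if (kb_free) {
      for (li in seq_len(nrow(lt)))
        cols[[paste(el, lt$line[li], sep = "_")]] <-
          dnorm(e_win, lt$energy_kev[li], sigma) * gain_kev
    } else {
      shape <- 0
      for (li in seq_len(nrow(lt)))
        shape <- shape + lt$rel_int[li] * dnorm(e_win, lt$energy_kev[li], sigma) * gain_kev
      cols[[el]] <- shape
    }
  }
  cols$bg0 <- rep(1, length(e_win))
  cols$bg1 <- e_win - mean(e_win)
  do.call(cbind, cols)
}

#' Fit K-alpha/K-beta emission peaks in one spectrum
#'
#' Gaussian peaks with centroids pinned at the table energies and a common
#' width, plus a linear background, fitted over the 5.5-10.5 keV window.
#' The width is the only nonlinear parameter (found by golden-section
#' search); for each width the areas and background are solved linearly
#' (variable projection). K-beta areas are tied to K-alpha by the table's
#' relative intensity unless `kb_free`.
#'
#' @param spectrum counts per channel.
#' @param calibration an `energy_calibration`.
#' @param line_table emission-line table (see [default_line_table()]).
#' @param window_kev fit window (keV).
#' @param sigma_bounds_kev search range for the common peak width.
#' @param kb_free free the K-beta areas instead of tying them.
#' @return a `peak_fit`: data.frame `areas` (element, ka_area, kb_area,
#'   centroid_kev, width_kev), `background` coefficients, `chi2`,
#'   `degenerate` flag.
#' @export
fit_spectrum <- function(spectrum, calibration,
                         line_table = default_line_table(),
                         window_kev = c(5.5, 10.5),
                         sigma_bounds_kev = c(0.02, 0.2),
                         kb_free = FALSE) {
  e <- channel_energies(length(spectrum), calibration)
  if (min(e) > 5 || max(e) < 11)
    stop2("calibrated axis must cover 5-11 keV")
  win <- e >= window_kev[1] & e <= window_kev[2]
  y <- as.numeric(spectrum[win]); e_win <- e[win]
  elements <- unique(line_table$element)
  if (all(y == 0)) {
    areas <- data.frame(element = elements, ka_area = 0, kb_area = 0,
                        centroid_kev = vapply(elements, function(el)
                          line_table$energy_kev[line_table$element == el &
                                                  line_table$line == "Ka"][1], 0),
                        width_kev = NA_real_)
    return(structure(list(areas = areas, background = c(0, 0), chi2 = 0,
                          degenerate = TRUE), class = "peak_fit"))
  }
  rss_at <- function(sig) {
    A <- xrf_design(e_win, sig, line_table, calibration$gain_kev, kb_free)
    fit <- lm.fit(A, y)
    sum(fit$residuals^2)
  }
  opt <- optimize(rss_at, sigma_bounds_kev, tol = 1e-6)
  sig <- opt$minimum
  A <- xrf_design(e_win, sig, line_table, calibration$gain_kev, kb_free)
  fit <- lm.fit(A, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  kb_ratio <- vapply(elements, function(el) {
    r <- line_table$rel_int[line_table$element == el & line_table$line == "Kb"]
    if (length(r)) r[1] else 0
  }, 0)
  if (kb_free) {
    ka <- pmax(0, cf[paste0(elements, "_Ka")])
    kb <- pmax(0, cf[paste0(elements, "_Kb")])
  } else {
    ka <- pmax(0, cf[elements])
    kb <- ka * kb_ratio
  }
  areas <- data.frame(
    element = elements,
    ka_area = unname(ka), kb_area = unname(kb),
    centroid_kev = vapply(elements, function(el)
      line_table$energy_kev[line_table$element == el & line_table$line == "Ka"][1], 0),
    width_kev = sig)
  structure(list(areas = areas,
                 background = unname(cf[c("bg0", "bg1")]),
                 chi2 = opt$objective,
                 degenerate = FALSE), class = "peak_fit")
}

## Batched area fitting of many spectra sharing one width: the width is
## estimated once on the summed spectrum, then all areas follow from a single
## linear solve. Returns a matrix n_spec x n_elements.
fit_spectra_batch <- function(spectra_mat, calibration,
                              line_table = default_line_table(),
                              window_kev = c(5.5, 10.5),
                              sigma_bounds_kev = c(0.02, 0.2)) {
  e <- channel_energies(ncol(spectra_mat), calibration)
  win <- e >= window_kev[1] & e <= window_kev[2]
  e_win <- e[win]
  Y <- t(spectra_mat[, win, drop = FALSE])   # n_win x n_spec
  ysum <- rowSums(Y)
  rss_at <- function(sig) {
    A <- xrf_design(e_win, sig, line_table, calibration$gain_kev, FALSE)
    sum(lm.fit(A, ysum)$residuals^2)
  }
  sig <- optimize(rss_at, sigma_bounds_kev, tol = 1e-6)$minimum
  A <- xrf_design(e_win, sig, line_table, calibration$gain_kev, FALSE)
  cf <- qr.coef(qr(A), Y)                    # n_coef x n_spec
  cf[is.na(cf)] <- 0
  elements <- unique(line_table$element)
  out <- t(pmax(cf[seq_along(elements), , drop = FALSE], 0))
  colnames(out) <- elements
  out
}

#' Normalise fitted areas by exposure and flux
#'
#' @param areas array or matrix of fitted areas (counts).
#' @param exposure_s exposure time (s), > 0.
#' @param flux incident flux (photons/s), > 0.
#' @return areas / (exposure * flux).
#' @export
normalize_areas <- function(areas, exposure_s, flux) {
  if (exposure_s <= 0 || flux <= 0) stop2("exposure and flux must be positive")
  areas / (exposure_s * flux)
}

#' Self-absorption correction of an XRF sinogram
#'
#' Multiplies each sinogram point by `T^-(1 + (E_beam/E_line)^3)/2`: a
#' geometric-mean path model in which the incident beam is attenuated (at the
#' beam energy) over half its chord on average, and the fluorescence exits
#' over a comparable path with mu scaled by `(E_beam/E_line)^3`. The factor is
#' always >= 1 and increases as transmission drops.
#'
#' @param sinogram normalised area sinogram (any numeric array).
#' @param transmission matching transmission values in (0, 1].
#' @param line_energy_kev fluorescence line energy.
#' @param beam_energy_kev incident beam energy.
#' @return corrected sinogram, same shape.
#' @export
correct_self_absorption <- function(sinogram, transmission,
                                    line_energy_kev, beam_energy_kev) {
  if (!identical(dim(sinogram) %||% length(sinogram),
                 dim(transmission) %||% length(transmission)))
    stop2("sinogram and transmission shapes differ")
  if (any(transmission <= 0 | transmission > 1 + 1e-9))
    stop2("transmission must lie in (0, 1]")
  s_pow <- (beam_energy_kev / line_energy_kev)^3
  sinogram * transmission^(-(1 + s_pow) / 2)
}

#' Element maps from an XRF scan
#'
#' Full XRF-CT chain: per-point peak fitting, normalisation by exposure and
#' flux, self-absorption correction from the transmission sinogram, and
#' Hamming-filtered FBP per slice and element.
#'
#' @param scan an [simulate_xrf_scan()] result.
#' @param calibration an `energy_calibration`; defaults to the scan's true
#'   calibration.
#' @param transmission a [simulate_transmission()] result, or `NULL` to skip
#'   the self-absorption correction.
#' @param filter FBP filter.
#' @param elements which elements to reconstruct.
#' @return named list of `scalar_volume`s, one per element, in concentration
#'   units (the detector constant is divided out).
#' @export
element_maps <- function(scan, calibration = NULL, transmission = NULL,
                         filter = "hamming", elements = c("Fe", "Zn")) {
  geom <- scan$geometry
  if (is.null(calibration))
    calibration <- structure(list(gain_kev = scan$calibration$gain_kev,
                                  offset_kev = scan$calibration$offset_kev),
                             class = "energy_calibration")
  n_rot <- dim(scan$spectra)[1]
  n_ray <- dim(scan$spectra)[2]
  ## flattening (n_rot, n_ray, n_ch) column-major: rows are rotation-fastest
  spec_mat <- matrix(scan$spectra, n_rot * n_ray, dim(scan$spectra)[3])
  areas <- fit_spectra_batch(spec_mat, calibration, geom$line_table)
  out <- list()
  trans_rows <- NULL
  if (!is.null(transmission)) {
    i0 <- tilt0_index(transmission$proj_index)
    idx <- match(round(scan$proj_index$omega, 9),
                 round(transmission$proj_index$omega[i0], 9))
    if (any(is.na(idx)))
      stop2("transmission sinogram does not cover the XRF rotations")
    trans_rows <- transmission$transmission[i0[idx], , drop = FALSE]
  }
  for (el in elements) {
    sino <- matrix(areas[, el], n_rot, n_ray)   # rows rotations, ray-major cols
    sino <- normalize_areas(sino, geom$exposure_s, geom$flux) / geom$xrf_sens
    if (!is.null(trans_rows)) {
      e_line <- geom$line_table$energy_kev[geom$line_table$element == el &
                                             geom$line_table$line == "Ka"][1]
      sino <- correct_self_absorption(sino, trans_rows, e_line,
                                      geom$beam$energy_kev)
    }
    vol <- fbp_volume(sino, scan$proj_index$omega, geom$n_y, geom$n_z,
                      geom$step_mm, filter)
    out[[el]] <- scalar_volume(vol, geom$step_mm, el)
  }
  out
}
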