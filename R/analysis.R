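## Results-level computations: reverse analysis to per-voxel SAXS profiles,
## fibril-diameter mapping, low-collagen masking, 0-255 normalisation, and the
## pairwise cross-correlation table.

#' Retrieve per-voxel SAXS profiles from q-resolved reconstructions
#'
#' The "reverse analysis": with every q-bin reconstructed on a common grid,
#' each unmasked voxel of the region of interest yields a full 1D scattering
#' profile.
#'
#' @param q_volumes a [reconstruct_q_volumes()] result (list with `volumes`
#'   and `q_mid`).
#' @param roi list of inclusive index ranges `x`, `y`, `z`, or `NULL` for the
#'   full grid.
#' @param mask optional logical array on the full grid; only voxels that are
#'   `TRUE` contribute.
#' @return list with `q` (ascending), `intensity` (`n_voxel x n_q`), and
#'   `voxel_index` (linear indices into the full grid, for map assembly).
#' @export
reverse_profiles <- function(q_volumes, roi = NULL, mask = NULL) {
  vols <- q_volumes$volumes
  q <- q_volumes$q_mid
  ord <- order(q)
  grid <- dim(vols[[1]]$values)
  if (is.null(roi)) roi <- list(x = c(1, grid[1]), y = c(1, grid[2]),
                                z = c(1, grid[3]))
  in_roi <- array(FALSE, dim = grid)
  in_roi[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2]] <- TRUE
  if (!is.null(mask)) in_roi <- in_roi & mask
  idx <- which(in_roi)
  if (length(idx) == 0) stop2("no unmasked voxels in the region of interest")
  intensity <- vapply(vols[ord], function(v) v$values[idx], numeric(length(idx)))
  list(q = q[ord],
       intensity = matrix(intensity, nrow = length(idx)),
       voxel_index = idx, grid = grid)
}

#' Fibril diameter map from per-voxel profiles
#'
#' Runs [fit_fibril_params()] on every profile; voxels whose fit does not
#' converge are masked out. Values are reported as the diameter 2R (nm).
#'
#' @param profiles a [reverse_profiles()] result.
#' @param voxel_size_mm voxel size of the output volume.
#' @param init,multistart_R fit options passed to [fit_fibril_params()].
#' @param control optimiser control; the default is looser than the
#'   single-profile default, trading a little precision for per-voxel speed.
#' @return a `scalar_volume` labelled "diameter" with the convergence mask.
#' @export
diameter_map <- function(profiles, voxel_size_mm = 1,
                         init = collagen_params(D_nm = 65.45),
                         multistart_R = c(20, 25, 30),
                         control = list(maxit = 120, factr = 1e7)) {
  n_vox <- nrow(profiles$intensity)
  vals <- numeric(n_vox)
  ok <- logical(n_vox)
  ## warm start: neighbouring voxels have similar fibrils, so after the first
  ## full multi-start fit, seed each fit from the last success and fall back
  ## to the full multi-start when the fit degrades
  warm_R <- NULL
  chi_hist <- c()
  for (v in seq_len(n_vox)) {
    starts <- if (is.null(warm_R)) multistart_R else warm_R
    fit <- tryCatch(
      fit_fibril_params(profiles$q, profiles$intensity[v, ], init = init,
                        multistart_R = starts, control = control),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(warm_R) && length(chi_hist) >= 5 &&
        is.finite(fit$chi2_red) &&
        fit$chi2_red > 25 * stats::median(chi_hist)) {
      fit2 <- tryCatch(
        fit_fibril_params(profiles$q, profiles$intensity[v, ], init = init,
                          multistart_R = multistart_R, control = control),
        error = function(e) NULL)
      if (!is.null(fit2) && is.finite(fit2$chi2_red) &&
          fit2$chi2_red < fit$chi2_red) fit <- fit2
    }
    if (!is.null(fit) && isTRUE(fit$converged) && is.finite(fit$diameter_nm)) {
      vals[v] <- fit$diameter_nm
      ok[v] <- TRUE
      warm_R <- fit$diameter_nm / 2
      chi_hist <- c(tail(chi_hist, 49), fit$chi2_red)
    }
  }
  out <- array(0, dim = profiles$grid)
  m <- array(FALSE, dim = profiles$grid)
  out[profiles$voxel_index] <- vals
  m[profiles$voxel_index] <- ok
  scalar_volume(out, voxel_size_mm, "diameter", mask = m)
}

#' Mask out voxels with little or no collagen
#'
#' Keeps a voxel iff its mean-scattering value is at least `fraction` times
#' the maximum over the volume's own mask.
#'
#' @param mean_scattering a `scalar_volume`.
#' @param fraction threshold fraction in [0, 1); default 0.10.
#' @return logical array.
#' @export
mask_low_collagen <- function(mean_scattering, fraction = 0.10) {
  if (fraction < 0 || fraction >= 1) stop2("fraction must lie in [0, 1)")
  v <- mean_scattering$values
  vmax <- max(v[mean_scattering$mask])
  mean_scattering$mask & v >= fraction * vmax
}

#' Affine 0-255 normalisation of a map
#'
#' Maps the unmasked minimum to 0 and maximum to 255; values stay real
#' (no integer rounding). Pearson correlations between maps are unchanged by
#' this transform.
#'
#' @param volume a `scalar_volume`.
#' @param mask logical array; defaults to the volume's own mask.
#' @return a `scalar_volume` with normalised values (masked-out voxels 0).
#' @export
normalize_0_255 <- function(volume, mask = NULL) {
  mask <- mask %||% volume$mask
  v <- volume$values[mask]
  if (length(v) < 2 || diff(range(v)) == 0)
    stop2("normalisation undefined: fewer than 2 distinct unmasked values")
  out <- array(0, dim = dim(volume$values))
  out[mask] <- (volume$values[mask] - min(v)) / diff(range(v)) * 255
  scalar_volume(out, volume$voxel_size_mm,
                paste0(volume$label, " (0-255)"), mask = mask)
}

#' Pairwise cross-correlation table of the four analysis maps
#'
#' Voxel-wise Pearson correlation between the degree of collagen orientation,
#' fibril diameter, Fe and Zn maps over a common mask. The table is symmetric
#' with a unit diagonal; a field that is constant under the mask gets `NA` in
#' its row/column and is flagged.
#'
#' @param orientation_degree,diameter,fe,zn `scalar_volume`s on one grid.
#' @param mask common logical array; defaults to the intersection of the four
#'   volumes' masks. At least 10 voxels are required.
#' @return a `correlation_table`: `r` (4x4 matrix), `n_voxels`,
#'   `degenerate` (named logical).
#' @export
correlation_table <- function(orientation_degree, diameter, fe, zn,
                              mask = NULL) {
  vols <- list(orientation = orientation_degree, diameter = diameter,
               fe = fe, zn = zn)
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(vols, `[[`, "mask"))
  }
  n <- sum(mask)
  if (n < 10) stop2("need at least 10 voxels under the common mask (got %d)", n)
  vals <- vapply(vols, function(v) v$values[mask], numeric(n))
  degenerate <- apply(vals, 2, function(x) sd(x) == 0)
  r <- matrix(NA_real_, 4, 4, dimnames = list(names(vols), names(vols)))
  okc <- which(!degenerate)
  r[okc, okc] <- cor(vals[, okc, drop = FALSE])
  d <- diag(r); d[!degenerate] <- 1; diag(r) <- d
  structure(list(r = r, n_voxels = n, degenerate = degenerate),
            class = "correlation_table")
}

#' @exportS3Method base::print
print.correlation_table <- function(x, ...) {
  cat(sprintf("Pairwise cross-correlation over %d voxels\n", x$n_voxels))
  print(round(x$r, 2))
  invisible(x)
}

#' Write a correlation table to CSV
#'
#' @param table a `correlation_table`.
#' @param path output file.
#' @export
write_correlation_csv <- function(table, path) {
  df <- data.frame(field = rownames(table$r), round(table$r, 6),
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}
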