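#' Scalar volume container
#'
#' A labelled 3D array on the phantom grid with a voxel size and an optional
#' validity mask.
#'
#' @param values 3D numeric array.
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param label short description, e.g. "Fe", "mean-scattering".
#' @param mask logical array of the same shape; defaults to all TRUE.
#' @return a `scalar_volume`.
#' @export
scalar_volume <- function(values, voxel_size_mm, label = "", mask = NULL) {
  stopifnot(length(dim(values)) == 3)
  if (any(!is.finite(values))) stop2("scalar volume values must be finite")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 label = label, mask = mask),
            class = "scalar_volume")
}

#' @exportS3Method base::print
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scalar_volume '%s'> %d x %d x %d, voxel %.4g mm, %d masked-in\n",
              x$label, d[1], d[2], d[3], x$voxel_size_mm, sum(x$mask)))
  invisible(x)
}

#' @exportS3Method base::print
print.phantom <- function(x, ...) {
  d <- dim(x$anisotropy)
  cat(sprintf("<phantom> %d x %d x %d voxels (%.4g mm), %d in support, seed %d\n",
              d[1], d[2], d[3], x$voxel_size_mm, sum(x$support), x$seed))
  invisible(x)
}
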