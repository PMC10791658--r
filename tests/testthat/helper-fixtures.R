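## Shared fixtures, built once per test run and cached (several tests reuse
## the same phantom/geometry; re-generating them per test would dominate the
## suite's runtime).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

## small 3D phantom + geometry used across forward/recon tests
small_phantom_config <- function(...) {
  phantom_config(grid = c(16L, 16L, 8L), voxel_size_mm = 0.075,
                 cylinder_diameter_mm = 1.14,
                 lesion_center_mm = c(0.1, 0.1, 0), lesion_radius_mm = 0.3,
                 ...)
}

small_geometry <- function(...) {
  scan_geometry(n_y = 16L, n_z = 8L, step_mm = 0.075, tilts_deg = 0,
                n_rot_tilt0 = 24L, ...)
}

## a hand-built phantom-like object (bypasses the generator) for tests that
## need exact field control
manual_phantom <- function(grid, vs, fill = function(ph) ph) {
  z <- array(0, dim = grid)
  ph <- structure(list(
    collagen_density = z, orientation = array(0, dim = c(grid, 3L)),
    anisotropy = z, fibril_diameter = z, fe = z, zn = z, mu = z,
    support = array(TRUE, dim = grid),
    voxel_size_mm = vs, config = NULL, seed = 0L), class = "phantom")
  fill(ph)
}

## default uniform scattering phantom: isotropic collagen everywhere in a
## cylinder, constant diameter
isotropic_phantom <- function(grid = c(16L, 16L, 8L), vs = 0.075,
                              density = 1, diameter = 50, mu = 0.1) {
  manual_phantom(grid, vs, function(ph) {
    co <- (seq_len(grid[1]) - (grid[1] + 1) / 2) * vs
    r2 <- outer(co^2, co^2, "+")
    inside <- r2 <= (grid[1] * vs * 0.45)^2
    for (k in seq_len(grid[3])) {
      ph$collagen_density[, , k][inside] <- density
      ph$fibril_diameter[, , k][inside] <- diameter
      ph$mu[, , k][inside] <- mu
      ph$support[, , k] <- inside
    }
    ph$orientation[, , , 3] <- 1
    ph
  })
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
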