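test_that("fbp centres points, matches the analytic disc and is linear", {
  ## single hot voxel: argmax at the true position
  ph <- manual_phantom(c(24L, 24L, 2L), 0.05, function(p) {
    p$mu[16, 9, ] <- 1
    p
  })
  geom <- scan_geometry(n_y = 24L, n_z = 2L, step_mm = 0.05, tilts_deg = 0,
                        n_rot_tilt0 = 60L)
  tr <- simulate_transmission(ph, geom)
  rec <- reconstruct_mu(tr)
  am <- which(rec$values[, , 1] == max(rec$values[, , 1]), arr.ind = TRUE)
  expect_equal(as.integer(am), c(16L, 9L))

  ## analytic uniform disc: interior relative RMSE <= 0.10
  n <- 64
  offs <- (1:n - (n + 1) / 2)
  R <- 20
  angles <- seq(0, 180, length.out = 61)[1:60]
  sino <- sapply(angles, function(a) ifelse(abs(offs) < R,
                                            2 * sqrt(pmax(0, R^2 - offs^2)), 0))
  rec2 <- fbp(sino, angles, filter = "hamming", spacing_mm = 1)
  xs <- matrix(offs, n, n); ys <- matrix(offs, n, n, byrow = TRUE)
  inside <- sqrt(xs^2 + ys^2) <= R - 2
  expect_lt(sqrt(mean((rec2[inside] - 1)^2)), 0.10)

  ## linearity
  expect_equal(fbp(3.7 * sino, angles), 3.7 * fbp(sino, angles),
               tolerance = 1e-9)
  expect_error(fbp(sino, angles[-1]), "angles")
  expect_error(fbp(sino[, 1, drop = FALSE], angles[1]), "at least 2")
})

test_that("fbp agrees with an independently coded oracle on 16x16 data", {
  set.seed(5)
  ## avoid an exact 90 degree projection: cos(pi/2) is 6e-17 rather than 0,
  ## which puts the outermost ray exactly on the domain-boundary knife edge
  ## where the two independent interpolation codes may round differently
  angles <- seq(0.5, 179.5, length.out = 20)
  for (filt in c("ramp", "hamming")) {
    sino <- matrix(runif(16 * 20), 16, 20)
    expect_lt(max(abs(fbp(sino, angles, filter = filt) -
                        oracle_fbp(sino, angles, filter = filt))), 1e-6)
  }
})

test_that("attenuation reconstruction is quantitative and linear", {
  vs <- 0.05
  n <- 24L
  ph <- manual_phantom(c(n, n, 2L), vs, function(p) {
    co <- (seq_len(n) - (n + 1) / 2) * vs
    r2 <- outer(co^2, co^2, "+")
    for (k in 1:2) p$mu[, , k][r2 <= 0.45^2] <- 0.2
    p
  })
  geom <- scan_geometry(n_y = n, n_z = 2L, step_mm = vs, tilts_deg = 0,
                        n_rot_tilt0 = 40L)
  tr <- simulate_transmission(ph, geom)
  rec <- reconstruct_mu(tr)
  co <- (seq_len(n) - (n + 1) / 2) * vs
  interior <- outer(co^2, co^2, "+") <= 0.35^2
  expect_lt(sqrt(mean((rec$values[, , 1][interior] - 0.2)^2)) / 0.2, 0.10)

  ## empty phantom reconstructs to zero
  tr0 <- simulate_transmission(manual_phantom(c(n, n, 2L), vs), geom)
  expect_lt(max(abs(reconstruct_mu(tr0)$values)), 1e-9)

  ## doubling mu doubles the reconstruction
  ph2 <- ph; ph2$mu <- 2 * ph$mu
  rec2 <- reconstruct_mu(simulate_transmission(ph2, geom))
  expect_equal(rec2$values, 2 * rec$values, tolerance = 1e-6)

  tr_bad <- tr; tr_bad$transmission[1] <- 0
  expect_error(reconstruct_mu(tr_bad), "\\(0, 1\\]")
})

test_that("tensor tomography recovers isotropy, alignment and descends", {
  ## isotropic phantom, noiseless: reconstructed anisotropy ~ 0 wherever
  ## there is collagen signal (support-edge voxels with next-to-no density
  ## are partial-volume artefacts and are masked in the analysis anyway)
  grid <- c(12L, 12L, 4L)
  iso <- manual_phantom(grid, 0.075, function(p) {
    co <- (seq_len(12) - 6.5) * 0.075
    r2 <- outer(co^2, co^2, "+")
    for (k in 1:4) {
      p$collagen_density[, , k] <- exp(-r2 / 0.06) * (r2 <= 0.4^2)
      p$support[, , k] <- r2 <= 0.4^2
    }
    p$fibril_diameter[] <- 50
    p$orientation[, , , 3] <- 1
    p
  })
  geom <- scan_geometry(n_y = 12L, n_z = 4L, step_mm = 0.075,
                        tilts_deg = c(0, 27, 45), n_rot_tilt0 = 16L,
                        n_rot_tilted = 16L,
                        q_edges = seq(0.44, 0.52, length.out = 3))
  sx <- simulate_saxs_scan(iso, geom, noise = "none", background = 0)
  tf <- reconstruct_tensor(sx, n_iter = 250L)
  po <- principal_orientation(tf, n_dirs = 2000L)
  signal <- iso$support & iso$collagen_density >= 0.1
  expect_true(all(po$anisotropy$values[signal] <= 0.05))
  ## objective log is non-increasing
  expect_true(all(diff(tf$objective) <= 1e-9 * tf$objective[1]))

  ## aligned phantom: principal axes recovered
  ph <- fixture("ph_aligned", {
    generate_phantom(phantom_config(grid = c(12L, 12L, 12L),
                                    voxel_size_mm = 0.075,
                                    cylinder_diameter_mm = 0.85,
                                    lesion_center_mm = c(0.05, 0.05, 0.1),
                                    lesion_radius_mm = 0.25,
                                    target_anisotropy = 0.9), seed = 6)
  })
  geom3 <- scan_geometry(n_y = 12L, n_z = 12L, step_mm = 0.075,
                         tilts_deg = c(0, 27, 45), n_rot_tilt0 = 16L,
                         n_rot_tilted = 16L,
                         q_edges = seq(0.44, 0.52, length.out = 3))
  sx3 <- simulate_saxs_scan(ph, geom3, noise = "none", background = 0)
  tf3 <- reconstruct_tensor(sx3, n_iter = 120L)
  po3 <- principal_orientation(tf3, n_dirs = 2000L)
  sel <- ph$anisotropy >= 0.5 & ph$support
  ev <- matrix(po3$orientation, 12^3, 3)
  tv <- matrix(ph$orientation, 12^3, 3)
  ang <- acos(pmin(1, abs(rowSums(ev[sel, ] * tv[sel, ])))) * 180 / pi
  expect_lt(mean(ang), 10)
  expect_true(all(diff(tf3$objective) <= 1e-9 * tf3$objective[1]))

  ## single tilt: flagged but still runs
  geom1 <- scan_geometry(n_y = 12L, n_z = 4L, step_mm = 0.075, tilts_deg = 0,
                         n_rot_tilt0 = 8L,
                         q_edges = seq(0.44, 0.52, length.out = 3))
  sx1 <- simulate_saxs_scan(iso, geom1, noise = "none", background = 0)
  expect_warning(tf1 <- reconstruct_tensor(sx1, n_iter = 5L), "single-tilt")
  expect_true(tf1$single_tilt)
})

test_that("principal orientation and anisotropy extraction are canonical", {
  mk_field <- function(A) structure(list(
    components = matrix(c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3]),
                        1, 6),
    grid = c(1L, 1L, 1L), voxel_size_mm = 1, objective = 0,
    single_tilt = FALSE, q_bin = 1L), class = "rank2_tensor_field")
  po <- principal_orientation(mk_field(diag(c(0, 0, 1))), n_dirs = 2000L)
  expect_equal(as.numeric(po$orientation[1, 1, 1, ]), c(0, 0, 1))
  po2 <- principal_orientation(mk_field(diag(c(1, 0, 0))), n_dirs = 10000L)
  expect_equal(po2$anisotropy$values[1], 2 / sqrt(5), tolerance = 1e-3)
  ## scaling invariance of the eigenvector
  set.seed(8)
  B <- matrix(rnorm(9), 3); A <- B %*% t(B)
  e1 <- principal_orientation(mk_field(A), n_dirs = 500L)$orientation[1, 1, 1, ]
  e2 <- principal_orientation(mk_field(5 * A), n_dirs = 500L)$orientation[1, 1, 1, ]
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-12)
  ## zero tensor: masked out
  po0 <- principal_orientation(mk_field(matrix(0, 3, 3)), n_dirs = 500L)
  expect_false(po0$anisotropy$mask[1, 1, 1])
})

test_that("mean-scattering volume tracks collagen density", {
  ## isotropic orientation but spatially varying density
  iso <- manual_phantom(c(16L, 16L, 8L), 0.075, function(p) {
    co <- (seq_len(16) - 8.5) * 0.075
    r2 <- outer(co^2, co^2, "+")
    inside <- r2 <= 0.55^2
    dens <- (0.2 + exp(-r2 / 0.1)) * inside
    for (k in 1:8) {
      p$collagen_density[, , k] <- dens * (0.7 + 0.3 * k / 8)
      p$support[, , k] <- inside
    }
    p$fibril_diameter[] <- 50
    p$orientation[, , , 3] <- 1
    p
  })
  geom <- small_geometry(q_edges = seq(0.44, 0.52, length.out = 3))
  sx <- simulate_saxs_scan(iso, geom, noise = "none", background = 0)
  ms <- mean_scattering_volume(sx)
  s <- iso$support
  expect_gt(cor(ms$values[s], iso$collagen_density[s]), 0.95)

  ## zero collagen: nothing reconstructed
  none <- manual_phantom(c(16L, 16L, 8L), 0.075,
                         function(p) { p$fibril_diameter[] <- 50; p })
  sx0 <- simulate_saxs_scan(none, geom, noise = "none", background = 0)
  expect_lt(max(abs(mean_scattering_volume(sx0)$values)), 1e-9)

  ## averaging is grouping-independent: mean over segment pairs equals the
  ## grand mean fed to the same FBP
  d <- mmtomo:::corrected_saxs_data(sx, sx$q5_bin)
  g1 <- apply(d, c(1, 2), mean)
  g2 <- (apply(d[, , 1:8], c(1, 2), mean) + apply(d[, , 9:16], c(1, 2), mean)) / 2
  expect_equal(g1, g2, tolerance = 1e-9)
})
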