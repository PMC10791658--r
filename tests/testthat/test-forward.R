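test_that("acquisition counts follow the scan schedule", {
  paper_geom <- scan_geometry(n_y = 48L, n_z = 60L, n_rot_tilt0 = 51L)
  expect_equal(count_acquired(paper_geom, "xrf"), 146880)
  tiny <- scan_geometry(n_y = 1L, n_z = 1L, tilts_deg = 0, n_rot_tilt0 = 1L)
  expect_equal(count_acquired(tiny, "saxs"), 1)
  g1 <- scan_geometry(n_y = 8L, n_z = 5L)
  g2 <- scan_geometry(n_y = 16L, n_z = 5L)
  expect_equal(count_acquired(g2, "saxs"), 2 * count_acquired(g1, "saxs"))
  expect_equal(count_acquired(g2, "xrf"), 2 * count_acquired(g1, "xrf"))
  expect_error(scan_geometry(tilts_deg = c(9, 18)), "include 0")
})

test_that("transmission follows Beer-Lambert and the sample symmetry", {
  ## empty phantom: T = 1 everywhere
  empty <- manual_phantom(c(8L, 8L, 4L), 0.1)
  geom <- scan_geometry(n_y = 8L, n_z = 4L, step_mm = 0.1, tilts_deg = 0,
                        n_rot_tilt0 = 3L)
  tr <- simulate_transmission(empty, geom)
  expect_true(all(tr$transmission == 1))

  ## uniform-mu cylinder, central ray: T = exp(-mu * diameter), fine grid so
  ## the voxelised chord converges to the analytic one
  vs <- 0.02
  n <- 60L
  ph <- manual_phantom(c(n, n, 4L), vs, function(p) {
    co <- (seq_len(n) - (n + 1) / 2) * vs
    r2 <- outer(co^2, co^2, "+")
    inside <- r2 <= 0.6^2
    for (k in 1:4) p$mu[, , k][inside] <- 0.1
    p
  })
  geom_c <- scan_geometry(n_y = 61L, n_z = 1L, step_mm = vs, tilts_deg = 0,
                          n_rot_tilt0 = 2L)
  trc <- simulate_transmission(ph, geom_c)
  central <- 31L  # zero offset ray
  expect_equal(trc$transmission[1, central], exp(-0.1 * 1.2), tolerance = 1e-3)

  ## cylindrically symmetric attenuation: the sinogram is rotation-invariant
  ## up to voxelisation error, which must shrink under grid refinement (a
  ## voxelised field sampled by trilinear interpolation is only rotation
  ## invariant in the continuum limit)
  sym_dev <- function(n, vs) {
    ph_sym <- manual_phantom(c(n, n, 2L), vs, function(p) {
      co <- (seq_len(n) - (n + 1) / 2) * vs
      r2 <- outer(co^2, co^2, "+")
      ## compact Gaussian: tails vanish before the square grid boundary, so
      ## the only rotation-variance left is trilinear discretisation
      for (k in 1:2) p$mu[, , k] <- 0.3 * exp(-r2 / 0.02)
      p
    })
    geom_s <- scan_geometry(n_y = n, n_z = 2L, step_mm = vs, tilts_deg = 0,
                            n_rot_tilt0 = 6L)
    trs <- simulate_transmission(ph_sym, geom_s)
    max(abs(sweep(trs$transmission, 2, trs$transmission[1, ])))
  }
  d24 <- sym_dev(24L, 0.05)
  d48 <- sym_dev(48L, 0.025)
  expect_lt(d24, 2e-3)
  expect_lt(d48, d24 / 2)   # ~quadratic convergence to exact symmetry
})

test_that("SAXS simulation obeys the tensor signal model", {
  grid <- c(12L, 12L, 4L)
  geom <- scan_geometry(n_y = 12L, n_z = 4L, step_mm = 0.075, tilts_deg = 0,
                        n_rot_tilt0 = 4L,
                        q_edges = seq(0.4, 0.56, length.out = 5))
  ## zero collagen: expectation is background only
  empty <- manual_phantom(grid, 0.075, function(p) {
    p$fibril_diameter[] <- 50; p
  })
  sx0 <- simulate_saxs_scan(empty, geom, noise = "none", background = 1.7)
  expect_true(all(sx0$intensity == 1.7))

  ## isotropic phantom, noiseless: all segments identical
  iso <- manual_phantom(grid, 0.075, function(p) {
    p$collagen_density[5:8, 5:8, ] <- 1
    p$fibril_diameter[] <- 50
    p$orientation[, , , 3] <- 1
    p
  })
  sxi <- simulate_saxs_scan(iso, geom, noise = "none", background = 0)
  for (s in 2:geom$n_segments)
    expect_equal(sxi$intensity[, , s, ], sxi$intensity[, , 1, ],
                 tolerance = 1e-9)

  ## doubling the exposure doubles the expected signal over background
  geom2 <- geom; geom2$exposure_s <- 2 * geom$exposure_s
  sx2 <- simulate_saxs_scan(iso, geom2, noise = "none", background = 0.5)
  sx1 <- simulate_saxs_scan(iso, geom, noise = "none", background = 0.5)
  expect_equal(sx2$intensity - 0.5, 2 * (sx1$intensity - 0.5),
               tolerance = 1e-9)

  ## Poisson noise: mean of repeated draws matches the expectation
  lam <- sx1$intensity
  big <- which(lam > 50)[1:20]
  acc <- 0
  for (sd_ in 1:50)
    acc <- acc + simulate_saxs_scan(iso, geom, seed = sd_,
                                    background = 0.5)$intensity[big]
  z <- (acc / 50 - lam[big]) / sqrt(lam[big] / 50)
  expect_true(all(abs(z) < 5))

  ## determinism
  a <- simulate_saxs_scan(iso, geom, seed = 7)
  b <- simulate_saxs_scan(iso, geom, seed = 7)
  expect_identical(a$intensity, b$intensity)
})

test_that("tilt-0 SAXS at 180 deg + omega mirrors the segments and rays", {
  ph <- fixture("ph_small", generate_phantom(small_phantom_config(), seed = 4))
  geom <- scan_geometry(n_y = 16L, n_z = 8L, step_mm = 0.075, tilts_deg = 0,
                        rot0_deg = c(30, 210), n_segments = 16L,
                        q_edges = seq(0.44, 0.52, length.out = 3))
  sx <- simulate_saxs_scan(ph, geom, noise = "none", background = 0)
  n_seg <- 16L
  seg_map <- ((8L - seq_len(n_seg)) %% n_seg) + 1L   # phi -> pi - phi
  ray_map <- as.vector(outer(16:1, 0:7 * 16L, "+"))  # y reversed per z row
  for (s in seq_len(n_seg)) {
    expect_equal(sx$intensity[2, , s, ],
                 sx$intensity[1, ray_map, seg_map[s], ],
                 tolerance = 1e-6)
  }
  ## transmission shares the ray symmetry
  expect_equal(sx$transmission[2, ], sx$transmission[1, ray_map],
               tolerance = 1e-9)
})

test_that("XRF spectra reflect concentrations, lines and absorption", {
  grid <- c(12L, 12L, 2L)
  vs <- 0.075
  ph <- manual_phantom(grid, vs, function(p) {
    p$zn[4:9, 4:9, ] <- 0.8
    p$mu[3:10, 3:10, ] <- 0.25
    p
  })  # note: no Fe anywhere
  geom <- scan_geometry(n_y = 12L, n_z = 2L, step_mm = vs, tilts_deg = 0,
                        n_rot_tilt0 = 4L)
  sc <- simulate_xrf_scan(ph, geom, absorption = FALSE, noise = "none",
                          background = 0.31)
  ## no Fe: the 6.40 keV window holds background only (Zn lines are far)
  e <- sc$energy_kev
  fe_win <- e > 6.3 & e < 6.5
  expect_true(all(abs(sc$spectra[, , fe_win] - 0.31) < 1e-9))

  ## absorption off, noiseless: Zn K-alpha areas = Radon transform of zn
  proj <- build_projectors(grid, vs, geom)
  radon <- t(sapply(proj, function(p) as.numeric(p$P %*% as.vector(ph$zn))))
  big <- radon > 0.01 * max(radon)
  expect_lt(max(abs(sc$true_areas[, , "Zn"][big] - radon[big]) / radon[big]),
            1e-6)
  ## ... and the fitted areas agree too (fit as used by element_maps)
  cal <- calibrate_energy(colSums(matrix(sc$spectra, 4 * 24, length(e))) + 1e-9,
                          c(8.639, 9.572))
  hot_ray <- which.max(radon[1, ])
  pf <- fit_spectrum(sc$spectra[1, hot_ray, ], cal)
  expected <- radon[1, hot_ray] * geom$flux * geom$exposure_s * geom$xrf_sens
  expect_equal(pf$areas$ka_area[pf$areas$element == "Zn"], expected,
               tolerance = 1e-3)

  ## absorption strictly reduces every line area where there is signal
  sc_abs <- simulate_xrf_scan(ph, geom, absorption = TRUE, noise = "none")
  expect_true(all(sc_abs$true_areas[, , "Zn"][big] < sc$true_areas[, , "Zn"][big]))

  ## Poisson: mean of 100 noisy realisations within sampling error
  lam <- sc$spectra[1, hot_ray, ]
  hot <- which(lam > 20)
  acc <- 0
  for (sd_ in 1:100)
    acc <- acc + simulate_xrf_scan(ph, geom, absorption = FALSE, seed = sd_,
                                   background = 0.31)$spectra[1, hot_ray, hot]
  z <- (acc / 100 - lam[hot]) / sqrt(lam[hot] / 100)
  expect_true(all(abs(z) < 5))
})
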