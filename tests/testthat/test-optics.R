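test_that("absorption coefficient follows the chromophore mixing law", {
  grid <- sim_grid()
  # vhb = 0 -> the blood term vanishes: only water absorption remains, and
  # that water part is proportional to w_water (so both absorbers at zero
  # would give zero absorption everywhere)
  mua0 <- absorption_coefficient(tissue_params(vhb = 0, w_water = 0.8),
                                 grid, fix_tab)
  mua_water_only <- outer(0.8, interp_table(fix_tab, "mua_water",
                                            grid$wavelengths_nm))
  expect_equal(mua0, mua_water_only, tolerance = 1e-12)
  mua0b <- absorption_coefficient(tissue_params(vhb = 0, w_water = 0.9),
                                  grid, fix_tab)
  expect_equal(mua0b, mua_water_only * 0.9 / 0.8, tolerance = 1e-12)

  # linearity: doubling vhb doubles the blood contribution exactly
  pa <- tissue_params(sto2 = 0.6, vhb = 0.05, w_water = 0.8)
  pb <- tissue_params(sto2 = 0.6, vhb = 0.10, w_water = 0.8)
  blood_a <- absorption_coefficient(pa, grid, fix_tab) - mua_water_only
  blood_b <- absorption_coefficient(pb, grid, fix_tab) - mua_water_only
  expect_equal(blood_b, 2 * blood_a, tolerance = 1e-12)

  # out-of-coverage wavelength names the wavelength
  expect_error(absorption_coefficient(pa, c(500, 1200), fix_tab), "1200")
})

test_that("absorption is StO2-independent at isosbestic wavelengths", {
  iso <- find_isosbestic(fix_tab, c(500, 995))
  expect_gt(length(iso), 0)
  p_deoxy <- tissue_params(sto2 = 0, vhb = 0.1)
  p_oxy <- tissue_params(sto2 = 1, vhb = 0.1)
  mua0 <- absorption_coefficient(p_deoxy, iso, fix_tab)
  mua1 <- absorption_coefficient(p_oxy, iso, fix_tab)
  expect_equal(as.vector(mua0), as.vector(mua1), tolerance = 1e-9)
})

test_that("reduced scattering follows the 500 nm-anchored power law", {
  p <- tissue_params(mus500 = 10, b_mie = 1)
  expect_equal(as.vector(reduced_scattering(p, 500)), 10)
  expect_equal(as.vector(reduced_scattering(p, 1000)), 5)
  # minimum scattering power still decreases strictly over the camera range
  pmin <- tissue_params(mus500 = 20, b_mie = 0.3)
  musp <- as.vector(reduced_scattering(pmin, camera_grid()))
  expect_true(all(diff(musp) < 0))
})

test_that("diffuse reflectance is bounded, opaque-limited and monotone in blood", {
  # bounds over a large random draw of valid parameters
  p <- sample_params(10000, seed = 21)
  R <- diffuse_reflectance(p, sim_grid(), fix_tab)$values
  expect_true(all(R >= 0 & R <= 1))

  # opaque limit via the absorption override hook
  p1 <- tissue_params()
  mua <- absorption_coefficient(p1, sim_grid(), fix_tab)
  R_opaque <- diffuse_reflectance(p1, sim_grid(), fix_tab,
                                  mua_override = mua * 1e6)$values
  expect_true(all(R_opaque < 1e-3))

  # more blood -> lower reflectance wherever blood absorbs
  lo <- tissue_params(vhb = 0.01); hi <- tissue_params(vhb = 0.30)
  grid_cam <- camera_grid()
  R_lo <- diffuse_reflectance(lo, grid_cam, fix_tab)$values
  R_hi <- diffuse_reflectance(hi, grid_cam, fix_tab)$values
  eps <- interp_table(fix_tab, "eps_hbo2", grid_cam$wavelengths_nm)
  expect_true(all(R_hi[eps > 0] < R_lo[eps > 0]))
})

test_that("reflectance at extreme StO2 agrees only at isosbestic wavelengths", {
  grid_cam <- camera_grid()
  p0 <- tissue_params(sto2 = 0, vhb = 0.1)
  p1 <- tissue_params(sto2 = 1, vhb = 0.1)
  R0 <- as.vector(diffuse_reflectance(p0, grid_cam, fix_tab)$values)
  R1 <- as.vector(diffuse_reflectance(p1, grid_cam, fix_tab)$values)
  expect_gt(max(abs(R0 - R1)), 0.01)  # strong Hb/HbO2 contrast exists
  iso <- find_isosbestic(fix_tab, c(500, 995))
  R0i <- diffuse_reflectance(p0, structure(list(wavelengths_nm = iso,
                                                spacing_nm = NA),
                                           class = "wavelength_grid"), fix_tab)
  R1i <- diffuse_reflectance(p1, structure(list(wavelengths_nm = iso,
                                                spacing_nm = NA),
                                           class = "wavelength_grid"), fix_tab)
  expect_equal(as.vector(R0i$values), as.vector(R1i$values), tolerance = 1e-9)
})

test_that("tissue parameter ranges are enforced at construction", {
  expect_error(tissue_params(sto2 = 1.2), "sto2")
  expect_error(tissue_params(vhb = 0.5), "vhb")
  expect_error(tissue_params(mus500 = 2), "mus500")
  expect_silent(tissue_params(sto2 = 0, vhb = 0.3))
})

test_that("camera resampling preserves constants, lines and linearity", {
  grid <- sim_grid()
  L <- length(grid$wavelengths_nm)
  # constant spectrum
  const <- matrix(0.42, 1, L)
  out <- resample_to_camera(const, fix_cam, grid = grid)
  expect_equal(as.vector(out$values), rep(0.42, 100))
  # output grid is 500, 505, ..., 995
  expect_equal(out$grid$wavelengths_nm, seq(500, 995, 5))
  # linear-in-wavelength spectrum with symmetric boxcar -> line at centers
  lin <- matrix(0.001 * grid$wavelengths_nm, 1, L)
  out_lin <- resample_to_camera(lin, fix_cam, grid = grid)
  expect_equal(as.vector(out_lin$values), 0.001 * seq(500, 995, 5),
               tolerance = 1e-12)
  # linearity of the twin
  s1 <- matrix(runif(L), 1); s2 <- matrix(runif(L), 1)
  lhs <- resample_to_camera(2 * s1 + 3 * s2, fix_cam, grid = grid)$values
  rhs <- 2 * resample_to_camera(s1, fix_cam, grid = grid)$values +
    3 * resample_to_camera(s2, fix_cam, grid = grid)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # coverage gap errors name the band
  short_grid <- wavelength_grid(600, 1000, 2)
  expect_error(resample_to_camera(matrix(1, 1, 201), fix_cam, grid = short_grid),
               "500")
})

test_that("L1 normalization scales to unit sum, is idempotent, rejects zero", {
  expect_equal(l1_normalize(c(2, 2)), c(0.5, 0.5))
  v <- runif(100)
  n1 <- l1_normalize(v)
  expect_equal(sum(abs(n1)), 1, tolerance = 1e-9)
  expect_equal(l1_normalize(n1), n1, tolerance = 1e-12)
  expect_error(l1_normalize(rep(0, 10)), "zero")
  M <- matrix(runif(50), 5)
  expect_equal(rowSums(l1_normalize(M)), rep(1, 5), tolerance = 1e-9)
})
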