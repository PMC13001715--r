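sett <- spectrometer_settings()  # 9.5 GHz, 3100 G centre, 1600 G sweep

test_that("hyperfine-free resonance reduces to the closed-form free-spin field", {
  iso <- spin_system(2.0023, 2.0023, 0, 0, gauss_fwhm = 10)
  cst <- epr_constants()
  b_exact <- 1e4 * cst$h * 9.5e9 / (2.0023 * cst$mu_B)
  for (th in c(0, 0.4, pi / 2)) {
    rf <- resonance_fields(iso, sett, th)
    expect_equal(rf$field, rep(b_exact, 4), tolerance = 1e-9)
  }
})

test_that("parallel-orientation line centre and hyperfine spacing match closed form", {
  cu <- spin_system(2.198, 2.05, 607, 60)
  rf <- resonance_fields(cu, sett, 0)
  cst <- epr_constants()
  b0 <- 1e4 * cst$h * 9.5e9 / (2.198 * cst$mu_B)
  a <- 1e4 * 607e6 * cst$h / (2.198 * cst$mu_B)
  expect_equal(b0, 3088.1, tolerance = 0.05)
  expect_equal(a, 197.3, tolerance = 0.05)
  # first-order positions bracket the second-order-shifted lines
  first_order <- b0 - rf$m_I * a
  expect_equal(sort(round(first_order)), c(2792, 2989, 3187, 3384),
               tolerance = 1)
  expect_true(all(rf$field < first_order))  # shifts lower every field
})

test_that("second-order fields agree with the 8x8 diagonalization oracle to 0.5 G", {
  # isotropic-coupling regime where the effective-Hamiltonian form the
  # perturbation expansion assumes is exact
  cu <- spin_system(2.198, 2.05, 607, 607)
  rf <- resonance_fields(cu, sett, 0)
  orc <- oracle_resonance_fields(2.198, 607, 9.5)
  expect_equal(sort(rf$field), sort(orc$field), tolerance = 0.5)
  # shift magnitude ordering: I(I+1) - m^2 is 1.5 for |m|=3/2, 3.75 for 1/2
  b0 <- 1e4 * epr_constants()$h * 9.5e9 / (2.198 * epr_constants()$mu_B)
  a <- 1e4 * 607e6 * epr_constants()$h / (2.198 * epr_constants()$mu_B)
  shifts <- (b0 - rf$m_I * a) - rf$field
  expect_true(all(shifts[abs(rf$m_I) == 0.5] >
                    shifts[abs(rf$m_I) == 1.5]))
})

test_that("an isotropic A = 0 powder line is a symmetric derivative with zero integral", {
  iso <- spin_system(2.0023, 2.0023, 0, 0, gauss_fwhm = 15)
  sp <- powder_spectrum(iso, sett)
  expect_equal(pracma::trapz(sp$field, sp$intensity), 0, tolerance = 1e-10)
  # derivative antisymmetric about the line: max and min equidistant
  cst <- epr_constants()
  b <- 1e4 * cst$h * 9.5e9 / (2.0023 * cst$mu_B)
  up <- sp$field[which.max(sp$intensity)]
  dn <- sp$field[which.min(sp$intensity)]
  expect_equal((up + dn) / 2, b, tolerance = 1.5)
})

test_that("powder spectrum converges with orientation count (<0.5% RMS, 256 vs 512)", {
  cu <- spin_system(2.198, 2.05, 607, 60, gauss_fwhm = 25)
  s1 <- powder_spectrum(cu, sett, 256)
  s2 <- powder_spectrum(cu, sett, 512)
  rel <- sqrt(mean((s1$intensity - s2$intensity)^2)) /
    sqrt(mean(s2$intensity^2))
  expect_lt(rel, 0.005)
})

test_that("the highest-field parallel extremum sits at the theta = 0 resonance", {
  cu <- spin_system(2.198, 2.05, 607, 60, gauss_fwhm = 20)
  sp <- powder_spectrum(cu, sett, 512)
  rf0 <- resonance_fields(cu, sett, 0)
  grid_step <- sp$field[2] - sp$field[1]
  # lowest-field feature: the m_I = +3/2 parallel line
  low_line <- min(rf0$field)
  sel <- abs(sp$field - low_line) < 60
  peak <- sp$field[sel][which.max(abs(sp$intensity[sel]))]
  expect_lt(abs(peak - low_line), 25)
  # absorption maximum near the perpendicular singularity, far above
  expect_gt(sp$field[which.max(sp$intensity)], low_line + 200)
  expect_true(grid_step > 0)
})

test_that("superposition is the identity for one spectrum and linear in weights", {
  iso <- spin_system(2.05, 2.05, 100, 50, gauss_fwhm = 20)
  cu <- spin_system(2.198, 2.05, 607, 60, gauss_fwhm = 25)
  s1 <- powder_spectrum(iso, sett)
  s2 <- powder_spectrum(cu, sett)
  expect_equal(superpose(list(s1), 1)$intensity, s1$intensity)
  half <- superpose(list(s1, s1), c(0.5, 0.5))
  expect_equal(half$intensity, s1$intensity, tolerance = 1e-12)
  mix <- superpose(list(s1, s2), c(0.3, 0.7))
  expect_equal(double_integral(mix),
               0.3 * double_integral(s1) + 0.7 * double_integral(s2),
               tolerance = 1e-9)
  bad <- s2; bad$field <- bad$field + 1
  expect_error(superpose(list(s1, bad), c(1, 1)), "common field grid")
})

test_that("double integration: zero trace, analytic area, scaling, field shift", {
  f <- seq(2000, 4000, length.out = 4001)
  zero <- structure(list(field = f, intensity = rep(0, 4001),
                         provenance = list()), class = "cw_spectrum")
  expect_equal(double_integral(zero), 0)
  # derivative of a unit-area Gaussian absorption integrates back to 1
  g <- dnorm(f, 3000, 50)
  sp <- structure(list(field = f,
                       intensity = pracma::gradient(g, f[2] - f[1]),
                       provenance = list()), class = "cw_spectrum")
  expect_equal(double_integral(sp), 1, tolerance = 1e-3)
  sp3 <- sp; sp3$intensity <- 3 * sp$intensity
  expect_equal(double_integral(sp3), 3 * double_integral(sp),
               tolerance = 1e-9)
  # invariance under field-axis shift
  sps <- sp; sps$field <- sp$field + 500
  expect_equal(double_integral(sps), double_integral(sp),
               tolerance = 1e-9)
})

test_that("titration linearity: construction, noise robustness, degenerate cases", {
  tit <- make_cw_titration(equivalents = seq(0.5, 5, by = 0.5))
  res <- titration_linearity(tit$equivalents, tit$spectra)
  expect_gt(res$r_squared, 0.999)
  expect_gt(res$slope, 0)
  # 1% noise at 8 points keeps R^2 > 0.99
  tn <- make_cw_titration(equivalents = seq(0.5, 4, by = 0.5),
                          noise_sigma = 0.01, seed = 11)
  rn <- titration_linearity(tn$equivalents, tn$spectra)
  expect_gt(rn$r_squared, 0.99)
  # constant spectra: slope ~ 0
  const <- rep(tit$spectra[1], 5)
  rc <- suppressWarnings(titration_linearity(seq(1, 5), const))
  expect_lt(abs(rc$slope), 1e-9 * abs(res$slope))
  expect_error(titration_linearity(1:2, tit$spectra[1:2]), "at least 3")
})
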