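rg_sim <- seq(1, 10, by = 0.02)
rg_inv <- seq(1.5, 8, by = 0.05)
tgrid <- seq(0, 2.2, length.out = 140)

test_that("kernel: unit first row, bounded entries, 1/r^3 frequency scale", {
  K <- dipolar_kernel(tgrid, seq(2, 6, by = 0.5))
  expect_equal(unname(K[1, ]), rep(1, ncol(K)))
  expect_true(all(K <= 1 + 1e-12 & K >= -0.5 - 1e-12))
  expect_equal(52.04 / 3.5^3, 1.2138, tolerance = 1e-4)
  expect_error(dipolar_kernel(tgrid, c(3, -1)), "positive")
})

test_that("Gauss-Legendre kernel matches a Riemann-sum oracle", {
  t <- seq(0, 2, length.out = 24)
  r <- seq(1.8, 7, length.out = 16)
  K <- dipolar_kernel(t, r)
  xs <- (seq_len(20000) - 0.5) / 20000
  ang <- 1 - 3 * xs^2
  for (j in seq_along(r)) {
    ko <- rowMeans(cos(2 * pi * (52.04 / r[j]^3) * outer(t, ang)))
    expect_lt(max(abs(K[, j] - ko)), 1e-6)
  }
})

test_that("a narrow 3.5 nm distribution puts the first trace minimum at the kernel minimum", {
  P <- distance_distribution(rg_sim, dnorm(rg_sim, 3.5, 0.01))
  tr <- simulate_ridme(P, background_model(0, 1.5, 1), t_us = tgrid)
  kcol <- dipolar_kernel(tgrid, 3.5)
  i_tr <- which(diff(sign(diff(tr$signal))) == 2)[1] + 1
  i_k <- which(diff(sign(diff(as.numeric(kcol)))) == 2)[1] + 1
  expect_equal(tgrid[i_tr], tgrid[i_k], tolerance = 0.05)
  # near the known ~0.58 / nu_dd powder first-minimum position
  nu <- 52.04 / 3.5^3
  expect_equal(tgrid[i_tr] * nu, 0.58, tolerance = 0.12)
})

test_that("lambda -> 0 leaves a pure background; seeds reproduce bit-identically", {
  P <- distance_distribution(rg_sim, dnorm(rg_sim, 3.5, 0.1))
  tr <- simulate_ridme(P, background_model(0.08, 1.6, 1e-6), t_us = tgrid)
  fit <- nls(y ~ exp(-k * t^d), data = data.frame(t = tgrid, y = tr$signal),
             start = list(k = 0.05, d = 1.5))
  expect_lt(sqrt(mean(resid(fit)^2)), 1e-6)
  a <- simulate_ridme(P, noise_sigma = 0.02, seed = 3, t_us = tgrid)
  b <- simulate_ridme(P, noise_sigma = 0.02, seed = 3, t_us = tgrid)
  expect_identical(a$signal, b$signal)
})

test_that("noiseless round trip recovers the mode and width of a 3.5 nm Gaussian", {
  P <- distance_distribution(rg_sim, dnorm(rg_sim, 3.5, 0.1))
  tr <- simulate_ridme(P, background_model(0.08, 1.6, 0.3), t_us = tgrid)
  fit <- suppressWarnings(invert_tikhonov(tr, rg_inv, max_outer = 60))
  expect_true(all(fit$P$density >= 0))
  expect_equal(pracma::trapz(fit$P$r, fit$P$density), 1, tolerance = 1e-9)
  mode <- fit$P$r[which.max(fit$P$density)]
  expect_lte(abs(mode - 3.5), 0.05)
  w_true <- 2 * sqrt(2 * log(2)) * 0.1
  w_fit <- fwhm_of(fit$P$r, fit$P$density)
  expect_gte(w_fit, w_true / 2)
  expect_lte(w_fit, w_true * 2)
})

test_that("curvature norm of the inverted distribution decreases with alpha", {
  P <- distance_distribution(rg_sim, dnorm(rg_sim, 3.5, 0.1))
  tr <- simulate_ridme(P, background_model(0.08, 1.6, 0.3), t_us = tgrid)
  L <- cuepr:::.second_diff_matrix(length(rg_inv))
  norms <- vapply(c(0.1, 1, 10), function(a) {
    f <- suppressWarnings(invert_tikhonov(tr, rg_inv, alpha = a))
    sqrt(sum((L %*% f$P$density)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("all-zero traces are rejected", {
  expect_error(ridme_trace(tgrid, rep(0, length(tgrid))), "non-zero")
  tr <- ridme_trace(tgrid, c(1, rep(0, length(tgrid) - 1)))
  tr$signal <- rep(0, length(tgrid))
  expect_error(invert_tikhonov(tr, rg_inv), "all-zero")
})

test_that("multi-field combination: identity, metadata, normalization commutes", {
  P <- distance_distribution(rg_sim, dnorm(rg_sim, 3.5, 0.1))
  tr <- simulate_ridme(P, background_model(0.08, 1.6, 0.3), t_us = tgrid,
                       field_offset_g = -100)
  expect_equal(combine_field_positions(list(tr, tr))$signal, tr$signal)
  offs <- c(-100, -600, -800)
  trs <- lapply(offs, function(o)
    simulate_ridme(P, background_model(0.08, 1.6, 0.3), t_us = tgrid,
                   field_offset_g = o))
  cmb <- combine_field_positions(trs)
  expect_equal(cmb$field_offset_g, offs)
  expect_equal(cmb$signal[1], 1)
  # commutes with normalization: scaling any input changes nothing
  trs2 <- trs
  trs2[[2]]$signal <- trs2[[2]]$signal  # already normalized by constructor
  expect_equal(combine_field_positions(trs2)$signal, cmb$signal)
  expect_error(combine_field_positions(list()), "empty")
})

test_that("traces with different modulation depths combine to the same mode", {
  P <- distance_distribution(rg_sim, dnorm(rg_sim, 3.5, 0.1))
  trA <- simulate_ridme(P, background_model(0.08, 1.6, 0.2), t_us = tgrid)
  trB <- simulate_ridme(P, background_model(0.08, 1.6, 0.4), t_us = tgrid)
  cmb <- combine_field_positions(list(trA, trB))
  fit <- suppressWarnings(invert_tikhonov(cmb, rg_inv))
  expect_lte(abs(fit$P$r[which.max(fit$P$density)] - 3.5), 0.1)
})
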