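# Distance table used throughout: the decoy's six sites, built once.
local_table <- local({
  decoy <- make_decoy_structure(decoy_spec(seed = 1))
  pairwise_distances(detect_metal_sites(decoy))
})

test_that("configuration enumeration counts and ordering", {
  labs <- rownames(local_table)
  expect_length(enumerate_configs(labs, 3, 3), choose(6, 3))  # 20
  expect_length(enumerate_configs(labs, 2, 6), 57)  # sum C(6,k), k=2..6
  expect_length(enumerate_configs(labs[1:2]), 1)
  expect_error(enumerate_configs(labs, min_size = 1), "min_size")
  expect_error(enumerate_configs(labs, max_size = 7), "max_size")
  # deterministic: two calls identical
  expect_identical(enumerate_configs(labs, 2, 4),
                   enumerate_configs(labs, 2, 4))
})

test_that("a single pair gives one unit-integral Gaussian at the tabled distance", {
  d <- simulate_distribution(c("ATCUN", "siteB"), local_table)
  expect_equal(pracma::trapz(d$r, d$density), 1, tolerance = 1e-9)
  expect_equal(d$r[which.max(d$density)], local_table["ATCUN", "siteB"],
               tolerance = 0.021)
  expect_error(simulate_distribution(c("ATCUN", "nope"), local_table),
               "nope")
})

test_that("three-site mixtures weight each pair 1/3 at the closed-form ordinate", {
  cfg <- c("ATCUN", "siteB", "H287")
  d <- simulate_distribution(cfg, local_table, sigma = 0.1)
  prs <- attr(d, "pairs")
  expect_equal(nrow(prs), 3)
  expect_equal(prs$weight, rep(1 / 3, 3))
  expect_equal(sum(prs$weight), 1)
  # density at the isolated 3.5 nm mean ~ (1/3) / (sigma sqrt(2 pi))
  ord <- (1 / 3) / (0.1 * sqrt(2 * pi))
  expect_equal(ord, 1.3298, tolerance = 1e-4)
  at35 <- d$density[which.min(abs(d$r - local_table["ATCUN", "H287"]))]
  expect_equal(at35, ord, tolerance = 0.02)
})

test_that("all 57 simulated distributions integrate to 1 within 1e-9", {
  cfgs <- enumerate_configs(rownames(local_table), 2, 6)
  ints <- vapply(cfgs, function(cf) {
    d <- simulate_distribution(cf, local_table)
    pracma::trapz(d$r, d$density)
  }, numeric(1))
  expect_true(all(abs(ints - 1) < 1e-9))
})

test_that("small sigma concentrates >= 99% of mass within 3 sigma of each mean", {
  cfg <- c("ATCUN", "H287", "H509")  # well-separated means
  sig <- 0.02
  # grid resolves the narrow Gaussians (step = sigma/4)
  d <- simulate_distribution(cfg, local_table, sigma = sig,
                             r_grid = seq(1, 10, by = 0.005))
  prs <- attr(d, "pairs")
  mass <- sum(vapply(prs$mean_nm, function(m) {
    sel <- abs(d$r - m) <= 3 * sig
    pracma::trapz(d$r[sel], d$density[sel])
  }, numeric(1)))
  expect_gte(mass, 0.99)
})

test_that("overlap score: identical = 1, disjoint < 1e-6, symmetric, bounded", {
  r <- seq(1, 10, by = 0.02)
  a <- distance_distribution(r, dnorm(r, 2.0, 0.1))
  b <- distance_distribution(r, dnorm(r, 6.0, 0.1))
  expect_equal(score_config(a, a)$score, 1, tolerance = 1e-9)
  expect_lt(score_config(a, b)$score, 1e-6)
  s_ab <- score_config(a, b)$score
  s_ba <- score_config(b, a)$score
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  m <- distance_distribution(r, dnorm(r, 3.5, 0.3) + dnorm(r, 4.5, 0.2))
  sc <- score_config(a, m)$score
  expect_gte(sc, 0); expect_lte(sc, 1)
  expect_error(score_config(a, b, window = c(11, 12)), "window")
})

test_that("a config containing the experimental 3.5 nm pair outscores a 2.0 nm-only config", {
  r <- seq(1, 10, by = 0.02)
  expr <- distance_distribution(
    r, 0.5 * dnorm(r, 3.5, 0.1) + 0.5 * dnorm(r, 4.5, 0.1))
  good <- simulate_distribution(c("ATCUN", "H287"), local_table)  # 3.5 nm
  bad <- simulate_distribution(c("ATCUN", "siteA"), local_table)  # 2.0 nm
  expect_gt(score_config(good, expr)$score, score_config(bad, expr)$score)
})

test_that("ranking places the generating config at least as high as its sub-configs", {
  r <- seq(1, 10, by = 0.02)
  gen <- c("ATCUN", "siteB", "H287")
  expr <- simulate_distribution(gen, local_table, r_grid = r)
  expr$source <- "experimental"
  cfgs <- enumerate_configs(rownames(local_table), 2, 6)
  rk <- rank_configs(cfgs, local_table, expr)
  gen_score <- rk$score[rk$config == paste(gen, collapse = ",")]
  subs <- c("ATCUN,siteB", "ATCUN,H287", "siteB,H287")
  for (s in subs) expect_gte(gen_score, rk$score[rk$config == s])
  # single-config input ranks that config first
  rk1 <- rank_configs(list(gen), local_table, expr)
  expect_equal(nrow(rk1), 1)
})

test_that("scores are unchanged under permutation of the config list", {
  r <- seq(1, 10, by = 0.02)
  expr <- distance_distribution(r, dnorm(r, 3.5, 0.2))
  cfgs <- enumerate_configs(rownames(local_table), 2, 3)
  set.seed(3)
  perm <- sample(seq_along(cfgs))
  rk1 <- rank_configs(cfgs, local_table, expr)
  rk2 <- rank_configs(cfgs[perm], local_table, expr)
  expect_equal(rk1, rk2)
})

test_that("mass wholly outside the window cannot raise the windowed score", {
  r <- seq(1, 10, by = 0.02)
  w <- detectability_window(1.5, 8)
  expr <- distance_distribution(r, dnorm(r, 3.5, 0.1))
  inside <- simulate_distribution(c("ATCUN", "H287"), local_table)
  # add a pair at 9.5 nm (outside the window) by hand
  dens <- (inside$density + dnorm(r, 9.5, 0.1)) / 2
  augmented <- distance_distribution(r, dens)
  s_in <- score_config(inside, expr, window = w)$score
  s_aug <- score_config(augmented, expr, window = w)$score
  expect_lte(s_aug, s_in + 1e-9)
})

test_that("detectability window defaults and validation", {
  w <- detectability_window()
  expect_equal(unname(w), c(1.5, 8.0))
  expect_error(detectability_window(5, 2), "lower < upper")
})
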