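test_that("constructed crossovers are recovered within one grid spacing", {
  gr <- gen_rheology(t_gel = 600, n_points = 200)
  g <- find_gel_point(gr$sweep)
  expect_lt(abs(g$t_gel - 600), gr$truth$grid_spacing)
  expect_true(g$bracket[1] <= g$t_gel && g$t_gel <= g$bracket[2])
  expect_gt(g$G_cross, 0)
})

test_that("monotone sweeps raise distinguishable no-gel-point errors", {
  t <- seq(10, 100, by = 10)
  expect_error(find_gel_point(rheology_sweep(t, rep(10, 10), rep(100, 10))),
               class = "brushmech_all_liquid")
  expect_error(find_gel_point(rheology_sweep(t, rep(100, 10), rep(10, 10))),
               class = "brushmech_all_solid")
})

test_that("a symmetric bracket interpolates to the midpoint", {
  # log G' - log G'' = (-a, -a, +a, +a): crossing between samples 2 and 3
  a <- 0.4
  gpp <- rep(100, 4)
  gp <- gpp * exp(c(-a, -a, a, a))
  g <- find_gel_point(rheology_sweep(c(100, 200, 300, 400), gp, gpp))
  expect_equal(g$t_gel, 250)
})

test_that("single-sample flickers are skipped but counted", {
  gpp <- rep(100, 8)
  d <- c(-0.5, 0.2, -0.4, -0.3, 0.3, 0.5, 0.8, 1.0)  # flicker at sample 2
  g <- find_gel_point(rheology_sweep(seq(10, 80, by = 10), 100 * exp(d), gpp))
  expect_equal(g$n_crossings, 2L)
  expect_true(g$t_gel > 40 && g$t_gel < 50)  # the sustained crossing
})

test_that("detection is invariant to uniform modulus rescaling", {
  gr <- gen_rheology(t_gel = 900, n_points = 150)
  g1 <- find_gel_point(gr$sweep)
  scaled <- rheology_sweep(gr$sweep$time_s, 7.3 * gr$sweep$G_prime_Pa,
                           7.3 * gr$sweep$G_double_prime_Pa)
  g2 <- find_gel_point(scaled)
  expect_equal(g2$t_gel, g1$t_gel)
  expect_equal(g2$G_cross, 7.3 * g1$G_cross, tolerance = 1e-12)
})

test_that("grid refinement shrinks the detection error", {
  errs <- vapply(c(50, 100, 200, 400), function(n) {
    gr <- gen_rheology(t_gel = 600, n_points = n)
    abs(find_gel_point(gr$sweep)$t_gel - 600)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("interpolated crossover modulus lies between the bracketing samples", {
  gr <- gen_rheology(t_gel = 300, n_points = 80)
  g <- find_gel_point(gr$sweep)
  sw <- gr$sweep
  i <- which(sw$time_s == g$bracket[1])
  rng <- range(sw$G_prime_Pa[i:(i + 1)], sw$G_double_prime_Pa[i:(i + 1)])
  expect_gte(g$G_cross, rng[1])
  expect_lte(g$G_cross, rng[2])
})

test_that("the median filter rescues a noisy sweep", {
  gr <- gen_rheology(t_gel = 600, n_points = 300, noise = "multiplicative",
                     noise_sd = 0.05, seed = 11)
  g <- find_gel_point(gr$sweep, median_filter = TRUE)
  expect_lt(abs(g$t_gel - 600) / 600, 0.1)
})

test_that("gel-time trends recover constructed functional forms", {
  # power law: t_gel = 5 * ratio^2
  ratios <- c(1, 2, 4, 8)
  d <- data.frame(t_gel = 5 * ratios^2, ratio = ratios)
  tr <- tgel_trend(d, "ratio", model = "loglog")
  expect_equal(tr$slope, 2, tolerance = 1e-6)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)
  # perfect Arrhenius dependence
  temps <- c(20, 37, 50)
  d2 <- data.frame(t_gel = exp(-5 + 4000 / (temps + 273.15)),
                   temperature_C = temps)
  tr2 <- tgel_trend(d2, "temperature_C", model = "arrhenius")
  expect_equal(tr2$slope, 4000, tolerance = 1e-6)
  expect_equal(tr2$r_squared, 1, tolerance = 1e-9)
})

test_that("trend fitting rejects degenerate covariate designs", {
  d <- data.frame(t_gel = c(10, 20, 30), ratio = c(1, 1, 2))
  expect_error(tgel_trend(d, "ratio"), "rank-deficient")
  expect_error(tgel_trend(data.frame(t_gel = c(1, 2), ratio = c(1, 2)),
                          "ratio"), "at least 3")
})

test_that("trend accepts a list of gel results sharing a covariate axis", {
  gels <- lapply(c(1, 2, 4), function(r) {
    gr <- gen_rheology(t_gel = 100 * r^1.5, n_points = 400)
    g <- find_gel_point(gr$sweep)
    g$covariates <- list(ratio = r)
    g
  })
  tr <- tgel_trend(gels, "ratio", model = "loglog")
  expect_equal(tr$slope, 1.5, tolerance = 0.01)
  gels[[2]]$covariates <- list(other = 2)
  expect_error(tgel_trend(gels, "ratio"), "covariate")
})
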