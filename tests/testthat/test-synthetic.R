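test_that("noiseless tensile curves equal the equation of state pointwise", {
  tg <- gen_tensile(E = 4.2, beta = 0.10, n_points = 40)
  expect_equal(tg$curve$sigma, eq1_oracle(tg$curve$lambda, 4.2, 0.10),
               tolerance = 1e-14)
  expect_equal(max(tg$curve$lambda), 0.10^-0.5)
  expect_equal(min(tg$curve$lambda), 1)
})

test_that("zero-variance noise is the identity and seeds are reproducible", {
  base <- gen_tensile(E = 5, beta = 0.2, n_points = 30)
  zero <- gen_tensile(E = 5, beta = 0.2, n_points = 30,
                      noise = "multiplicative", noise_sd = 0, seed = 1)
  expect_identical(base$curve$sigma, zero$curve$sigma)
  a <- gen_tensile(E = 5, beta = 0.2, n_points = 30,
                   noise = "multiplicative", noise_sd = 0.02, seed = 42)
  b <- gen_tensile(E = 5, beta = 0.2, n_points = 30,
                   noise = "multiplicative", noise_sd = 0.02, seed = 42)
  c <- gen_tensile(E = 5, beta = 0.2, n_points = 30,
                   noise = "multiplicative", noise_sd = 0.02, seed = 43)
  expect_identical(a$curve$sigma, b$curve$sigma)
  expect_false(identical(a$curve$sigma, c$curve$sigma))
})

test_that("tensile generator enforces its spec contracts", {
  expect_error(gen_tensile(5, 0.1, f_sing = 1), class = "brushmech_spec_error")
  expect_error(gen_tensile(5, 0, n_points = 20), class = "brushmech_spec_error")
  expect_error(gen_tensile(5, 0.1, noise = "multiplicative", noise_sd = 0.02),
               class = "brushmech_spec_error")  # seed mandatory
  expect_error(gen_tensile(5, 0.1, n_points = 4), class = "brushmech_spec_error")
  capped <- gen_tensile(5, 0.1, f_sing = 0.5)
  expect_lte(max(capped$curve$lambda), 0.5 * lambda_sing(0.1) + 1e-12)
})

test_that("rheology construction places the crossover analytically", {
  for (tg in c(60, 600, 3600)) {
    gr <- gen_rheology(t_gel = tg, n_points = 300)
    g <- find_gel_point(gr$sweep)
    expect_lt(abs(g$t_gel - tg), gr$truth$grid_spacing)
  }
  expect_error(gen_rheology(600, G_inf_prime = 100, G_inf_dblprime = 200),
               class = "brushmech_spec_error")  # no crossover possible
  a <- gen_rheology(600, noise = "additive", noise_sd = 5, seed = 7)
  b <- gen_rheology(600, noise = "additive", noise_sd = 5, seed = 7)
  expect_identical(a$sweep$G_prime_Pa, b$sweep$G_prime_Pa)
})

test_that("every generator's output passes its consumer's input validation", {
  expect_s3_class(gen_tensile(4.2, 0.1)$curve, "bb_curve")
  expect_s3_class(gen_rheology(600)$sweep, "bb_sweep")
  expect_s3_class(gen_tpa()$trace, "bb_tpa_trace")
})

test_that("end-to-end recovery closes the loop for all three generators", {
  tg <- gen_tensile(E = 15.3, beta = 0.23, n_points = 60)
  f <- fit_constitutive(tg$curve)
  expect_equal(f$params$E_struct, 15.3, tolerance = 1e-6)
  expect_equal(f$params$beta, 0.23, tolerance = 1e-6)
  gr <- gen_rheology(t_gel = 1200, n_points = 250)
  expect_lt(abs(find_gel_point(gr$sweep)$t_gel - 1200),
            gr$truth$grid_spacing)
  tp <- gen_tpa(peaks = c(1, 0.8), A_down = c(0.5, 0.3), A_up = c(0.4, 0.25))
  m <- tpa_metrics(tp$trace)
  expect_equal(m$cohesiveness, tp$truth$cohesiveness, tolerance = 1e-9)
  expect_equal(m$resilience, tp$truth$resilience, tolerance = 1e-9)
  expect_equal(m$springiness, tp$truth$springiness, tolerance = 1e-9)
})

test_that("TPA generator validates its area/peak request", {
  expect_error(gen_tpa(peaks = c(1, -1)), class = "brushmech_spec_error")
  expect_error(gen_tpa(A_down = c(0.5, 0)), class = "brushmech_spec_error")
  a <- gen_tpa(noise = "multiplicative", noise_sd = 0.02, seed = 3)
  b <- gen_tpa(noise = "multiplicative", noise_sd = 0.02, seed = 3)
  expect_identical(a$trace$force_N, b$trace$force_N)
  expect_error(gen_tpa(noise = "multiplicative", noise_sd = 0.02),
               class = "brushmech_spec_error")  # seed mandatory
})

test_that("the packaged reference table is complete and stable", {
  tab <- gen_table1_fixture()
  expect_equal(nrow(tab), 11L)
  fm <- tab[tab$chemistry == "F:M" & tab$ratio == "1:1", ]
  expect_equal(fm$E_kPa, 15.3)
  expect_equal(fm$beta, 0.23)
  expect_identical(as.data.frame(gen_table1_fixture()),
                   as.data.frame(gen_table1_fixture()))
})
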