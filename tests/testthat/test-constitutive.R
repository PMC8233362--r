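test_that("true stress vanishes at lambda = 1 and matches closed forms", {
  for (i in seq_len(nrow(param_grid))) {
    p <- material_params(param_grid$E[i], param_grid$beta[i])
    expect_identical(true_stress(1, p), 0)
  }
  # neo-Hookean limit closed form: (E/3)(lambda^2 - 1/lambda)
  expect_equal(true_stress(2, material_params(9, 0)), 10.5)
  lam <- seq(1, 4, by = 0.05)
  p0 <- material_params(7.3, 0)
  expect_equal(true_stress(lam, p0), (7.3 / 3) * (lam^2 - 1 / lam),
               tolerance = 1e-15)
  # frozen arbitrary-precision evaluation of the printed equation
  expect_equal(true_stress(1.5, material_params(15.3, 0.23)),
               12.9255987347033632, tolerance = 1e-14)
})

test_that("true stress rejects inadmissible elongations", {
  p <- material_params(5, 0.25)  # singular condition near lambda ~ 3.4
  expect_error(true_stress(-1, p), class = "brushmech_domain_error")
  expect_error(true_stress(0, p), class = "brushmech_domain_error")
  expect_error(true_stress(5, p), class = "brushmech_domain_error")
  # compression is admissible and carries the sign of (lambda - 1)
  expect_lt(true_stress(0.8, p), 0)
  expect_gt(true_stress(1.2, p), 0)
})

test_that("Young's modulus formula matches the numerical initial slope", {
  expect_equal(young_modulus(material_params(5, 0)), 5)
  expect_equal(round_half_up(young_modulus(material_params(15.3, 0.23)), 1),
               22.3)
  expect_equal(round_half_up(young_modulus(material_params(4.8, 0.06)), 1),
               5.2)
  expect_error(young_modulus(3, beta = 1), class = "brushmech_domain_error")
  h <- 1e-5
  for (i in seq_len(nrow(param_grid))) {
    p <- material_params(param_grid$E[i], param_grid$beta[i])
    slope <- (true_stress(1 + h, p) - true_stress(1 - h, p)) / (2 * h)
    expect_equal(slope, p$E0, tolerance = 1e-6)
  }
})

test_that("theoretical elongation at break is beta^(-1/2)", {
  expect_equal(lambda_max_theo(0.25), 2)
  expect_equal(round_half_up(lambda_max_theo(0.08), 1), 3.5)
  expect_equal(round_half_up(lambda_max_theo(0.06), 1), 4.1)
  expect_error(lambda_max_theo(0), class = "brushmech_domain_error")
  expect_error(lambda_max_theo(1), class = "brushmech_domain_error")
})

test_that("stress is strictly increasing up to the singularity and diverges there", {
  for (i in seq_len(nrow(param_grid))) {
    E <- param_grid$E[i]; b <- param_grid$beta[i]
    p <- material_params(E, b)
    ls <- lambda_sing(b)
    lam <- seq(1, 0.999 * ls, length.out = 200)
    sig <- true_stress(lam, p)
    expect_true(all(diff(sig) > 0))
    mid <- true_stress(0.5 * (1 + ls), p)
    expect_gt(true_stress(0.999 * ls, p), 100 * mid)
  }
})

test_that("singular elongation bounds the strand-extensibility estimate", {
  betas <- seq(0.01, 0.99, by = 0.01)
  for (b in betas) {
    ls <- lambda_sing(b)
    expect_gte(ls, lambda_max_theo(b))
    # root actually satisfies the defining cubic condition
    expect_lt(abs(b * (ls^2 + 2 / ls) / 3 - 1), 1e-8)
  }
})

test_that("material parameter invariants are enforced", {
  expect_error(material_params(-1, 0.1))
  expect_error(material_params(5, 1))
  expect_error(material_params(5, -0.1))
  p <- material_params(4.2, 0.1)
  expect_equal(p$E0, eq2_oracle(4.2, 0.1))
  expect_equal(p$lambda_max, 0.1^-0.5)
  expect_true(is.na(material_params(4.2, 0)$lambda_max))
})

test_that("architectural scaling law has the printed exponent and linearity", {
  k <- scaling_constants("calibrated", C = 1000)
  r <- structural_modulus_predicted(0.2, 14, k) /
    structural_modulus_predicted(0.2, 70, k)
  expect_equal(r, (71 / 15)^1.5, tolerance = 1e-12)
  expect_identical(structural_modulus_predicted(0, 14, k), 0)
  expect_equal(structural_modulus_predicted(0.4, 14, k),
               2 * structural_modulus_predicted(0.2, 14, k))
})

test_that("scaling constants validate their mode requirements", {
  expect_error(scaling_constants("calibrated"),
               class = "brushmech_missing_constant")
  expect_error(scaling_constants("analytic"),
               class = "brushmech_missing_constant")
  ka <- scaling_constants("analytic", v = 0.1)
  E <- structural_modulus_predicted(0.1, 14, ka)
  expect_true(is.finite(E) && E > 0)
})

test_that("engineering/true stress conversion is the incompressible identity", {
  expect_equal(engineering_to_true(1, 5), 5)
  expect_equal(engineering_to_true(2, 3), 6)
  lam <- seq(1, 3, by = 0.1); sig <- lam^2
  expect_equal(engineering_to_true(lam, sig / lam), sig)
  expect_error(engineering_to_true(0, 1), class = "brushmech_domain_error")
})

test_that("architecture descriptor validates its DP invariants", {
  a <- architecture(200, 14, 889, "NCO:OH", "1:4")
  expect_s3_class(a, "bb_architecture")
  expect_error(architecture(1000, 14, 889))   # n_x > n_bb
  expect_error(architecture(0, 14, 889))
  expect_error(architecture(10.5, 14, 889))
})
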