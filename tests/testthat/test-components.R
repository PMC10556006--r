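test_that("ingestion rate is allometric and proportional to phi", {
  p <- ingestion_params(alpha = 1, beta = 0.75)
  expect_equal(ingestion_rate(1, 16, p), 8)
  expect_equal(ingestion_rate(0, 123, p), 0)
  expect_equal(ingestion_rate(0.5, 16, p), 4)
  # homogeneity: doubling alpha doubles S at every mass
  p2 <- ingestion_params(alpha = 2, beta = 0.75)
  W <- c(0.67, 5, 50, 400)
  expect_equal(ingestion_rate(0.8, W, p2), 2 * ingestion_rate(0.8, W, p))
})

test_that("post-break ingestion policies differ only above the break mass", {
  hold <- ingestion_params(1, 0.75, W_break = 16)
  cap <- ingestion_params(1, 0.75, W_break = 16,
                          post_break_policy = "cap-at-break-value")
  expect_equal(ingestion_rate(1, 10, hold), ingestion_rate(1, 10, cap))
  expect_equal(ingestion_rate(1, 81, hold), 27)
  expect_equal(ingestion_rate(1, 81, cap), 8)
})

test_that("ingestion rejects invalid phi and mass", {
  p <- ingestion_params(1, 0.75)
  expect_error(ingestion_rate(1.2, 10, p), "phi")
  expect_error(ingestion_rate(-0.1, 10, p), "phi")
  expect_error(ingestion_rate(0.5, -1, p), "positive")
})

test_that("energy density of new tissue follows the composition mix", {
  expect_equal(energy_density_EM(1, composition_params(f_CP = 1, f_L = 0)), 17)
  expect_equal(energy_density_EM(1, composition_params(f_CP = 0, f_L = 1)), 34)
  expect_equal(energy_density_EM(1, composition_params(f_R = 1, E_MR = 20)), 20)
  # mixed composition: (17 * 0.5 + 34 * 0.25) * 0.8 + 7 * 0.2
  c_mix <- composition_params(f_CP = 0.5, f_L = 0.25, f_R = 0.2, E_MR = 7)
  expect_equal(energy_density_EM(1, c_mix), 17 * 0.5 * 0.8 + 34 * 0.25 * 0.8 + 1.4)
  expect_error(energy_density_EM(1, composition_params(f_CP = 0.7, f_L = 0.5)),
               "composition")
})

test_that("growth overhead mixes division, enlargement and reproduction", {
  expect_equal(growth_overhead_ES(1, composition_params(f_R = 0, f_G = 1,
                                                        E_SSG = 5)), 5)
  expect_equal(growth_overhead_ES(1, composition_params(f_R = 1, E_SR = 8)), 8)
  expect_equal(growth_overhead_ES(1, composition_params(f_R = 0.5, f_G = 0,
                                                        E_SSD = 4, E_SR = 8)), 6)
  # a mass-dependent enlargement fraction hook is honoured
  cc <- composition_params(f_G = function(W) pmin(1, 0.1 * W), E_SSD = 2,
                           E_SSG = 6, f_R = 0)
  expect_equal(growth_overhead_ES(5, cc), 0.5 * 2 + 0.5 * 6)
})

test_that("feeding cost is proportional by default and accepts monotone customs", {
  expect_equal(feeding_cost(100, feeding_params(k_F = 0.1)), 10)
  expect_equal(feeding_cost(0, feeding_params(k_F = 0.1)), 0)
  fp <- feeding_params(cost_fn = function(S) 0.05 * S + 0.001 * S^2)
  expect_equal(feeding_cost(10, fp), 0.6)
  expect_error(feeding_params(cost_fn = function(S) -S), "non-decreasing")
  expect_error(feeding_params(cost_fn = function(S) S + 1), "vanish")
  expect_error(feeding_params(k_F = 1), "k_F")
})

test_that("defence fraction follows its allometric-downregulation form", {
  expect_equal(defence_fraction(1, 4, a_N = 0.1, b_N = 1, delta = 1), 0.4)
  expect_equal(defence_fraction(0, 123, a_N = 0.5, b_N = 2, delta = 1), 0)
  expect_equal(defence_fraction(1, 77, a_N = 0.3, b_N = 0, delta = 2), 0.3)
  expect_error(defence_fraction(1, 20, a_N = 0.1, b_N = 1, delta = 1),
               "diverge")
})

test_that("maintenance cost reproduces its basal and negotiable limits", {
  # basal only
  m0 <- maintenance_params(gamma_BS = 0.5, a_NS = 0)
  expect_equal(maintenance_cost(1, 10, m0), 5)
  # phi = 0 with delta = 1 fully downregulates the negotiable part
  m1 <- maintenance_params(gamma_BS = 0.5, a_NS = 0.2, b_NS = 0, delta = 1)
  expect_equal(maintenance_cost(0, 10, m1), 5)
  # one-tissue amplification 1 / (1 - rho)
  m2 <- maintenance_params(gamma_BS = 1, a_NS = 0.5, b_NS = 1, delta = 1)
  expect_equal(maintenance_cost(1, 1, m2), 2)
  # two-tissue sum with defence off
  m3 <- maintenance_params(gamma_BS = 1, gamma_BR = 2, a_NS = 0, a_NR = 0)
  expect_equal(maintenance_cost(1, 2, m3, p_R = 0.5), 1 * 1 + 2 * 1)
  expect_error(maintenance_cost(1, 600, m2), "diverge")
})

test_that("two-tissue maintenance collapses to the one-tissue form when tissues coincide", {
  m2t <- maintenance_params(gamma_BS = 0.4, gamma_BR = 0.4,
                            a_NS = 0.002, a_NR = 0.002, b_NS = 1, b_NR = 1,
                            delta = 0.8)
  for (phi in c(0.3, 0.7, 1)) {
    for (W in c(0.67, 5, 60, 300)) {
      one <- maintenance_cost(phi, W, m2t, p_R = 0)
      direct <- 0.4 * W / (1 - 0.002 * W * phi^0.8)
      expect_equal(one, direct, tolerance = 1e-14)
    }
  }
  # p_R > 0 with identical halved tissues differs from the pooled one-tissue
  # form only through the allometry of the defence fraction; with b_N = 0 the
  # two coincide exactly
  m0 <- maintenance_params(gamma_BS = 0.4, gamma_BR = 0.4,
                           a_NS = 0.3, a_NR = 0.3, b_NS = 0, b_NR = 0)
  expect_equal(maintenance_cost(0.5, 100, m0, p_R = 0.25),
               0.4 * 100 / (1 - 0.3 * 0.5))
})

test_that("maintenance is non-decreasing in phi and linear in W when b_N = 0", {
  m <- maintenance_params(gamma_BS = 0.33, a_NS = 0.0011, b_NS = 1, delta = 1)
  for (W in c(1, 50, 250)) {
    costs <- vapply(seq(0, 1, by = 0.1), maintenance_cost, numeric(1),
                    W = W, m = m)
    expect_true(all(diff(costs) >= 0))
  }
  mlin <- maintenance_params(gamma_BS = 0.2, a_NS = 0.4, b_NS = 0, delta = 1)
  W <- c(1, 10, 100, 1000)
  expect_equal(maintenance_cost(0.6, W, mlin),
               W * maintenance_cost(0.6, 1, mlin))
})
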