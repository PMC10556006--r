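test_that("growth rate matches the reduced four-parameter form", {
  expect_equal(growth_rate(mgm33_params(1, 2 / 3, 0, 0), 8), 4)
  expect_equal(growth_rate(mgm33_params(1, 0.75, 0.5, 0.1), 1),
               1 - 0.5 / 0.9)
  # singular defence fraction is an error, not a clamp
  expect_error(growth_rate(mgm33_params(1, 0.75, 0.5, 0.1), 11), "diverge")
})

test_that("the growth rate vanishes at the ultimate mass", {
  p <- mgm_default_params()
  W_U <- ultimate_mass(p, phi = 1)
  expect_lt(abs(growth_rate(p, W_U, 1)), 1e-10 * growth_rate(p, W_U / 2, 1))
})

test_that("constant-rate growth integrates linearly", {
  p <- mgm33_params(a = 1, beta = 0, c = 0, a_N = 0)
  traj <- integrate_growth(p, W0 = 1, t_end = 5)
  expect_equal(traj$mass[traj$age == 5], 6, tolerance = 1e-8)
})

test_that("with b_N = 0 the engine reproduces the closed-form von Bertalanffy solution", {
  grid <- list(c(a = 1, b = 1, beta = 2 / 3, W0 = 0.125),
               c(a = 2, b = 1, beta = 2 / 3, W0 = 1),
               c(a = 1.5, b = 0.8, beta = 0.75, W0 = 0.67),
               c(a = 0.9, b = 0.25, beta = 0.5, W0 = 0.05),
               c(a = 3, b = 2, beta = 0.9, W0 = 0.67))
  for (g in grid) {
    p <- mgm_vb(g[["a"]], g[["b"]], g[["beta"]])
    t_end <- 12 / ((1 - g[["beta"]]) * g[["b"]])
    traj <- integrate_growth(p, W0 = g[["W0"]], t_end = t_end)
    exact <- vb_closed_form(traj$age, g[["a"]], g[["b"]], g[["beta"]],
                            g[["W0"]])
    expect_lt(max(abs(traj$mass - exact) / exact), 1e-6)
  }
})

test_that("trajectories are monotone and bounded by the ultimate mass", {
  for (phi in c(1, 0.7)) {
    p <- mgm_default_params()
    traj <- integrate_growth(p, W0 = 0.67, t_end = 400, phi = phi)
    expect_true(all(diff(traj$mass) >= -1e-9))
    expect_lte(max(traj$mass),
               ultimate_mass(p, phi = phi) * (1 + 1e-8))
  }
})

test_that("ultimate mass agrees with closed form, plateau, and error cases", {
  # (a/b)^(1/(1-beta)) for the von Bertalanffy reduction
  expect_equal(ultimate_mass(vb_params(2, 1, 2 / 3), W0 = 0.1), 8,
               tolerance = 1e-9)
  # root finder agrees with a long integration plateau
  p <- mgm33_params(a = 1, beta = 0.75, c = 0.25, a_N = 0.05)
  W_U <- ultimate_mass(p, W0 = 0.67)
  traj <- integrate_growth(p, W0 = 0.67, t_end = 400)
  expect_equal(max(traj$mass), W_U, tolerance = 1e-6)
  # immediate decline
  expect_error(ultimate_mass(mgm33_params(a = 0.01, beta = 0.75, c = 5,
                                          a_N = 0), W0 = 1), "decline")
  # indefinite growth (supply always beats expenditure)
  expect_error(ultimate_mass(mgm33_params(a = 2, beta = 1.2, c = 0.1,
                                          a_N = 0), W0 = 1), "indefinite")
})

test_that("trajectory summaries recover analytic descriptors of comparators", {
  # logistic: symmetric hump, omega* = 1/2
  lg <- logistic_params(r = 0.5, K = 4)
  traj <- integrate_growth(lg, W0 = 0.05, t_end = 60)
  s <- summarize_trajectory(traj)
  expect_equal(s$W_star, 2, tolerance = 1e-6)
  expect_equal(s$omega_star, 0.5, tolerance = 1e-6)
  expect_equal(s$Wdot_max, 0.5, tolerance = 1e-6)
  # von Bertalanffy beta = 2/3: omega* = 8/27
  vb <- vb_params(1, 1, 2 / 3)
  tvb <- integrate_growth(vb, W0 = 0.125, t_end = 25,
                          ages = seq(0, 25, length.out = 5001))
  svb <- summarize_trajectory(tvb)
  expect_equal(svb$omega_star, 8 / 27, tolerance = 1e-8)
  # t95 against analytic inversion of the closed form
  u <- 1 / 3
  t95_exact <- -log((1 - 0.95^u) / (1 - 0.125^u)) / (u * 1)
  expect_equal(svb$t95, t95_exact, tolerance = 1e-6)
  # t_at_fraction is monotone in the fraction
  fr <- seq(0.3, 0.95, by = 0.05)
  expect_true(all(diff(svb$t_at_fraction(fr)) > 0))
})

test_that("summaries demand a trajectory long enough to reach W95", {
  p <- mgm_default_params()
  short <- integrate_growth(p, W0 = 0.67, t_end = 30)
  expect_error(summarize_trajectory(short), "t_end")
})

test_that("energy budgets close along integrated trajectories", {
  p <- mgm_default_params()
  traj <- integrate_growth(p, W0 = 0.67, t_end = 200,
                           ages = seq(0, 200, length.out = 201))
  eb <- energy_budget_series(traj)
  expect_lt(max(abs(eb$rel_residual)), 1e-8)
  expect_true(all(eb$S > 0))
  # maintenance-free model spends nothing on R_M
  p0 <- mgm_params(ingestion_params(1, 0.75), flat_composition(2),
                   feeding_params(0.1),
                   maintenance_params(gamma_BS = 1e-300, a_NS = 0), e = 0.7)
  t0 <- integrate_growth(p0, 1, 5, ages = seq(0, 5, length.out = 21))
  expect_equal(max(energy_budget_series(t0)$R_M), 0, tolerance = 1e-250)
  # phi = 0: no intake, negative bound-energy rate flagged
  ebz <- energy_budget_series(integrate_growth(p, 10, 1, phi = 0,
                                               ages = c(0, 0.5, 1)))
  expect_true(all(ebz$S == 0))
  expect_true(all(ebz$shrinking))
})

test_that("identical parameters and solver settings give bit-identical trajectories", {
  p <- mgm_default_params()
  t1 <- integrate_growth(p, 0.67, 150)
  t2 <- integrate_growth(p, 0.67, 150)
  expect_identical(t1$mass, t2$mass)
})

test_that("piecewise-constant phi schedules are honoured", {
  p <- mgm_vb(1, 0.5, 2 / 3)
  sched <- stats::stepfun(5, c(1, 0.5))
  traj <- integrate_growth(p, 0.5, 10, phi = sched,
                           ages = seq(0, 10, length.out = 501))
  full <- integrate_growth(p, 0.5, 10, phi = 1,
                           ages = seq(0, 10, length.out = 501))
  expect_equal(traj$mass[traj$age <= 5], full$mass[full$age <= 5],
               tolerance = 1e-7)
  expect_true(all(traj$mass[traj$age > 6] < full$mass[full$age > 6]))
})

test_that("restriction sweep reproduces the delta-dependent response patterns", {
  p <- mgm_default_params()
  sw <- food_restriction_sweep(p, phi_grid = seq(1, 0.5, by = -0.1),
                               delta_grid = c(0.5, 1), t_end = 600)
  expect_true(all(is.na(sw$error)))
  for (d in c(0.5, 1)) {
    rows <- sw[sw$delta == d, ]
    expect_equal(rows$phi, seq(1, 0.5, by = -0.1))
    # W95 falls and t95 rises monotonically with restriction
    expect_true(all(diff(rows$W95) < 0))
    expect_true(all(diff(rows$t95) > 0))
  }
  # the ad-libitum column is delta-independent
  adlib <- sw[sw$phi == 1, ]
  expect_equal(adlib$W_U[1], adlib$W_U[2], tolerance = 1e-10)
  expect_equal(adlib$t95[1], adlib$t95[2], tolerance = 1e-8)
})

test_that("growth-rate curves are ordered by food acquirement", {
  p <- mgm_default_params()
  Wgrid <- seq(1, 150, length.out = 40)
  rates <- sapply(c(0.5, 0.7, 0.9, 1), function(phi)
    growth_rate(p, Wgrid, phi))
  expect_true(all(diff(t(rates)) > 0))
})

test_that("with b_N = 0 the age at a given mass fraction is nearly independent of phi", {
  # classical regime: surface-limited uptake, no negotiable maintenance
  p <- mgm_params(ingestion_params(alpha = 4.5, beta = 2 / 3),
                  composition_params(), feeding_params(0.1),
                  maintenance_params(gamma_BS = 0.33, a_NS = 0, b_NS = 0),
                  e = 0.7)
  phis <- c(1, 0.9, 0.8, 0.7, 0.6)
  ages <- sapply(phis, function(phi) {
    traj <- integrate_growth(p, 0.67, 900, phi = phi)
    s <- summarize_trajectory(traj, p)
    s$t_at_fraction(c(0.75, 0.9, 0.95))
  })
  spread <- apply(ages, 1, function(a) diff(range(a)) / max(a))
  expect_true(all(spread < 0.05))
})

test_that("sweep records per-cell failures without aborting", {
  # high maintenance: growth impossible at low phi
  p <- mgm_default_params()
  p$maintenance$gamma_BS <- 2
  sw <- food_restriction_sweep(p, phi_grid = c(1, 0.05), delta_grid = 1,
                               t_end = 200)
  expect_true(any(!is.na(sw$error)))
  expect_true(any(is.na(sw$error)))
})
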