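default_grid <- function(t_end = 4e4) seq(0, t_end, by = 165)

test_that("no nucleation source means no fibril mass", {
  p <- aggregation_params(kn = 0, k2 = 0, m_total = 2e-6)
  traj <- simulate_aggregation(p, default_grid())
  expect_true(all(traj$M == 0))
  expect_true(all(traj$m == 2e-6))
})

test_that("mass is conserved and moments are monotone across random draws", {
  set.seed(2024)
  for (i in 1:60) {
    p <- aggregation_params(
      kn = 10^stats::runif(1, -6, -2),
      kplus = 10^stats::runif(1, 5, 7),
      k2 = 10^stats::runif(1, 2, 6),
      m_total = 10^stats::runif(1, -6.5, -5.5),
      M0 = 0, P0 = 0
    )
    traj <- simulate_aggregation(p, default_grid(2e4))
    expect_lte(max(abs(traj$m + traj$M - p$m_total)) / p$m_total, 1e-6)
    expect_true(all(diff(traj$M) >= -1e-12 * p$m_total))
    expect_true(all(diff(traj$P) >= -1e-16))
    expect_true(all(traj$m >= 0) && all(traj$M >= 0) && all(traj$P >= 0))
  }
})

test_that("early-time fibril mass follows the quadratic limit for k2 = 0", {
  # leading order of the unseeded primary-nucleation system:
  # M(t) ~ ends * kn * kplus * m_total^(nc+1) * t^2 / 2 * ... with
  # dP = kn m^nc, dM = ends kplus m P => M ~ ends kplus kn m^(nc+1) t^2 / 2
  p <- aggregation_params(kn = 1e-4, k2 = 0, kplus = 3e6, m_total = 2e-6)
  th <- half_time(amytrap:::simulate_to_plateau(p))
  t <- seq(0, 0.01 * th, length.out = 50)
  traj <- simulate_aggregation(p, t)
  expected <- p$ends * p$kplus * p$kn * p$m_total^(p$nc + 1) * t^2 / 2
  sel <- expected > 0
  expect_lt(max(abs(traj$M[sel] / expected[sel] - 1)), 0.01)
})

test_that("half-time interpolation is exact on a logistic and grid-robust", {
  # symmetric logistic: midpoint is the half-time by construction
  t0 <- 5000; tau <- 400
  t <- seq(0, 2e4, by = 165)
  M <- 1e-6 / (1 + exp(-(t - t0) / tau))
  # shift so the curve starts at 0 like a real mass curve
  M <- M - M[1]
  ht <- half_time(list(t = t, M = M))
  expect_equal(ht, t0, tolerance = 1e-3)

  p <- aggregation_params(m_total = 2e-6)
  tr1 <- simulate_aggregation(p, default_grid())
  tr2 <- simulate_aggregation(p, seq(0, 4e4, by = 82.5))
  h1 <- half_time(tr1); h2 <- half_time(tr2)
  expect_lt(abs(h1 / h2 - 1), 1e-3)
  # interpolated crossing equals the fine-grid oracle
  expect_lt(abs(h1 / fine_grid_half_time(tr1) - 1), 1e-3)
})

test_that("half-time errors on incomplete or flat curves", {
  p <- aggregation_params(m_total = 2e-6)
  th <- half_time(amytrap:::simulate_to_plateau(p))
  early <- simulate_aggregation(p, seq(0, 0.8 * th, length.out = 60))
  expect_error(half_time(early), "incomplete")
  expect_error(half_time(list(t = 0:99, M = rep(0, 100))), "no aggregation")
})

test_that("inhibitor couplings reduce to the uninhibited model when inert", {
  p <- aggregation_params(m_total = 2e-6)
  grid <- default_grid()
  base <- simulate_aggregation(p, grid)
  # zero binder
  i0 <- inhibitor_model(83e-9, 0, K_I = Inf)
  expect_identical(simulate_with_inhibitor(p, i0, grid)$M, base$M)
  # binder that neither sequesters (Kd -> Inf) nor modulates
  iweak <- inhibitor_model(1e3, 1e-6, K_I = Inf)
  tw <- simulate_with_inhibitor(p, iweak, grid)
  expect_lt(max(abs(tw$M - base$M)) / p$m_total, 1e-6)
})

test_that("sequestration-only inhibition is bit-identical to reduced monomer", {
  p <- aggregation_params(m_total = 2e-6)
  grid <- default_grid()
  inh <- inhibitor_model(83e-9, 1e-6, K_I = Inf)
  a <- simulate_with_inhibitor(p, inh, grid)
  m_eff <- free_monomer(2e-6, 1e-6, 83e-9)
  p2 <- p; p2$m_total <- m_eff
  b <- simulate_aggregation(p2, grid)
  expect_identical(a$M, b$M)
  expect_identical(a$P, b$P)
  expect_equal(attr(a, "effective_m_total"), m_eff)
  expect_equal(m_eff, 1.07e-6, tolerance = 0.005)
  # and the half-time is strictly longer than uninhibited
  expect_gt(half_time(amytrap:::simulate_to_plateau(p2)),
            half_time(amytrap:::simulate_to_plateau(p)))
})

test_that("modulation factor interpolates the table and honours both forms", {
  inh <- inhibitor_model(83e-9, 5e-7,
                         k2_factors = data.frame(conc = c(2.5e-7, 1e-6),
                                                 factor = c(0.6, 0.2)))
  expect_identical(modulation_factor(inh, 0), 1)
  expect_equal(modulation_factor(inh, 2.5e-7), 0.6)
  expect_equal(modulation_factor(inh, 1e-6), 0.2)
  mid <- modulation_factor(inh, 6e-7)
  expect_true(mid < 0.6 && mid > 0.2)
  expect_equal(modulation_factor(inh, 1e-5), 0.2)  # saturates past table
  par <- inhibitor_model(83e-9, 5e-7, K_I = 5e-7)
  expect_equal(modulation_factor(par, 5e-7), 0.5)
  expect_error(inhibitor_model(83e-9, 1e-6,
                               k2_factors = data.frame(conc = 1e-6,
                                                       factor = 1.2)),
               "0, 1")
})

test_that("half-time decreases with monomer, elongation and secondary nucleation", {
  base <- aggregation_params(m_total = 2e-6)
  th <- function(p) half_time(amytrap:::simulate_to_plateau(p))
  for (field in c("m_total", "kplus", "k2")) {
    vals <- base[[field]] * c(0.5, 1, 2)
    hs <- vapply(vals, function(v) {
      p <- base; p[[field]] <- v; th(p)
    }, numeric(1))
    expect_true(all(diff(hs) < 0), info = field)
  }
})

test_that("half-time scaling exponent diagnoses the dominant pathway", {
  m_grid <- 2e-6 * c(0.5, 1, 2, 4)
  # secondary-nucleation dominated, n2 = 2: exponent near -1.5
  p2 <- aggregation_params(kn = 1e-4, kplus = 3e6, k2 = 1e4, m_total = 2e-6)
  s2 <- half_time_scaling(p2, m_grid)
  expect_gte(s2$slope, -1.8); expect_lte(s2$slope, -1.2)
  # primary-only, nc = 2: shallower exponent
  p1 <- aggregation_params(kn = 1e-2, kplus = 3e6, k2 = 0, m_total = 2e-6)
  s1 <- half_time_scaling(p1, m_grid)
  expect_gte(s1$slope, -1.6); expect_lte(s1$slope, -0.9)
  # invariant under time-unit rescaling (all rates in 1/min instead of 1/s)
  p2min <- aggregation_params(kn = 1e-4 * 60, kplus = 3e6 * 60,
                              k2 = 1e4 * 60, m_total = 2e-6)
  s2min <- half_time_scaling(p2min, m_grid)
  expect_equal(s2min$slope, s2$slope, tolerance = 1e-3)
  expect_error(half_time_scaling(p2, c(1e-6, 2e-6)), ">= 4")
})

test_that("simulation rejects invalid grids and parameters", {
  p <- aggregation_params(m_total = 2e-6)
  expect_error(simulate_aggregation(p, seq(100, 200, by = 10)), "start at 0")
  expect_error(aggregation_params(kn = -1), ">= 0")
  expect_error(aggregation_params(m_total = 0), "m_total")
  expect_error(aggregation_params(M0 = 3e-6, m_total = 2e-6), "M0")
})
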