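test_that("normalization is affine-invariant, idempotent and flags flat traces", {
  p <- aggregation_params(m_total = 2e-6)
  ds <- gen_tht_dataset(seed = 3, params = p, sigma = 0, binder_concs = 0,
                        replicates = 2)
  nds <- normalize_tht(ds)
  grid <- sort(unique(ds$time_s))
  traj <- simulate_aggregation(p, grid)
  # affine invariance: a*M + b normalizes exactly like M itself
  raw <- tht_dataset(data.frame(time_s = grid, F = traj$M,
                                binder_conc_M = 0, replicate = 1),
                     monomer_conc = 2e-6)
  target <- normalize_tht(raw)$frac
  for (r in 1:2) {
    got <- nds$frac[nds$replicate == r]
    expect_equal(got, target, tolerance = 1e-9)
  }
  # and the result tracks M / M(plateau) up to the 5-point baseline bias
  expect_lt(max(abs(target - traj$M / traj$M[length(grid)])), 1e-3)
  # idempotent: renormalizing the normalized data changes nothing
  ds2 <- ds; ds2$F <- nds$frac
  nds2 <- normalize_tht(ds2)
  expect_equal(nds2$frac, nds$frac, tolerance = 1e-9)

  # flat trace flagged as no aggregation
  flat <- ds
  sel <- flat$replicate == 2
  flat$F[sel] <- 0.1
  nflat <- normalize_tht(flat)
  info <- attr(nflat, "normalization")
  expect_true(info$no_aggregation[info$replicate == 2])
  expect_false(info$no_aggregation[info$replicate == 1])

  # short traces are rejected
  short <- tht_dataset(data.frame(time_s = 1:5, F = 1:5,
                                  binder_conc_M = 0, replicate = 1),
                       monomer_conc = 2e-6)
  expect_error(normalize_tht(short), "fewer than 10")
})

test_that("uninhibited fit recovers rate products from its own model", {
  truth <- c(kn_kplus = 300, k2_kplus = 3e10)
  # noiseless: < 1% error
  ds0 <- gen_tht_dataset(seed = 1, sigma = 0, binder_concs = 0)
  f0 <- fit_uninhibited(normalize_tht(ds0))
  expect_true(f0$converged)
  expect_lt(max(abs(coef(f0) / truth - 1)), 0.01)

  # sigma = 0.02: median error over seeds < 10%
  errs <- vapply(1:7, function(sd) {
    ds <- gen_tht_dataset(seed = sd, sigma = 0.02, binder_concs = 0)
    max(abs(coef(fit_uninhibited(normalize_tht(ds))) / truth - 1))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)

  # the two-pathway model beats a primary-only model on its own data
  nds <- normalize_tht(gen_tht_dataset(seed = 2, sigma = 0.02,
                                       binder_concs = 0))
  full <- fit_uninhibited(nds)
  d0 <- nds[nds$binder_conc_M == 0, ]
  p_nok2 <- full$params; p_nok2$k2 <- 0
  grid <- sort(unique(c(0, d0$time_s)))
  pred <- stats::approx(grid, simulate_aggregation(p_nok2, grid)$M /
                          full$m_total, xout = d0$time_s)$y
  expect_lt(full$rss, sum((d0$frac - pred)^2))
})

test_that("sequestration-only predictions shift right and underfit modulated data", {
  ds <- gen_tht_dataset(seed = 6, binder_concs = c(0, 2.5e-7, 5e-7),
                        k2_factors = data.frame(conc = c(2.5e-7, 5e-7),
                                                factor = c(0.5, 0.2)))
  nds <- normalize_tht(ds)
  fit <- fit_uninhibited(nds)
  sp <- predict_sequestration_only(fit, 83e-9, c(0, 2.5e-7, 5e-7),
                                   ndata = nds)
  # zero binder: the uninhibited curve itself
  c0 <- sp$curves[sp$curves$binder_conc_M == 0, ]
  base <- predict(fit, t_grid = c0$t)
  expect_equal(c0$frac, base$frac, tolerance = 1e-9)
  # curves shift right monotonically with binder concentration
  th <- vapply(c(0, 2.5e-7, 5e-7), function(bc) {
    cv <- sp$curves[sp$curves$binder_conc_M == bc, ]
    half_time(list(t = cv$t, M = cv$frac), plateau = max(cv$frac))
  }, numeric(1))
  expect_true(all(diff(th) > 0))
  # data carry secondary-nucleation suppression the sequestration-only
  # model cannot explain: its residuals exceed the full model's
  mod <- fit_secondary_modulation(nds, fit, 83e-9)
  for (bc in c(2.5e-7, 5e-7)) {
    expect_gt(sp$residuals$rss[sp$residuals$binder_conc_M == bc],
              mod$factors$rss[mod$factors$binder_conc_M == bc])
  }
  expect_error(predict_sequestration_only(fit, NA, 1e-6), "binder_Kd")
})

test_that("modulation factors are recovered within 15% at sigma = 0.02", {
  truth <- c(0.5, 0.2)
  ds <- gen_tht_dataset(seed = 8, sigma = 0.02,
                        binder_concs = c(0, 2.5e-7, 5e-7),
                        k2_factors = data.frame(conc = c(2.5e-7, 5e-7),
                                                factor = truth))
  nds <- normalize_tht(ds)
  fit <- fit_uninhibited(nds)
  mod <- fit_secondary_modulation(nds, fit, 83e-9)
  expect_lt(max(abs(mod$factors$factor / truth - 1)), 0.15)
  expect_false(any(mod$factors$excluded))
  # half-times increase with binder concentration
  expect_true(all(diff(c(mod$t_half_uninhibited, mod$factors$t_half)) > 0))
})

test_that("factor pins to 1 on sequestration-only data", {
  ds <- gen_tht_dataset(seed = 4, sigma = 0, binder_concs = c(0, 5e-7),
                        k2_factors = data.frame(conc = 5e-7, factor = 1))
  nds <- normalize_tht(ds)
  fit <- fit_uninhibited(nds)
  mod <- fit_secondary_modulation(nds, fit, 83e-9)
  # exact up to the small baseline bias of the normalization convention
  expect_equal(mod$factors$factor, 1, tolerance = 1e-3)
})

test_that("conditions with > 90% bound monomer are excluded and flagged", {
  ds <- gen_tht_dataset(seed = 5, binder_Kd = 1e-9,
                        binder_concs = c(0, 5e-7, 4e-6))
  nds <- normalize_tht(ds)
  fit <- fit_uninhibited(nds)
  mod <- fit_secondary_modulation(nds, fit, 1e-9)
  tab <- mod$factors
  expect_true(tab$excluded[tab$binder_conc_M == 4e-6])   # ~100% bound
  expect_true(is.na(tab$factor[tab$binder_conc_M == 4e-6]))
  expect_false(tab$excluded[tab$binder_conc_M == 5e-7])
  expect_error(
    fit_secondary_modulation(nds[nds$binder_conc_M == 0, , drop = FALSE] |>
                               (\(d) {
                                 attr(d, "monomer_conc") <- 2e-6
                                 class(d) <- c("tht_dataset", "data.frame")
                                 d
                               })(), fit, 1e-9),
    "no inhibited")
})

test_that("parametric modulation mode recovers the generating K_I", {
  ds <- gen_tht_dataset(seed = 9, sigma = 0.02,
                        binder_concs = c(0, 2.5e-7, 5e-7, 1e-6),
                        K_I = 5e-7)
  nds <- normalize_tht(ds)
  fit <- fit_uninhibited(nds)
  mod <- fit_secondary_modulation(nds, fit, 83e-9, mode = "parametric")
  expect_lt(abs(mod$K_I / 5e-7 - 1), 0.3)
  expect_equal(unname(coef(mod)[["K_I"]]), mod$K_I)
})

test_that("potency concentration matches a dense grid scan and orders binders", {
  ds <- gen_tht_dataset(seed = 10, binder_concs = c(0, 2.5e-7, 5e-7, 1e-6))
  nds <- normalize_tht(ds)
  fit <- fit_uninhibited(nds)
  mod <- fit_secondary_modulation(nds, fit, 83e-9)

  expect_identical(potency_concentration(mod, increase = 0), 0)
  pc <- potency_concentration(mod, increase = 0.5)
  expect_gt(pc, 0)

  # bisection equals a dense grid scan of the half-time ratio to 1%
  th0 <- mod$t_half_uninhibited
  lg <- seq(log10(pc) - 0.5, log10(pc) + 0.5, length.out = 81)
  ratios <- vapply(lg, function(l) {
    p2 <- fit$params
    p2$m_total <- free_monomer(fit$m_total, 10^l, 83e-9)
    inh <- inhibitor_model(83e-9, 10^l,
                           k2_factors = mod$factors[!mod$factors$excluded,
                                                    c("binder_conc_M", "factor")] |>
                             stats::setNames(c("conc", "factor")))
    p2$k2 <- fit$params$k2 * modulation_factor(inh, 10^l)
    half_time(amytrap:::simulate_to_plateau(p2)) / th0
  }, numeric(1))
  grid_pc <- 10^lg[which(ratios >= 1.5)[1]]
  expect_lt(abs(pc / grid_pc - 1), 0.01)
})

test_that("stronger binders never have larger sequestration-only potency", {
  # direct monotonicity scan of the potency in binder affinity,
  # sequestration acting alone
  p <- aggregation_params(m_total = 2e-6)
  th0 <- half_time(amytrap:::simulate_to_plateau(p))
  pot_seq <- function(kd) {
    f <- function(lc) {
      p2 <- p; p2$m_total <- free_monomer(2e-6, 10^lc, kd)
      half_time(amytrap:::simulate_to_plateau(p2)) / th0 - 1.5
    }
    10^stats::uniroot(f, c(-9, -3))$root
  }
  pots <- vapply(c(10e-9, 83e-9, 755e-9), pot_seq, numeric(1))
  expect_true(all(diff(pots) > 0))
})
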