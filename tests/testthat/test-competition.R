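test_that("Kd <-> free-energy conversion reproduces the reference values", {
  th <- thermo_params()  # RT = 0.593 kcal/mol
  expect_equal(dg_from_kd(1e6, th), 0)  # 1 M standard state
  expect_equal(dg_from_kd(0.13, th), -9.40, tolerance = 0.001)
  expect_equal(dg_from_kd(0.03, th), -10.27, tolerance = 0.001)
  # exact round trip
  for (kd in c(1e-3, 0.13, 5, 1e4))
    expect_equal(kd_from_dg(dg_from_kd(kd, th), th), kd, tolerance = 1e-12)
  expect_error(dg_from_kd(-1), "positive")
})

test_that("lambda calibration reproduces the printed factor and is antisymmetric", {
  cal <- calibrate_lambda(-6.5, -9.5)
  expect_equal(cal$lambda, 157.436, tolerance = 1e-3)
  expect_equal(calibrate_lambda(-3, -3)$lambda, 1)
  expect_equal(calibrate_lambda(-2, -5)$lambda * calibrate_lambda(-5, -2)$lambda,
               1, tolerance = 1e-12)
})

test_that("PTM scale factor reproduces 0.021 and is monotone", {
  f <- ptm_scale_factor(-12.9, -7.6, calibrate_lambda(-6.5, -9.5))
  expect_equal(f, 0.021, tolerance = 0.03)
  expect_equal(1 / f, 48, tolerance = 0.05)  # ~48-fold enhancement
  expect_equal(ptm_scale_factor(-5, -5, calibrate_lambda(-4, -4)), 1)
  # stronger modified binding (more negative dG_mod) must shrink the factor
  fs <- sapply(c(-9, -10, -11), ptm_scale_factor, dg_wt = -7.6)
  expect_true(all(diff(fs) < 0))
})

test_that("calcium-state fractions follow the sequential two-site scheme", {
  cp <- ca_binding_params(kd_cef = 27, kd_pef = 250)
  expect_equal(ca_state_fractions(0, cp), c(apo = 1, half = 0, full = 0))
  lim <- ca_state_fractions(27, ca_binding_params(27, Inf))
  expect_equal(lim, c(apo = 0.5, half = 0.5, full = 0))
  # direct evaluation of the three Boltzmann terms
  w <- c(1, 100 / 27, 100^2 / (27 * 250))
  expect_equal(unname(ca_state_fractions(100, cp)), w / sum(w))
  expect_equal(sum(ca_state_fractions(3.7, cp)), 1)
})

test_that("equilibrium solver matches closed forms and conserves mass", {
  # no S100A1: two-component actin/PEVK binding has a quadratic solution
  tot <- system_totals(0, 1, 0.2, pca = 7)
  eq <- solve_equilibrium(tot, k_ap = 0.5)
  a <- 1; p <- 0.2; k <- 0.5
  pf_quad <- (-(a - p + k) + sqrt((a - p + k)^2 + 4 * k * p)) / 2
  expect_equal(eq$p, pf_quad, tolerance = 1e-9)
  expect_equal(eq$f_ap, (p - pf_quad) / p, tolerance = 1e-8)

  # S100A1 present but unable to bind: same baseline
  no_bind <- peptide_affinities(1, 1, 1, binding_enabled = c(FALSE, FALSE, FALSE))
  eq2 <- solve_equilibrium(system_totals(10, 1, 0.2, 7), affinities = no_bind,
                           k_ap = 0.5)
  expect_equal(eq2$f_ap, eq$f_ap, tolerance = 1e-10)

  # conservation and detailed balance on a generic state
  eq3 <- solve_equilibrium(system_totals(2, 1.5, 0.8, 5),
                           affinities = peptide_affinities(), k_ap = 0.3)
  s_tot <- eq3$s_apo + eq3$s_half + eq3$s_full + eq3$sp_apo + eq3$sp_half + eq3$sp_full
  expect_equal(s_tot, 2, tolerance = 1e-9)
  expect_equal(eq3$a + eq3$ap, 1.5, tolerance = 1e-9)
  expect_equal(eq3$p + eq3$ap + eq3$sp_apo + eq3$sp_half + eq3$sp_full, 0.8,
               tolerance = 1e-9)
  expect_equal(eq3$a * eq3$p / eq3$ap, 0.3, tolerance = 1e-9)
  expect_equal(eq3$s_apo * eq3$p / eq3$sp_apo, 0.52, tolerance = 1e-9)
  expect_equal(eq3$s_half * eq3$p / eq3$sp_half, 0.13, tolerance = 1e-9)
  expect_equal(eq3$s_full * eq3$p / eq3$sp_full, 0.03, tolerance = 1e-9)
})

test_that("solver agrees with the independent bisection oracle on random draws", {
  set.seed(101)
  for (i in 1:25) {
    kd <- 10^runif(3, -2, 1)
    k_ap <- 10^runif(1, -1, 1)
    s_t <- runif(1, 0, 20); a_t <- runif(1, 0.1, 5); p_t <- runif(1, 0.01, 2)
    pca <- runif(1, 3.5, 8)
    eq <- solve_equilibrium(system_totals(s_t, a_t, p_t, pca),
                            affinities = peptide_affinities(kd[1], kd[2], kd[3]),
                            k_ap = k_ap)
    oracle <- equilibrium_oracle_fap(s_t, a_t, p_t, pca, 27, 250,
                                     kd[1], kd[2], kd[3], k_ap)
    expect_equal(eq$f_ap, oracle, tolerance = 1e-7)
  }
})

test_that("dose-response is monotone in S100A1 and in the state affinities", {
  grid <- 10^seq(-2, 1.5, length.out = 12)
  dr <- dose_response(grid, a_total = 1, p_total = 0.2, pca = 4)
  expect_true(all(diff(dr$f_ap) <= 1e-12))
  expect_equal(dr$f_ap_norm[1], dr$f_ap[1] / dose_response(0, 1, 0.2, 4)$f_ap)

  # calcium-independent when all states share one Kd
  same <- peptide_affinities(0.2, 0.2, 0.2)
  d7 <- dose_response(grid, 1, 0.2, 7, affinities = same)
  d4 <- dose_response(grid, 1, 0.2, 4, affinities = same)
  expect_equal(d7$f_ap, d4$f_ap, tolerance = 1e-10)

  # elevated calcium displaces more PEVK when Ca states bind tighter
  d7b <- dose_response(grid, 1, 0.2, 7)
  d4b <- dose_response(grid, 1, 0.2, 4)
  expect_true(all(d4b$f_ap <= d7b$f_ap + 1e-12))

  # loosening any state's Kd can only raise f_AP
  base <- dose_response(grid, 1, 0.2, 4)$f_ap
  looser <- dose_response(grid, 1, 0.2, 4,
                          affinities = peptide_affinities(0.52, 1.3, 0.03))$f_ap
  expect_true(all(looser >= base - 1e-12))
})

test_that("noiseless synthetic curves are refitted to the generating constants", {
  truth <- peptide_affinities(0.52, 0.13, 0.03)
  data <- generate_binding_curves(truth, noise_sd = 0, seed = 50,
                                  pca_list = c(7, 5, 4))
  fit <- fit_affinities(data, a_total = 1, p_total = 0.2, n_boot = 0)
  expect_equal(fit$affinities$kd1, 0.52, tolerance = 1e-4)
  expect_equal(fit$affinities$kd2, 0.13, tolerance = 1e-4)
  expect_equal(fit$affinities$kd2p, 0.03, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  expect_length(fit$unidentifiable, 0)
})

test_that("a single low-calcium curve leaves the saturated-state Kd unidentifiable", {
  truth <- peptide_affinities(0.52, 0.13, 0.03)
  data <- generate_binding_curves(truth, noise_sd = 0, seed = 51, pca_list = 7)
  fit <- fit_affinities(data, a_total = 1, p_total = 0.2, n_boot = 0)
  expect_true("kd2p" %in% fit$unidentifiable)
  # the apo constant is still well determined
  expect_false("kd1" %in% fit$unidentifiable)
  # kd1 dominates at resting calcium; the faint half-saturated population
  # leaves a small compensation freedom, so recovery is near- but not exact
  expect_equal(fit$affinities$kd1, 0.52, tolerance = 0.05)
})

test_that("bootstrap confidence intervals cover the generating constants", {
  truth <- peptide_affinities(0.52, 0.13, 0.03)
  data <- generate_binding_curves(truth, noise_sd = 0.01, seed = 52,
                                  pca_list = c(7, 5, 4),
                                  s_grid = 10^seq(-2, 1.5, length.out = 8))
  fit <- fit_affinities(data, a_total = 1, p_total = 0.2, n_boot = 20, seed = 1)
  expect_equal(dim(fit$ci), c(3, 2))
  expect_true(all(fit$ci[, 1] < fit$ci[, 2]))
  expect_true(fit$ci["kd1", 1] < 0.52 && 0.52 < fit$ci["kd1", 2])
})

test_that("PTM-scaled curves lie at or below wild type and reduce to it at factor 1", {
  curves1 <- predict_ptm_curves(scale_factor = 1, pca_list = c(7, 4.5),
                                s_grid = 10^seq(-2, 1, length.out = 8))
  expect_equal(curves1$f_ap_mod, curves1$f_ap_wt, tolerance = 1e-12)
  curves <- predict_ptm_curves(scale_factor = 0.021, pca_list = c(7, 5, 4),
                               s_grid = 10^seq(-2, 1, length.out = 8))
  expect_true(all(curves$f_ap_mod <= curves$f_ap_wt + 1e-12))
  expect_equal(attr(curves, "scale_factor"), 0.021)
})
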