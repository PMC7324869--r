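test_that("reaction coordinate is the mass-weighted COM distance", {
  rc <- rc_definition(group1 = atom_selection(chain = "P", name = "CA"),
                      group2 = atom_selection(chain = "A", name = "CA"))
  s <- md_structure(rbind(
    make_ca_chain(rbind(c(0, 0, 0)), chain = "P")$atoms,
    make_ca_chain(rbind(c(3, 4, 0)), chain = "A")$atoms))
  expect_equal(reaction_coordinate(s, rc), 5)

  s2 <- md_structure(rbind(
    make_ca_chain(rbind(c(-1, 0, 0), c(1, 0, 0)), resno = 1:2, chain = "P")$atoms,
    make_ca_chain(rbind(c(10, 0, 0)), chain = "A")$atoms))
  expect_equal(reaction_coordinate(s2, rc), 10)

  # unequal masses: COM leans toward the heavy atom
  s3 <- s2
  s3$atoms$mass <- c(1, 3, 12)
  expect_equal(reaction_coordinate(s3, rc), 10 - (-1 * 1 + 1 * 3) / 4)
  expect_error(reaction_coordinate(s3, rc_definition(
    group1 = atom_selection(chain = "Z"))), "no atoms")
})

test_that("unbiased single-window WHAM reduces to exact histogramming", {
  samples <- c(rep(10.05, 120), rep(10.15, 60), rep(10.25, 20))
  w <- umbrella_window(center = 10, samples = samples, k = 0)
  prof <- wham(list(w), bin_width = 0.1, rt = 0.596)
  occupied <- !is.na(prof$G)
  g <- prof$G[occupied]
  expect_equal(g - min(g), -0.596 * log(c(120, 60, 20) / 120),
               tolerance = 1e-12)
})

test_that("WHAM recovers a quadratic potential from biased Boltzmann samples", {
  pot <- potential_spec("harmonic", k = 1, z0 = 20)
  w <- sample_umbrella_windows(pot, centers = seq(17.5, 22.5, 0.5), k = 18,
                               n_samples = 3000, seed = 14)
  prof <- wham(w)
  keep <- !is.na(prof$G) & abs(prof$z - 20) <= 2
  truth <- 0.5 * (prof$z[keep] - 20)^2
  dev <- prof$G[keep] - truth
  dev <- dev - mean(dev)  # profiles are defined up to an additive constant
  expect_lt(sqrt(mean(dev^2)), 0.1)
})

test_that("WHAM is invariant to window duplication and ordering", {
  pot <- potential_spec("harmonic", k = 2, z0 = 12)
  w <- sample_umbrella_windows(pot, centers = c(11, 12, 13), k = 10,
                               n_samples = 1500, seed = 4)
  base <- wham(w)
  perm <- wham(w[c(3, 1, 2)])
  expect_equal(perm$G, base$G, tolerance = 1e-10)
  # a window duplicated verbatim only rescales its weight: with a single
  # window the unbiased density (hence G) is unchanged
  one <- wham(w[2], grid = base$z)
  two <- wham(c(w[2], w[2]), grid = base$z)
  expect_equal(two$G, one$G, tolerance = 1e-8)
})

test_that("fixed-point WHAM agrees with a direct likelihood-optimisation route", {
  pot <- potential_spec("double_well", depth1 = 3, center1 = 12, width1 = 1,
                        depth2 = 1, center2 = 15, width2 = 1)
  w <- sample_umbrella_windows(pot, centers = seq(10, 17, 0.5), k = 12,
                               n_samples = 2000, seed = 6)
  prof <- wham(w)
  oracle <- wham_mle_oracle(w)
  expect_equal(prof$z, oracle$z)
  ok <- !is.na(prof$G) & !is.na(oracle$G)
  expect_true(sum(ok) > 50)
  expect_lt(max(abs(prof$G[ok] - oracle$G[ok])), 0.05)
})

test_that("non-convergence is reported with the residual", {
  w <- umbrella_window(10, rnorm(200, 10, 0.2), k = 18)
  w2 <- umbrella_window(11, rnorm(200, 11, 0.2), k = 18)
  expect_error(wham(list(w, w2), max_iter = 2), "did not converge")
})

test_that("block variance matches direct recomputation and handles edge cases", {
  expect_equal(block_variance(rep(3.2, 500), 100)$var_mean, 0)
  expect_equal(block_variance(rep(c(1, -1), 200), 2)$var_mean, 0)
  expect_error(block_variance(1:150, 200), "at least 2")

  # AR(1) series vs independent recomputation (trailing partial block dropped)
  set.seed(10)
  n <- 1050
  x <- numeric(n)
  for (i in 2:n) x[i] <- 0.8 * x[i - 1] + rnorm(1)
  bv <- block_variance(x, 200)
  means <- sapply(1:5, function(b) mean(x[((b - 1) * 200 + 1):(b * 200)]))
  expect_equal(bv$n_blocks, 5)
  expect_equal(bv$block_means, means)
  expect_equal(bv$var_mean, var(means) / 5)
})

test_that("mean-force error propagation is local, cumulative and closed-form", {
  mk_windows <- function(centers) lapply(centers, function(z)
    umbrella_window(z, rep(z, 400), k = 18))
  centers <- seq(10, 14, 0.5)
  w <- mk_windows(centers)
  fake_block <- function(v) structure(list(var_mean = v), class = "block_average")

  # all-zero variances
  eps0 <- propagate_pmf_error(w, lapply(centers, function(z) fake_block(0)),
                              grid = seq(10, 14, 0.1))
  expect_equal(eps0, rep(0, 41))

  # single noisy window: zero before it, positive at and beyond
  blocks <- lapply(seq_along(centers), function(i) fake_block(ifelse(i == 5, 1e-4, 0)))
  eps1 <- propagate_pmf_error(w, blocks, grid = centers)
  expect_equal(eps1[1:4], rep(0, 4))
  expect_true(all(eps1[5:9] > 0))

  # equal variances: trapezoid closed form (kappa dz sigma)^2 (m - 1.5)
  sig2 <- 4e-5
  blocks_eq <- lapply(centers, function(z) fake_block(sig2))
  eps <- propagate_pmf_error(w, blocks_eq, grid = centers)
  m <- 2:9
  expect_equal(eps[2:9], sqrt((18 * 0.5)^2 * sig2 * (m - 1.5)), tolerance = 1e-12)
  expect_true(all(diff(eps) >= 0))
})

test_that("bootstrap error is deterministic under seed and zero for constant data", {
  wconst <- lapply(c(10, 10.5), function(z)
    umbrella_window(z, rep(z, 300), k = 18))
  # point-mass windows leave intentionally empty bins between them
  prof <- suppressWarnings(bootstrap_error(wconst, n_trials = 5, seed = 3))
  expect_equal(prof$err[!is.na(prof$err)],
               rep(0, sum(!is.na(prof$err))))

  pot <- potential_spec("harmonic", k = 2, z0 = 12)
  w <- sample_umbrella_windows(pot, centers = c(11.5, 12, 12.5), k = 10,
                               n_samples = 800, seed = 5)
  e1 <- suppressWarnings(bootstrap_error(w, n_trials = 8, seed = 17))
  e2 <- suppressWarnings(bootstrap_error(w, n_trials = 8, seed = 17))
  expect_identical(e1$err, e2$err)
})

test_that("bootstrap error tracks the analytic histogram error on unbiased data", {
  # single unbiased window: per-bin G error ~ RT sqrt((1-p)/(n p))
  set.seed(30)
  n <- 4000
  samples <- rnorm(n, 20, 0.5)
  w <- umbrella_window(20, samples, k = 0)
  prof <- bootstrap_error(list(w), n_trials = 30, seed = 12, bin_width = 0.2)
  counts <- table(cut(samples, breaks = c(prof$z - 0.1, max(prof$z) + 0.1)))
  p <- as.numeric(counts) / n
  good <- p > 0.02
  analytic <- 0.596 * sqrt((1 - p) / (n * p))
  ratio <- prof$err[good] / analytic[good]
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("binding free energy extraction reads the well against the plateau", {
  z <- seq(10, 30, 0.1)
  flat <- structure(list(z = z, G = rep(2, length(z)),
                         err = rep(NA_real_, length(z)), rt = 0.596),
                    class = "pmf_profile")
  expect_equal(binding_dg(flat, c(11, 15), c(25, 30))$dg, 0)

  well <- structure(list(z = z, G = 9.5 - 9.5 * exp(-(z - 14)^2 / 2),
                         err = rep(0.1, length(z)), rt = 0.596),
                    class = "pmf_profile")
  bd <- binding_dg(well, c(12, 16), c(27, 30))
  expect_equal(bd$dg, -9.5, tolerance = 1e-6)
  expect_equal(bd$z_min, 14, tolerance = 0.05)
  expect_equal(bd$err, sqrt(0.1^2 + 0.1^2), tolerance = 1e-9)

  # double well: global-min lookup oracle
  G2 <- 5 - 5 * exp(-(z - 13)^2 / 2) - 3 * exp(-(z - 18)^2 / 2)
  dbl <- structure(list(z = z, G = G2 - min(G2),
                        err = rep(NA_real_, length(z)), rt = 0.596),
                   class = "pmf_profile")
  bd2 <- binding_dg(dbl, c(10, 20), c(26, 30))
  tail_mean <- mean(dbl$G[z >= 26])
  expect_equal(bd2$dg, min(dbl$G) - tail_mean)
  expect_error(binding_dg(dbl, c(5, 8), c(26, 30)), "outside")
})
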