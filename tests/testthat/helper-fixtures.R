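# Fixtures built in code: minimal structures, hand-rolled PDB text and
# independent oracle implementations used to cross-check the package.

# data.frame of atoms -> md_structure, filling routine columns
make_structure <- function(name, resno, x, y, z, chain = "A",
                           element = substr(name, 1, 1), resid = "ALA",
                           mass = 12) {
  md_structure(data.frame(name = name, element = element,
                          resno = as.integer(resno), resid = resid,
                          chain = chain, x = x, y = y, z = z, mass = mass,
                          stringsAsFactors = FALSE))
}

# CA-only chain: one CA per residue at given coordinates
make_ca_chain <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A") {
  make_structure(name = rep("CA", nrow(xyz)), resno = resno,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = chain)
}

# Fixed-width PDB ATOM record
pdb_atom_line <- function(eleno, name, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, element = substr(name, 1, 1),
                          altloc = " ") {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          eleno, name, altloc, resid, chain, resno, x, y, z, occ, b, element)
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Independent WHAM route: direct minimisation of the profiled negative
# log-likelihood over window free energies (BFGS), no fixed-point iteration.
wham_mle_oracle <- function(windows, bin_width = 0.1, rt = 0.596,
                            bias_convention = "half") {
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "center"))]
  samples <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(samples) / bin_width) * bin_width
  hi <- ceiling(max(samples) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  pref <- if (bias_convention == "half") 0.5 else 1
  counts <- vapply(windows, function(w)
    tabulate(findInterval(w$samples, edges, rightmost.closed = TRUE),
             nbins = length(centers)), numeric(length(centers)))
  counts <- matrix(counts, nrow = length(centers))
  num <- rowSums(counts)
  N <- colSums(counts)
  B <- vapply(windows, function(w)
    exp(-pref * w$k * (centers - w$center)^2 / rt), numeric(length(centers)))
  nll <- function(f_rest) {
    f <- c(0, f_rest)
    denom <- as.numeric(B %*% (N * exp(f / rt)))
    occ <- num > 0
    -(sum(num[occ] * log(num[occ] / denom[occ])) + sum(N * f) / rt)
  }
  opt <- optim(rep(0, length(windows) - 1), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  f <- c(0, opt$par)
  P <- num / as.numeric(B %*% (N * exp(f / rt)))
  G <- ifelse(num > 0, -rt * log(P), NA_real_)
  list(z = centers, G = G - min(G, na.rm = TRUE), f = f)
}

# Independent equilibrium oracle: bisection on the PEVK conservation
# residual, with its own mass-action algebra.
equilibrium_oracle_fap <- function(s_total, a_total, p_total, pca,
                                   kd_cef, kd_pef, kd1, kd2, kd2p, k_ap,
                                   enabled = c(TRUE, TRUE, TRUE)) {
  ca <- 10^(6 - pca)
  w <- c(1, ca / kd_cef, ca^2 / (kd_cef * kd_pef))
  f <- w / sum(w)
  inv <- sum(ifelse(enabled, f / c(kd1, kd2, kd2p), 0))
  residual <- function(pf) {
    af <- a_total / (1 + pf / k_ap)
    sf <- s_total / (1 + inv * pf)
    pf + af * pf / k_ap + sf * inv * pf - p_total
  }
  lo <- 0; hi <- p_total
  if (residual(hi) <= 0) {
    pf <- hi
  } else {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (residual(mid) > 0) hi <- mid else lo <- mid
    }
    pf <- (lo + hi) / 2
  }
  af <- a_total / (1 + pf / k_ap)
  (af * pf / k_ap) / p_total
}

# Shared heavy umbrella fixture (double well, full window layout).
make_wham_fixture <- function(seed = 1, n_samples = 10000) {
  pot <- potential_spec("double_well")
  windows <- sample_umbrella_windows(pot, n_samples = n_samples, seed = seed)
  profile <- wham(windows)
  truth <- potential_energy(pot, profile$z)
  list(potential = pot, windows = windows, profile = profile,
       truth = truth - min(truth))
}
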