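## 1-D weighted histogram analysis method (WHAM) for umbrella-sampling data,
## with two error estimators: Monte-Carlo bootstrap over window samples and
## block-averaging propagation through the mean-force (umbrella integration)
## view of the stratified free-energy profile.

#' Reaction-coordinate definition: COM-COM distance of two atom groups
#'
#' The dissociation coordinate used here is the distance between the
#' mass-weighted centre of mass of the peptide C-alpha atoms and that of
#' the C-alpha atoms lining the binding cleft (H3 C-terminus K30-T39 plus
#' H4 N-terminus E73-A84 by default).
#'
#' @param group1 `atom_selection` for the first group (default: C-alpha of
#'   chain P, the peptide).
#' @param group2 `atom_selection` for the second group (default: C-alpha of
#'   residues 30-39 and 73-84 on chain A).
#' @return object of class `rc_definition`.
#' @export
rc_definition <- function(group1 = atom_selection(chain = "P", name = "CA"),
                          group2 = atom_selection(chain = "A",
                                                  resno = c(30:39, 73:84),
                                                  name = "CA")) {
  structure(list(group1 = group1, group2 = group2), class = "rc_definition")
}

#' Evaluate a COM-COM reaction coordinate on one frame
#'
#' @param structure `md_structure`.
#' @param rc `rc_definition`.
#' @return distance between the two mass-weighted centres of mass, Angstrom.
#' @export
reaction_coordinate <- function(structure, rc = rc_definition()) {
  com <- function(sel) {
    idx <- select_atoms(structure, sel)
    if (!length(idx)) stop("reaction-coordinate group resolves to no atoms")
    m <- structure$atoms$mass[idx]
    colSums(coords(structure)[idx, , drop = FALSE] * m) / sum(m)
  }
  sqrt(sum((com(rc$group1) - com(rc$group2))^2))
}

#' Construct an umbrella window
#'
#' @param center restraint centre z_i, Angstrom.
#' @param samples reaction-coordinate samples collected under the bias,
#'   Angstrom.
#' @param k harmonic force constant, kcal/mol/Angstrom^2 (default 18).
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, samples, k = 18) {
  samples <- as.numeric(samples)
  if (!length(samples) || !all(is.finite(samples)))
    stop("window samples must be non-empty and finite")
  if (k < 0) stop("force constant must be >= 0")
  structure(list(center = center, k = k, samples = samples),
            class = "umbrella_window")
}

## Bias energy of window w at positions z.  The "half" convention,
## U = (K/2)(z - z0)^2, matches the NAMD colvars restraint; "full" uses
## U = K(z - z0)^2.
bias_energy <- function(w, z, bias_convention = "half") {
  pref <- switch(bias_convention, half = 0.5, full = 1,
                 stop("bias_convention must be 'half' or 'full'"))
  pref * w$k * (z - w$center)^2
}

make_grid <- function(samples, bin_width) {
  lo <- floor(min(samples) / bin_width) * bin_width
  hi <- ceiling(max(samples) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  list(edges = edges, centers = edges[-length(edges)] + bin_width / 2)
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Self-consistent solution of the weighted histogram equations: window
#' free energies f_i are iterated to a fixed point (convergence on
#' max |Delta f_i| < `tol`), the unbiased probability density follows, and
#' G(z) = -RT ln rho(z) is anchored so its minimum is zero.  Bins never
#' visited by any window are returned as `NA`.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param bin_width histogram bin width, Angstrom (default 0.1).
#' @param rt thermal energy RT, kcal/mol (default 0.596, i.e. 300 K).
#' @param tol convergence tolerance on the window free energies, kcal/mol.
#' @param max_iter iteration cap; non-convergence raises an error reporting
#'   the residual.
#' @param bias_convention `"half"` for U = (K/2)(z-z0)^2 (default) or
#'   `"full"` for U = K(z-z0)^2.
#' @param grid optional fixed bin-centre grid (used by the bootstrap so all
#'   trials share bins).
#' @return object of class `pmf_profile`: list with `z` (bin centres), `G`
#'   (kcal/mol, min-anchored), `err` (NA until an error estimator fills it),
#'   `rt`, `f` (window free energies), `n_iter`, `converged`.
#' @export
wham <- function(windows, bin_width = 0.1, rt = RT_300K, tol = 1e-10,
                 max_iter = 1e5, bias_convention = "half", grid = NULL) {
  if (!length(windows)) stop("no umbrella windows supplied")
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "center"))]
  all_samples <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(grid)) grid <- make_grid(all_samples, bin_width)$centers
  n_bins <- length(grid)
  n_win <- length(windows)
  half_bw <- if (n_bins > 1) (grid[2] - grid[1]) / 2 else bin_width / 2
  edges <- c(grid - half_bw, grid[n_bins] + half_bw)

  counts <- vapply(windows, function(w) {
    s <- w$samples[w$samples >= edges[1] & w$samples <= edges[n_bins + 1]]
    if (!length(s)) return(rep(0, n_bins))
    tabulate(pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L),
                  n_bins), nbins = n_bins)
  }, numeric(n_bins))
  counts <- matrix(counts, nrow = n_bins)
  N <- colSums(counts)
  if (any(N == 0)) stop("window with no samples on the histogram grid")
  num <- rowSums(counts)

  ## warn on gaps between adjacent windows' occupied ranges
  occ <- apply(counts > 0, 2, which)
  if (n_win > 1) for (i in seq_len(n_win - 1)) {
    if (min(occ[[i + 1]]) > max(occ[[i]]) + 1)
      warning(sprintf("histogram gap between windows at %.2f and %.2f Angstrom",
                      windows[[i]]$center, windows[[i + 1]]$center))
  }

  B <- vapply(windows, function(w) exp(-bias_energy(w, grid, bias_convention) / rt),
              numeric(n_bins))
  B <- matrix(B, nrow = n_bins)

  f <- numeric(n_win)
  resid <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gvec <- N * exp(f / rt)
    denom <- as.numeric(B %*% gvec)
    P <- num / denom
    S <- as.numeric(crossprod(B, P))
    f_new <- -rt * log(S)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                 as.integer(max_iter), resid))
  gvec <- N * exp(f / rt)
  P <- num / as.numeric(B %*% gvec)
  G <- ifelse(num > 0, -rt * log(P), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  structure(list(z = grid, G = G, err = rep(NA_real_, n_bins), rt = rt,
                 f = f, n_iter = iter, converged = TRUE,
                 bias_convention = bias_convention),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins over [%.2f, %.2f] Angstrom, RT = %.3f kcal/mol (%d WHAM iterations)\n",
              length(x$z), min(x$z), max(x$z), x$rt, x$n_iter))
  invisible(x)
}

#' Monte-Carlo bootstrap error of a WHAM profile
#'
#' Each trial resamples every window's reaction-coordinate samples with
#' replacement, re-solves WHAM on the same histogram grid, anchors the
#' trial profile, and the per-bin standard deviation over trials is
#' reported.  30 trials is the conventional setting.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param n_trials number of bootstrap trials (default 30).
#' @param seed RNG seed (set for reproducibility when not NULL).
#' @param anchor `"min"` (default) anchors each trial at its minimum;
#'   `"tail"` anchors on the unbound plateau (the mean over the occupied
#'   bins in the last 2 Angstrom of the sampled range, which is robust to
#'   shot noise in the extreme bins).
#' @param ... further arguments passed to [wham()].
#' @return `pmf_profile` as from [wham()] on the original data, with `err`
#'   filled with the per-bin bootstrap standard deviation (kcal/mol).
#' @export
bootstrap_error <- function(windows, n_trials = 30, seed = NULL,
                            anchor = c("min", "tail"), ...) {
  anchor <- match.arg(anchor)
  if (!is.null(seed)) set.seed(seed)
  base <- wham(windows, ...)
  anchor_fun <- function(G) {
    ref <- if (anchor == "min") {
      min(G, na.rm = TRUE)
    } else {
      occ <- which(!is.na(G))
      plateau <- occ[base$z[occ] >= max(base$z[occ]) - 2]
      mean(G[plateau])
    }
    G - ref
  }
  trials <- vapply(seq_len(n_trials), function(t) {
    wb <- lapply(windows, function(w) {
      w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
      w
    })
    anchor_fun(wham(wb, grid = base$z, ...)$G)
  }, numeric(length(base$z)))
  base$err <- apply(trials, 1, function(g)
    if (anyNA(g)) NA_real_ else sd(g))
  base$n_bootstrap <- n_trials
  base
}

#' Block-averaging variance of a window-mean reaction coordinate
#'
#' Splits a correlated time series into consecutive blocks of `block_size`
#' samples (a trailing partial block is dropped), and estimates the
#' variance of the overall mean as the variance of the block means divided
#' by the number of blocks.
#'
#' @param samples numeric time series.
#' @param block_size samples per block (default 200).
#' @return object of class `block_average`: `block_size`, `n_blocks`,
#'   `block_means`, `var_block_means`, and `var_mean` = sigma^2(mean).
#' @export
block_variance <- function(samples, block_size = 200) {
  n_blocks <- floor(length(samples) / block_size)
  if (n_blocks < 2)
    stop("need at least 2 complete blocks (", length(samples), " samples, block size ",
         block_size, ")")
  used <- samples[seq_len(n_blocks * block_size)]
  means <- colMeans(matrix(used, nrow = block_size))
  vb <- var(means)
  structure(list(block_size = block_size, n_blocks = n_blocks,
                 block_means = means, var_block_means = vb,
                 var_mean = vb / n_blocks),
            class = "block_average")
}

#' Propagated PMF error from per-window mean uncertainties
#'
#' Mean-force error propagation: in window i the mean restraint force is
#' kappa (z_i - <x>_i) (kappa = K for the half-convention bias
#' U = (K/2)(z-z0)^2, 2K otherwise), so the uncertainty of the window mean,
#' sigma(<x>_i) from [block_variance()], maps to a mean-force uncertainty
#' kappa sigma.  The free-energy difference from the reference window to
#' window m is the trapezoid integral of the mean force over the window
#' centres, and its variance is the quadrature sum of the independent
#' window contributions with the trapezoid weights.  The result is monotone
#' non-decreasing away from the reference end.
#'
#' @param windows list of [umbrella_window()] objects (sorted internally by
#'   centre).
#' @param block_results list of [block_variance()] results, parallel to
#'   `windows`.
#' @param grid reaction-coordinate positions at which to report the error.
#' @param bias_convention as in [wham()].
#' @param reference `"first"` (lowest centre, default) or `"last"`.
#' @return numeric vector of PMF standard errors (kcal/mol) on `grid`,
#'   linearly interpolated between window centres.
#' @export
propagate_pmf_error <- function(windows, block_results, grid,
                                bias_convention = "half",
                                reference = c("first", "last")) {
  reference <- match.arg(reference)
  if (length(windows) != length(block_results))
    stop("need one block_variance result per window")
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  windows <- windows[ord]; block_results <- block_results[ord]
  z <- vapply(windows, `[[`, numeric(1), "center")
  kappa <- vapply(windows, `[[`, numeric(1), "k") *
    switch(bias_convention, half = 1, full = 2)
  sig2 <- vapply(block_results, `[[`, numeric(1), "var_mean")
  m <- length(z)
  if (reference == "last") {
    z <- rev(-z); kappa <- rev(kappa); sig2 <- rev(sig2)
  }
  var_at <- numeric(m)  # variance of G(z_j) - G(z_ref)
  for (j in seq_len(m)) {
    if (j == 1) next
    cvec <- numeric(j)
    cvec[1] <- (z[2] - z[1]) / 2
    cvec[j] <- (z[j] - z[j - 1]) / 2
    if (j > 2) {
      i <- 2:(j - 1)
      cvec[i] <- (z[i + 1] - z[i - 1]) / 2
    }
    var_at[j] <- sum(cvec^2 * kappa[seq_len(j)]^2 * sig2[seq_len(j)])
  }
  eps <- sqrt(var_at)
  zc <- if (reference == "last") rev(-z) else z
  if (reference == "last") eps <- rev(eps)
  yl <- if (reference == "first") 0 else eps[1]
  yr <- if (reference == "last") 0 else eps[m]
  stats::approx(zc, eps, xout = grid, yleft = yl, yright = yr)$y
}

#' Binding free energy from a PMF profile
#'
#' Delta G = G at the bound-state minimum (searched within `bound_region`)
#' minus the mean G over the unbound plateau `unbound_region`.  Negative
#' values mean favourable binding.  If the profile carries per-bin errors,
#' they are propagated in quadrature from the two locations.
#'
#' @param pmf `pmf_profile`.
#' @param bound_region length-2 numeric, Angstrom range containing the
#'   bound well.
#' @param unbound_region length-2 numeric range over the dissociated
#'   plateau.
#' @return list with `dg` (kcal/mol), `err`, and `z_min` (location of the
#'   bound minimum).
#' @export
binding_dg <- function(pmf, bound_region, unbound_region) {
  inside <- function(region) {
    if (region[1] < min(pmf$z) - 1e-9 || region[2] > max(pmf$z) + 1e-9)
      stop("region [", region[1], ", ", region[2], "] outside the PMF grid")
    which(pmf$z >= region[1] & pmf$z <= region[2] & !is.na(pmf$G))
  }
  bi <- inside(bound_region); ui <- inside(unbound_region)
  if (!length(bi) || !length(ui)) stop("region contains no occupied bins")
  imin <- bi[which.min(pmf$G[bi])]
  dg <- pmf$G[imin] - mean(pmf$G[ui])
  err <- if (all(is.na(pmf$err))) NA_real_ else
    sqrt(pmf$err[imin]^2 + mean(pmf$err[ui], na.rm = TRUE)^2)
  list(dg = dg, err = err, z_min = pmf$z[imin])
}
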