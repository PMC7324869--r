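## Seeded synthetic-data generators: Metropolis umbrella sampling from known
## 1-D potentials, ideal backbone builders, noisy dose-response curves and
## per-residue energy tables.  Every generator is a pure function of its
## seed and carries its ground truth as an attribute so tests can close the
## loop.

#' Specify a 1-D potential for synthetic umbrella sampling
#'
#' Forms: `"harmonic"` (params `k`, `z0`); `"double_well"` (two Gaussian
#' wells on a flat plateau: params `depth1`, `center1`, `width1`, `depth2`,
#' `center2`, `width2`); `"tabulated"` (params `z`, `u`, interpolated by a
#' natural spline).  The default double well places a 9.5 kcal/mol bound
#' well at 14 Angstrom and a 2 kcal/mol intermediate at 20 Angstrom, so its
#' well depth matches the scale of a peptide-dissociation profile.
#'
#' @param form one of `"harmonic"`, `"double_well"`, `"tabulated"`.
#' @param ... form parameters overriding the defaults above.
#' @return object of class `potential_spec`.
#' @export
potential_spec <- function(form = c("double_well", "harmonic", "tabulated"),
                           ...) {
  form <- match.arg(form)
  defaults <- switch(form,
    harmonic = list(k = 2, z0 = 20),
    double_well = list(depth1 = 9.5, center1 = 14, width1 = 1.5,
                       depth2 = 2, center2 = 20, width2 = 1.5),
    tabulated = list(z = NULL, u = NULL))
  params <- utils::modifyList(defaults, list(...))
  if (form == "tabulated" && (is.null(params$z) || is.null(params$u)))
    stop("tabulated potential needs z and u vectors")
  structure(list(form = form, params = params), class = "potential_spec")
}

#' Evaluate a synthetic potential
#' @param spec [potential_spec()].
#' @param z positions, Angstrom.
#' @return potential energy, kcal/mol.
#' @export
potential_energy <- function(spec, z) {
  p <- spec$params
  u <- switch(spec$form,
    harmonic = 0.5 * p$k * (z - p$z0)^2,
    double_well = -p$depth1 * exp(-(z - p$center1)^2 / (2 * p$width1^2)) -
                  p$depth2 * exp(-(z - p$center2)^2 / (2 * p$width2^2)),
    tabulated = stats::spline(p$z, p$u, xout = z)$y)
  if (any(!is.finite(u))) stop("potential not finite on the requested interval")
  u
}

#' Default umbrella window layout
#'
#' Centres from 9.5 to 33.5 Angstrom at 0.5 Angstrom spacing: 49 windows.
#'
#' @param from,to,by layout limits and spacing, Angstrom.
#' @return numeric vector of window centres.
#' @export
window_layout <- function(from = 9.5, to = 33.5, by = 0.5) seq(from, to, by = by)

#' Draw umbrella-window samples from a known potential
#'
#' Per window, a seeded Metropolis random walk samples the biased Boltzmann
#' density exp(-(U(z) + U_bias(z))/RT).  Only equilibrium statistics matter
#' for WHAM, so Metropolis (exactly seedable) is used rather than dynamics.
#'
#' @param potential [potential_spec()].
#' @param centers window centres (default [window_layout()]).
#' @param k bias force constant, kcal/mol/Angstrom^2 (default 18).
#' @param n_samples retained samples per window.
#' @param seed RNG seed (required).
#' @param step Metropolis proposal standard deviation, Angstrom.  The
#'   default is about 2.4 times the standard deviation of the biased
#'   density under the default force constant, the classic efficiency
#'   optimum for a 1-D random walk.
#' @param stride record every `stride`-th move so retained samples are
#'   approximately decorrelated (the analogue of a frame-saving stride).
#' @param burnin discarded initial moves per window.
#' @param rt thermal energy, kcal/mol (default 0.596, 300 K).
#' @param bias_convention `"half"` (default) or `"full"`, as in [wham()].
#' @return list of [umbrella_window()] objects with attribute
#'   `ground_truth` recording the potential, RT and sampler settings.
#' @export
sample_umbrella_windows <- function(potential, centers = window_layout(),
                                    k = 18, n_samples = 2000, seed,
                                    step = 0.45, stride = 8, burnin = 500,
                                    rt = RT_300K, bias_convention = "half") {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  pref <- if (bias_convention == "half") 0.5 else 1
  windows <- lapply(centers, function(z0) {
    total_u <- function(z) potential_energy(potential, z) + pref * k * (z - z0)^2
    n_tot <- burnin + n_samples * stride
    prop <- rnorm(n_tot, sd = step)
    uacc <- runif(n_tot)
    out <- numeric(n_tot)
    z <- z0
    uz <- total_u(z)
    for (i in seq_len(n_tot)) {
      zn <- z + prop[i]
      un <- total_u(zn)
      if (uacc[i] < exp((uz - un) / rt)) {
        z <- zn; uz <- un
      }
      out[i] <- z
    }
    umbrella_window(center = z0,
                    samples = out[seq(burnin + stride, n_tot, by = stride)],
                    k = k)
  })
  attr(windows, "ground_truth") <- list(potential = potential, rt = rt,
                                        k = k, centers = centers, seed = seed,
                                        step = step, stride = stride,
                                        burnin = burnin,
                                        n_samples = n_samples,
                                        bias_convention = bias_convention)
  windows
}

## --- ideal backbone builder -------------------------------------------------

## Place atom d from a, b, c with bond length |c-d|, angle b-c-d (deg) and
## dihedral a-b-c-d (deg); standard internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; chi <- dihedral * pi / 180
  bc <- normalize(c - b)
  n <- normalize(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  c + bond * (-bc * cos(ang) + m * cos(chi) * sin(ang) + n * sin(chi) * sin(ang))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

bb_geom <- list(b_nca = 1.458, b_cac = 1.525, b_cn = 1.329, b_co = 1.231,
                b_nh = 1.01, ang_ncac = 111.2, ang_cacn = 116.2,
                ang_cnca = 121.7, ang_caco = 120.8, omega = 180)

#' Build an ideal polyalanine backbone at fixed dihedrals
#'
#' Standard bond lengths and angles, uniform (phi, psi) and trans peptide
#' bonds.  Atoms per residue: N, H (from residue 2), CA, C, O.  The
#' canonical alpha-helix is (phi, psi) = (-57, -47); a fully extended chain
#' is (180, 180).
#'
#' @param n_residues chain length (2 to 1000).
#' @param phi,psi backbone dihedrals, degrees.
#' @param chain chain identifier.
#' @return `md_structure`.
#' @export
build_helix_coords <- function(n_residues, phi = -57, psi = -47, chain = "A") {
  if (n_residues < 2 || n_residues > 1000)
    stop("n_residues must be between 2 and 1000")
  if (!is.finite(phi) || !is.finite(psi)) stop("dihedrals must be finite")
  g <- bb_geom
  N <- CA <- C <- O <- matrix(NA_real_, n_residues, 3)
  H <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_nca, 0, 0)
  ang <- g$ang_ncac * pi / 180
  C[1, ] <- CA[1, ] + g$b_cac * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_residues) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_cn, g$ang_cacn, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_nca, g$ang_cnca, g$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_cac, g$ang_ncac, phi)
    H[i, ] <- N[i, ] + g$b_nh *
      normalize(normalize(N[i, ] - C[i - 1, ]) + normalize(N[i, ] - CA[i, ]))
  }
  for (i in seq_len(n_residues)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_co, g$ang_caco, psi + 180)
  }
  rows <- list()
  masses <- c(N = 14.007, H = 1.008, C = 12.011, O = 15.999)
  for (i in seq_len(n_residues)) {
    add <- function(name, element, xyz)
      data.frame(name = name, element = element, resno = i, resid = "ALA",
                 chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
                 mass = masses[[element]], stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- add("N", "N", N[i, ])
    if (i > 1) rows[[length(rows) + 1]] <- add("H", "H", H[i, ])
    rows[[length(rows) + 1]] <- add("CA", "C", CA[i, ])
    rows[[length(rows) + 1]] <- add("C", "C", C[i, ])
    rows[[length(rows) + 1]] <- add("O", "O", O[i, ])
  }
  md_structure(do.call(rbind, rows))
}

#' Generate noisy dose-response binding curves with known ground truth
#'
#' Solves the competition model on a concentration grid at each pCa, adds
#' Gaussian noise to the bound fraction and clips to \[0, 1\].  The
#' generating parameters are attached as the `ground_truth` attribute.
#'
#' @param affinities true [peptide_affinities()].
#' @param s_grid total S100A1 grid, uM.
#' @param a_total,p_total fixed totals, uM.
#' @param pca_list pCa values, one curve each.
#' @param noise_sd Gaussian noise on f_AP (>= 0).
#' @param seed RNG seed (required).
#' @param ca_params [ca_binding_params()].
#' @param k_ap actin-PEVK dissociation constant, uM.
#' @return data.frame with columns `s100_total_uM`, `f_ap`, `pca` and
#'   attribute `ground_truth`.
#' @export
generate_binding_curves <- function(affinities = peptide_affinities(),
                                    s_grid = 10^seq(-2, 1.5, length.out = 12),
                                    a_total = 1, p_total = 0.2,
                                    pca_list = c(7, 5, 4), noise_sd = 0.02,
                                    seed,
                                    ca_params = ca_binding_params(),
                                    k_ap = 0.5) {
  if (missing(seed)) stop("a seed is required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  curves <- do.call(rbind, lapply(pca_list, function(pca)
    dose_response(s_grid, a_total, p_total, pca, ca_params, affinities, k_ap)))
  f <- curves$f_ap
  if (noise_sd > 0) f <- pmin(pmax(f + rnorm(length(f), sd = noise_sd), 0), 1)
  out <- data.frame(s100_total_uM = curves$s100_total_uM, f_ap = f,
                    pca = curves$pca)
  attr(out, "ground_truth") <- list(affinities = affinities,
                                    a_total = a_total, p_total = p_total,
                                    pca_list = pca_list, noise_sd = noise_sd,
                                    seed = seed, k_ap = k_ap,
                                    ca_params = ca_params,
                                    f_ap_true = curves$f_ap)
  out
}

#' Generate dimer and monomer energy tables with known interaction offsets
#'
#' Monomer tables hold baseline per-residue energies plus noise; the dimer
#' table adds a specified per-residue interaction offset (split evenly over
#' the three energy terms).  The offsets are the ground-truth values that
#' [per_residue_interaction_delta()] should recover.
#'
#' @param n_frames frames per table.
#' @param residues_a,residues_b residue numbers of the two monomers
#'   (disjoint).
#' @param offsets named numeric vector of per-residue interaction energies
#'   (kcal/mol), names = residue numbers; unnamed residues get 0.
#' @param noise_sd Gaussian noise per term, kcal/mol.
#' @param seed RNG seed (required).
#' @return list with `dimer`, `monomers` (list of two [energy_table()]s)
#'   and attribute `ground_truth` (the full offset vector).
#' @export
generate_energy_tables <- function(n_frames, residues_a, residues_b,
                                   offsets = numeric(0), noise_sd = 0,
                                   seed) {
  if (missing(seed)) stop("a seed is required")
  if (length(intersect(residues_a, residues_b)))
    stop("monomer residue sets must be disjoint")
  set.seed(seed)
  all_res <- c(residues_a, residues_b)
  off <- setNames(rep(0, length(all_res)), all_res)
  off[names(offsets)] <- offsets
  base <- c(e_eel = -5, e_vdw = -3, e_solv = 2)
  make <- function(residues, with_offset) {
    grid <- expand.grid(frame = seq_len(n_frames), resno = residues)
    for (term in names(base)) {
      v <- base[[term]] + rnorm(nrow(grid), sd = noise_sd)
      if (with_offset) v <- v + off[as.character(grid$resno)] / 3
      grid[[term]] <- v
    }
    grid
  }
  monomers <- list(energy_table(make(residues_a, FALSE), "monomerA"),
                   energy_table(make(residues_b, FALSE), "monomerB"))
  dimer <- energy_table(make(all_res, TRUE), "dimer")
  out <- list(dimer = dimer, monomers = monomers)
  attr(out, "ground_truth") <- off
  out
}

#' Write umbrella windows to per-window series files plus metadata
#'
#' Emits one plain-text sample file per window, a `windows.csv` metadata
#' table (window_id, center, force_constant, path) and a
#' `ground_truth.json` sidecar when the windows carry one.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param dir output directory (created if needed).
#' @return path to the metadata CSV, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    path <- file.path(dir, sprintf("window_%03d.dat", i))
    writeLines(format(w$samples, digits = 10, trim = TRUE, scientific = FALSE),
               path)
    data.frame(window_id = i, center = w$center, force_constant = w$k,
               path = basename(path))
  }))
  meta_path <- file.path(dir, "windows.csv")
  write.csv(meta, meta_path, row.names = FALSE)
  gt <- attr(windows, "ground_truth")
  if (!is.null(gt)) {
    gt$potential <- unclass(gt$potential)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(meta_path)
}

#' Read umbrella windows written by [write_umbrella_windows()]
#'
#' @param meta_path path to the `windows.csv` metadata file.
#' @return list of [umbrella_window()] objects.
#' @export
read_umbrella_windows <- function(meta_path) {
  meta <- read.csv(meta_path)
  dir <- dirname(meta_path)
  lapply(seq_len(nrow(meta)), function(i)
    umbrella_window(center = meta$center[i],
                    samples = read_window_series(file.path(dir, meta$path[i])),
                    k = meta$force_constant[i]))
}
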