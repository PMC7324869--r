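## Shrake-Rupley solvent-accessible surface area.  No R package in the
## dependency set evaluates SASA without an external binary, so the rolling
## sphere is implemented directly on a deterministic Fibonacci point mesh.

vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               CA = 2.31, MG = 1.73, ZN = 1.39, "NA" = 2.27, K = 2.75)

## Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley rolling-sphere SASA: each atom is covered with a
#' deterministic quasi-uniform mesh at radius r_vdw + probe, and a mesh
#' point contributes area when it is not inside any other atom's expanded
#' sphere.  A point lying exactly on m expanded surfaces (within a small
#' tolerance, as for coincident atoms) is shared equally between the m
#' atoms.  Elements without a tabulated van der Waals radius fall back to
#' `default_radius` with a warning.
#'
#' @param structure `md_structure`.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points mesh points per atom (default 960).
#' @param default_radius fallback van der Waals radius, Angstrom.
#' @return data.frame with columns `chain`, `resno`, `sasa` (Angstrom^2)
#'   and attribute `atom_sasa` holding the per-atom values.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, default_radius = 1.8) {
  at <- structure$atoms
  xyz <- coords(structure)
  ele <- toupper(at$element)
  r <- unname(vdw_radii[ele])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(ele[unknown]), collapse = ", "),
            "; using default radius ", default_radius, " Angstrom")
    r[unknown] <- default_radius
  }
  rs <- r + probe
  mesh <- fibonacci_sphere(n_points)
  tol <- 1e-6
  n_atoms <- nrow(at)
  atom_area <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    ## neighbours whose expanded sphere can reach atom i's expanded surface
    dc <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dc < rs + rs[i] & seq_len(n_atoms) != i)
    pts <- sweep(mesh * rs[i], 2, xyz[i, ], `+`)
    w <- rep(1, n_points)
    m <- rep(1L, n_points)  # how many expanded surfaces the point lies on
    for (j in nb) {
      dj <- sqrt(rowSums(sweep(pts, 2, xyz[j, ])^2))
      w[dj < rs[j] - tol] <- 0
      m[abs(dj - rs[j]) <= tol] <- m[abs(dj - rs[j]) <= tol] + 1L
    }
    atom_area[i] <- 4 * pi * rs[i]^2 * sum(w / m) / n_points
  }
  key <- paste(at$chain, at$resno, sep = "|")
  first <- !duplicated(key)
  out <- data.frame(chain = at$chain[first], resno = at$resno[first],
                    stringsAsFactors = FALSE)
  agg <- tapply(atom_area, key, sum)
  out$sasa <- as.numeric(agg[paste(out$chain, out$resno, sep = "|")])
  attr(out, "atom_sasa") <- atom_area
  out
}
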