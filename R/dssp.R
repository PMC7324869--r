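## Alpha-helix assignment from backbone geometry, following the
## Kabsch-Sander electrostatic hydrogen-bond model, plus a generic geometric
## hydrogen-bond counter.  Only the helix (H) state is needed here; the full
## secondary-structure alphabet is out of scope.

KS_COUPLING <- 0.084 * 332  # kcal/mol * Angstrom, partial-charge prefactor
KS_CUTOFF <- -0.5           # kcal/mol; bonds weaker than this are ignored

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

## Backbone table for one chain: matrices of N, CA, C, O (and H, placed if
## absent) indexed by residue order.
chain_backbone <- function(atoms, xyz, chain) {
  rows <- which(atoms$chain == chain)
  resnos <- sort(unique(atoms$resno[rows]))
  pick <- function(resno, name) {
    r <- rows[atoms$resno[rows] == resno & atoms$name[rows] == name]
    if (length(r) != 1) return(rep(NA_real_, 3))
    xyz[r[1], ]
  }
  n <- length(resnos)
  get_mat <- function(name) t(vapply(resnos, pick, numeric(3), name = name))
  N <- get_mat("N"); CA <- get_mat("CA"); C <- get_mat("C"); O <- get_mat("O")
  if (anyNA(N) || anyNA(CA) || anyNA(C) || anyNA(O))
    stop(sprintf("chain %s: missing backbone atoms (need N, CA, C, O per residue)",
                 chain))
  H <- get_mat("H")
  missing_h <- is.na(H[, 1])
  ## amide H reconstruction: 1.01 Angstrom from N, opposed to the bisector
  ## of the N->C(prev) and N->CA directions.  Residue 1 has no amide H.
  for (i in which(missing_h)) {
    if (i == 1) next
    u <- normalize(normalize(N[i, ] - C[i - 1, ]) + normalize(N[i, ] - CA[i, ]))
    H[i, ] <- N[i, ] + 1.01 * u
  }
  list(resno = resnos, N = N, CA = CA, C = C, O = O, H = H,
       has_h = !(seq_len(n) == 1 & missing_h))
}

## Kabsch-Sander energy of the hydrogen bond donated by residue i's NH to
## residue j's CO, kcal/mol.
ks_energy <- function(bb, i, j) {
  if (i == 1 && is.na(bb$H[1, 1])) return(Inf)
  d <- function(a, b) sqrt(sum((a - b)^2))
  rON <- d(bb$O[j, ], bb$N[i, ]); rCH <- d(bb$C[j, ], bb$H[i, ])
  rOH <- d(bb$O[j, ], bb$H[i, ]); rCN <- d(bb$C[j, ], bb$N[i, ])
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)  # clashing, treated as bonded
  KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

## Alpha-helix flags for one chain: residue belongs to H if it lies in a
## stretch i+1..i+4 supported by two consecutive 4-turns (CO(i)->NH(i+4)
## and CO(i+1)->NH(i+5) hydrogen bonds).
assign_helix_chain <- function(bb) {
  n <- length(bb$resno)
  helix <- rep(FALSE, n)
  if (n < 6) return(helix)
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n - 4)) {
    if (bb$resno[i + 4] - bb$resno[i] != 4) next  # chain break
    turn4[i] <- ks_energy(bb, i + 4, i) < KS_CUTOFF
  }
  for (i in seq_len(n - 5)) {
    if (turn4[i] && turn4[i + 1]) helix[(i + 1):(i + 4)] <- TRUE
  }
  helix
}

#' Alpha-helix assignment for one frame
#'
#' Assigns each residue to helix/not-helix using the Kabsch-Sander
#' hydrogen-bond energy (bond if E < -0.5 kcal/mol) and the standard
#' alpha-helix pattern of two consecutive i -> i+4 bonds.  Amide hydrogens
#' are taken from the structure when present and otherwise placed 1.01
#' Angstrom from N opposite the bisector of the N-C(prev) and N-CA bonds.
#'
#' @param structure `md_structure` with backbone N, CA, C, O atoms.
#' @return data.frame with columns `chain`, `resno`, `helix` (logical).
#' @export
dssp_helix <- function(structure) {
  at <- structure$atoms
  xyz <- coords(structure)
  out <- lapply(unique(at$chain), function(ch) {
    bb <- chain_backbone(at, xyz, ch)
    data.frame(chain = ch, resno = bb$resno,
               helix = assign_helix_chain(bb), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-residue helicity over a trajectory
#'
#' Fraction of frames in which each residue is assigned alpha-helical by
#' [dssp_helix()].  The default residue range is the H4 C-terminal segment
#' C85-S93, whose folding reports on calcium-dependent activation.
#'
#' @param trajectory `md_trajectory` (an `md_structure` is treated as one
#'   frame).
#' @param residues residue numbers to report (default 85:93).
#' @param chain chain(s) to report; default all.
#' @return data.frame with columns `chain`, `resno`, `helicity` in \[0,1\].
#' @export
helicity <- function(trajectory, residues = 85:93, chain = NULL) {
  traj <- if (inherits(trajectory, "md_structure"))
    md_trajectory(trajectory, list(coords(trajectory))) else trajectory
  per_frame <- lapply(seq_len(n_frames(traj)), function(i)
    dssp_helix(frame_structure(traj, i)))
  base <- per_frame[[1]][, c("chain", "resno")]
  frac <- rowMeans(vapply(per_frame, function(d) as.numeric(d$helix),
                          numeric(nrow(base))))
  out <- cbind(base, helicity = frac)
  keep <- out$resno %in% residues
  if (!is.null(chain)) keep <- keep & out$chain %in% chain
  out <- out[keep, ]
  rownames(out) <- NULL
  out
}

#' Count geometric hydrogen bonds in one frame
#'
#' A donor-acceptor pair is counted when the donor-acceptor heavy-atom
#' distance is at most `d_cut` and the D-H...A angle is at least
#' `angle_cut`.  Defaults (3.5 Angstrom, 135 degrees) are common trajectory
#' analysis settings.
#'
#' @param structure `md_structure`.
#' @param donors data.frame with integer columns `donor` and `hydrogen`
#'   (atom indices into the structure's atom table).
#' @param acceptors integer vector of acceptor atom indices.
#' @param d_cut donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cut minimum D-H-A angle, degrees.
#' @return integer count of bonded pairs.
#' @export
hbond_count <- function(structure, donors, acceptors,
                        d_cut = 3.5, angle_cut = 135) {
  xyz <- coords(structure)
  count <- 0L
  for (k in seq_len(nrow(donors))) {
    d_idx <- donors$donor[k]; h_idx <- donors$hydrogen[k]
    for (a_idx in acceptors) {
      if (a_idx == d_idx) next
      da <- sqrt(sum((xyz[a_idx, ] - xyz[d_idx, ])^2))
      if (da > d_cut) next
      v1 <- xyz[d_idx, ] - xyz[h_idx, ]
      v2 <- xyz[a_idx, ] - xyz[h_idx, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= angle_cut) count <- count + 1L
    }
  }
  count
}
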