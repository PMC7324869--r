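## Structure / trajectory containers and readers.
##
## Atoms live in a plain data.frame (one row per atom, stable order) so that
## every metric can index it directly; parsing of the PDB format itself is
## delegated to bio3d.

atomic_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971, F = 18.998,
                   CL = 35.45, BR = 79.904, I = 126.904, CA = 40.078,
                   MG = 24.305, ZN = 65.38, FE = 55.845, MN = 54.938,
                   CU = 63.546, "NA" = 22.990, K = 39.098)

element_mass <- function(element, default = 12.011) {
  m <- unname(atomic_masses[toupper(element)])
  if (anyNA(m)) {
    warning("unknown element(s) ",
            paste(unique(element[is.na(m)]), collapse = ", "),
            "; assigning mass ", default, " amu")
    m[is.na(m)] <- default
  }
  m
}

#' Construct a molecular structure object
#'
#' An `md_structure` is a light container holding one conformer: an ordered
#' atom table plus the index of the model it came from.  Positions are in
#' Angstrom, residue numbers follow PDB author numbering (1-based), masses are
#' in amu.
#'
#' @param atoms data.frame with columns `name` (atom name, e.g. `"CA"`),
#'   `element`, `resno` (integer), `resid` (3-letter residue code), `chain`
#'   (single character), `x`, `y`, `z` (Angstrom) and `mass` (amu).
#' @param model_index which model of a multi-model file this conformer is.
#' @param n_models total number of models in the source file, if known.
#'
#' @return object of class `md_structure`.
#' @export
md_structure <- function(atoms, model_index = 1L, n_models = 1L) {
  required <- c("name", "element", "resno", "resid", "chain",
                "x", "y", "z", "mass")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$resno < 1))
    stop("residue numbers must be >= 1 (PDB author numbering)")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 model_index = as.integer(model_index),
                 n_models = as.integer(n_models)),
            class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d residues, chains %s (model %d of %d)\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ","),
              x$model_index, x$n_models))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param structure `md_structure`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of one model of a (possibly multi-model NMR)
#' PDB file.  Alternate locations are reduced to the highest-occupancy
#' conformer (first wins on ties); hydrogens are retained.  The default is
#' model 1, which gives a deterministic conformer for multi-model NMR
#' depositions.
#'
#' @param path PDB file.
#' @param model 1-based model index.
#' @return `md_structure`; the `n_models` field reports the model count of
#'   the file.
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models)
    stop(sprintf("model %d out of range (file has %d model(s))",
                 model, n_models))
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)

  ## altloc: keep highest occupancy per (chain, resno, insert, name)
  keep <- rep(TRUE, nrow(at))
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    for (k in unique(key[alt])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  ele <- at$elesy
  bad <- is.na(ele) | ele == ""
  if (any(bad))
    ele[bad] <- bio3d::atom2ele(at$elety[bad])
  mass <- element_mass(ele)
  atoms <- data.frame(name = at$elety, element = ele,
                      resno = as.integer(at$resno), resid = at$resid,
                      chain = ifelse(is.na(at$chain), " ", at$chain),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      mass = mass, stringsAsFactors = FALSE)[keep, ]
  md_structure(atoms, model_index = model, n_models = n_models)
}

#' Write a structure to a PDB file
#'
#' Inverse of [read_pdb()]: chain/residue/atom identity and coordinates are
#' preserved to PDB precision (3 decimals).
#'
#' @param structure `md_structure`.
#' @param path output file.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(structure))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$name, chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Atom selection
#'
#' A declarative filter over the atom table: any combination of chain,
#' inclusive 1-based residue range(s), and atom name(s).  `NULL` means "no
#' constraint".  Residue ranges may be given as a vector of residue numbers
#' (e.g. `c(61:62, 72:73)`).
#'
#' @param chain chain identifier(s) or NULL.
#' @param resno residue number(s) (PDB author numbering) or NULL.
#' @param name atom name(s), e.g. `"CA"`, or NULL.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(chain = NULL, resno = NULL, name = NULL) {
  structure(list(chain = chain, resno = resno, name = name),
            class = "atom_selection")
}

#' Resolve a selection to atom indices
#'
#' Deterministic and order-preserving: indices come back in topology order,
#' so applying the same selection twice gives the same subset.  An empty
#' result is legal.
#'
#' @param structure `md_structure` (or an `md_trajectory`, whose topology is
#'   used).
#' @param selection `atom_selection`.
#' @return integer vector of row indices into the atom table.
#' @export
select_atoms <- function(structure, selection) {
  if (inherits(structure, "md_trajectory")) structure <- structure$topology
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
  if (!is.null(selection$resno)) keep <- keep & a$resno %in% selection$resno
  if (!is.null(selection$name))  keep <- keep & a$name  %in% selection$name
  which(keep)
}

#' Construct a trajectory
#'
#' @param topology `md_structure` giving atom identities.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param frame_stride optional time per frame (arbitrary units).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, frame_stride = NULL) {
  n <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3,
               logical(1))
  if (!all(ok)) stop("every frame must be an n_atoms x 3 matrix")
  structure(list(topology = topology, frames = frames,
                 frame_stride = frame_stride),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory `md_trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL block becomes one frame; the first model supplies the topology.
#'
#' @param path PDB file.
#' @param frame_stride optional time per frame.
#' @return `md_trajectory`.
#' @export
read_trajectory_pdb <- function(path, frame_stride = NULL) {
  top <- read_pdb(path, model = 1L)
  frames <- lapply(seq_len(top$n_models), function(m)
    coords(read_pdb(path, model = m)))
  md_trajectory(top, frames, frame_stride = frame_stride)
}

#' Structure at one frame of a trajectory
#' @param trajectory `md_trajectory`.
#' @param i frame index.
#' @return `md_structure` with the topology's atom table and frame i's
#'   coordinates.
#' @export
frame_structure <- function(trajectory, i) {
  s <- trajectory$topology
  s$atoms[, c("x", "y", "z")] <- trajectory$frames[[i]]
  s
}

#' Read a reaction-coordinate time series for one umbrella window
#'
#' Plain text, one sample (Angstrom) per row.  Files written as
#' `time value` pairs are handled by `time_column = TRUE`, which keeps only
#' the second column.  Comma, tab and whitespace separators are accepted.
#'
#' @param path text/CSV file.
#' @param time_column if TRUE the first column is a time stamp and is
#'   dropped.
#' @return numeric vector of samples.
#' @export
read_window_series <- function(path, time_column = FALSE) {
  if (!file.exists(path)) stop("window series file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty window series file: ", path)
  col <- if (time_column) 2L else 1L
  vals <- vapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "[,;[:space:]]+")[[1]]
    if (length(fields) < col)
      stop(sprintf("line %d of %s has %d field(s), need %d",
                   i, path, length(fields), col))
    v <- suppressWarnings(as.numeric(fields[[col]]))
    if (is.na(v))
      stop(sprintf("non-numeric value '%s' on line %d of %s",
                   fields[[col]], i, path))
    v
  }, numeric(1))
  vals
}
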