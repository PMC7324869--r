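## Per-residue interaction-energy bookkeeping for end-point (MM-GBSA style)
## dimer-vs-monomer decompositions.  The solvation/mechanics energies
## themselves arrive as tables; this module handles the ensemble averaging
## Delta G = <G_dimer> - <G_monomer> and its per-residue split into
## electrostatic, van der Waals and solvation terms (bonded terms excluded
## upstream).

#' Construct a per-frame, per-residue energy table
#'
#' @param df data.frame with columns `frame`, `resno`, `e_eel`, `e_vdw`,
#'   `e_solv` (kcal/mol).
#' @param system label: `"dimer"`, `"monomerA"`, `"monomerB"`, ...
#' @return object of class `energy_table`.
#' @export
energy_table <- function(df, system = "dimer") {
  need <- c("frame", "resno", "e_eel", "e_vdw", "e_solv")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("energy table lacks columns: ", paste(missing_cols, collapse = ", "))
  counts <- table(df$resno)
  if (length(unique(counts)) > 1)
    stop("inconsistent frame counts across residues")
  structure(list(data = df[, need], system = system), class = "energy_table")
}

#' Read an energy table from CSV
#' @param path CSV with columns frame, resno, e_eel, e_vdw, e_solv.
#' @param system system label.
#' @return `energy_table`.
#' @export
read_energy_table <- function(path, system = "dimer") {
  energy_table(read.csv(path), system = system)
}

energy_totals_by_residue <- function(tab) {
  d <- tab$data
  tot <- d$e_eel + d$e_vdw + d$e_solv
  split(tot, d$resno)
}

#' Per-residue interaction free-energy difference (dimer minus monomers)
#'
#' For each residue the ensemble-averaged total energy
#' (E_EEL + E_vdW + E_solv) in the dimer minus the same average in the
#' monomer containing that residue.  Monomer residue sets must partition
#' the dimer's residues.  The reported `sd` combines the frame-wise
#' standard deviations of the dimer and monomer totals in quadrature.
#'
#' @param dimer `energy_table` for the dimer.
#' @param monomers list of `energy_table`s whose residues partition the
#'   dimer's.
#' @return data.frame with columns `resno`, `delta` (kcal/mol), `sd`.
#'   Summing `delta` over residues gives the total `<G_dimer> -
#'   <G_monomers>` of the same tables.
#' @export
per_residue_interaction_delta <- function(dimer, monomers) {
  if (inherits(monomers, "energy_table")) monomers <- list(monomers)
  dim_tot <- energy_totals_by_residue(dimer)
  mono_tot <- do.call(c, lapply(monomers, energy_totals_by_residue))
  if (anyDuplicated(names(mono_tot)))
    stop("monomer residue sets overlap")
  if (!setequal(names(dim_tot), names(mono_tot)))
    stop("monomer residues do not partition the dimer residues")
  resno <- sort(as.integer(names(dim_tot)))
  delta <- vapply(as.character(resno), function(r)
    mean(dim_tot[[r]]) - mean(mono_tot[[r]]), numeric(1))
  sdev <- vapply(as.character(resno), function(r)
    sqrt(stats::var(dim_tot[[r]]) + stats::var(mono_tot[[r]])), numeric(1))
  data.frame(resno = resno, delta = unname(delta), sd = unname(sdev))
}
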