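## Structural metrics on structures and trajectories: H3/H4 opening angle,
## Kabsch superposition / RMSD / RMSF, residue contact maps, hierarchical
## clustering on pairwise RMSD.

backbone_names <- c("N", "CA", "C", "O")

coords_of <- function(x, idx = NULL) {
  m <- if (inherits(x, "md_structure")) coords(x) else as.matrix(x)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Definition of the H3/H4 inter-helix opening angle
#'
#' The opening of the hydrophobic target-binding patch of an S100/EF-hand
#' domain is measured as the angle, at the hinge, between two rays: one to
#' the C-alpha of a residue at the C-terminal end of helix 4 (default C85)
#' and one to the C-alpha of a residue on helix 3 (default A53).  The hinge
#' vertex is the geometric centroid of the C-alpha atoms of the loop
#' residues flanking it (default L61-D62 and Q72-E73).  Larger angles mean a
#' more open, peptide-competent patch.
#'
#' @param chain chain to measure (default `"A"`).
#' @param ray1_resno,ray2_resno residue numbers of the two ray C-alphas.
#' @param vertex_resno residue numbers whose C-alpha centroid is the vertex.
#' @return object of class `angle_definition`.
#' @export
angle_definition <- function(chain = "A", ray1_resno = 53L, ray2_resno = 85L,
                             vertex_resno = c(61L, 62L, 72L, 73L)) {
  structure(list(chain = chain, ray1_resno = ray1_resno,
                 ray2_resno = ray2_resno, vertex_resno = vertex_resno),
            class = "angle_definition")
}

#' H3/H4 inter-helix opening angle
#'
#' Angle in degrees at the vertex centroid between the rays to the two
#' C-alpha atoms of an [angle_definition()].  Invariant under rigid-body
#' motion of the frame.
#'
#' @param structure `md_structure` (one frame).
#' @param definition `angle_definition`.
#' @return angle in degrees, in \[0, 180\].
#' @export
helix_angle <- function(structure, definition = angle_definition()) {
  one_ca <- function(resno) {
    idx <- select_atoms(structure, atom_selection(chain = definition$chain,
                                                  resno = resno, name = "CA"))
    if (length(idx) != 1)
      stop(sprintf("ray selection (chain %s, residue %s, CA) resolves to %d atoms",
                   definition$chain, paste(resno, collapse = ","), length(idx)))
    coords(structure)[idx, ]
  }
  vidx <- select_atoms(structure, atom_selection(chain = definition$chain,
                                                 resno = definition$vertex_resno,
                                                 name = "CA"))
  if (!length(vidx)) stop("vertex selection resolves to no atoms")
  vertex <- colMeans(coords(structure)[vidx, , drop = FALSE])
  v1 <- one_ca(definition$ray1_resno) - vertex
  v2 <- one_ca(definition$ray2_resno) - vertex
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("ray atom coincides with vertex centroid")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

## Kabsch: rotation R and translation t such that from %*% R + t best fits
## onto `to` (row-vector convention), least squares.
kabsch_fit <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  fc <- sweep(from, 2, cf); tc <- sweep(to, 2, ct)
  H <- crossprod(fc, tc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = R, translation = ct - as.numeric(cf %*% R))
}

apply_fit <- function(m, fit) sweep(m %*% fit$rotation, 2, fit$translation, `+`)

#' Optimal superposition RMSD between two frames
#'
#' Least-squares (Kabsch) rigid-body superposition of `frame_b` onto
#' `frame_a` over the selected atoms.
#'
#' @param frame_a,frame_b `md_structure` objects or n x 3 coordinate
#'   matrices with matching atom order.
#' @param selection optional `atom_selection` (applied to both; requires
#'   `md_structure` inputs); default all atoms.
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3) and
#'   `translation` (length 3): `frame_b` coords `%*%` rotation + translation
#'   superposes onto `frame_a`.
#' @export
superpose_rmsd <- function(frame_a, frame_b, selection = NULL) {
  idx <- NULL
  if (!is.null(selection)) {
    idx <- select_atoms(frame_a, selection)
    idx_b <- select_atoms(frame_b, selection)
    if (!identical(idx, idx_b)) stop("selection resolves differently in the two frames")
  }
  a <- coords_of(frame_a, idx); b <- coords_of(frame_b, idx)
  if (nrow(a) != nrow(b)) stop("atom count mismatch between frames")
  if (nrow(a) < 3) stop("need at least 3 atoms for superposition")
  fit <- kabsch_fit(b, a)
  bf <- apply_fit(b, fit)
  list(rmsd = sqrt(mean(rowSums((bf - a)^2))),
       rotation = fit$rotation, translation = fit$translation)
}

#' Root-mean-square fluctuation per residue
#'
#' Frames are first superposed onto frame 1 over the fit selection, a mean
#' structure is formed, and every frame is then superposed onto that mean
#' (one alignment pass).  The RMSF of a residue is the root mean square,
#' over frames and over its selected atoms (default backbone N, C-alpha, C,
#' O), of the deviation from the mean structure.
#'
#' @param trajectory `md_trajectory` with at least 2 frames.
#' @param selection atoms to report on; default backbone atoms.
#' @param fit_selection atoms used for the superposition; defaults to
#'   `selection`.
#' @return data.frame with columns `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf <- function(trajectory,
                 selection = atom_selection(name = backbone_names),
                 fit_selection = selection) {
  if (n_frames(trajectory) < 2) stop("RMSF needs at least 2 frames")
  fit_idx <- select_atoms(trajectory, fit_selection)
  if (length(fit_idx) < 3) stop("fit selection needs at least 3 atoms")
  align_to <- function(frames, ref) lapply(frames, function(f) {
    apply_fit(f, kabsch_fit(f[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE]))
  })
  pass1 <- align_to(trajectory$frames, trajectory$frames[[1]])
  mean_xyz <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- align_to(trajectory$frames, mean_xyz)
  mean_xyz <- Reduce(`+`, pass2) / length(pass2)

  idx <- select_atoms(trajectory, selection)
  sq <- Reduce(`+`, lapply(pass2, function(f)
    rowSums((f[idx, , drop = FALSE] - mean_xyz[idx, , drop = FALSE])^2)))
  msf_atom <- sq / length(pass2)

  at <- trajectory$topology$atoms[idx, ]
  key <- paste(at$chain, at$resno, sep = "|")
  agg <- tapply(msf_atom, key, mean)
  first <- !duplicated(key)
  out <- data.frame(chain = at$chain[first], resno = at$resno[first],
                    stringsAsFactors = FALSE)
  out$rmsf <- sqrt(as.numeric(agg[paste(out$chain, out$resno, sep = "|")]))
  out[order(out$chain, out$resno), ]
}

residue_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  ukey <- unique(key)
  list(index = match(key, ukey),
       table = data.frame(chain = sub("\\|.*", "", ukey),
                          resno = as.integer(sub(".*\\|", "", ukey)),
                          stringsAsFactors = FALSE))
}

#' Residue-residue contact map
#'
#' Two residues are in contact in a frame if their minimum heavy-atom
#' distance is less than or equal to `cutoff` (the boundary counts).  Only
#' pairs at least `min_sep` residues apart in sequence are considered
#' ("i and i+6" at the default); pairs on different chains are always
#' eligible.  Over a trajectory the map holds the fraction of frames in
#' contact.
#'
#' @param x `md_trajectory` or single `md_structure`.
#' @param cutoff distance cutoff, Angstrom (default 7).
#' @param min_sep minimum sequence separation (default 6).
#' @return object of class `contact_map`: list with `residues`
#'   (data.frame chain/resno), `frequency` (symmetric matrix in \[0,1\]),
#'   `cutoff`, `min_sep`.
#' @export
contact_map <- function(x, cutoff = 7, min_sep = 6) {
  traj <- if (inherits(x, "md_structure")) md_trajectory(x, list(coords(x))) else x
  at <- traj$topology$atoms
  heavy <- which(toupper(at$element) != "H")
  ri <- residue_index(at[heavy, ])
  res <- ri$table
  nres <- nrow(res)
  eligible <- matrix(FALSE, nres, nres)
  for (i in seq_len(nres - 1)) for (j in (i + 1):nres) {
    eligible[i, j] <- eligible[j, i] <-
      res$chain[i] != res$chain[j] || abs(res$resno[i] - res$resno[j]) >= min_sep
  }
  freq <- matrix(0, nres, nres)
  for (f in traj$frames) {
    xyz <- f[heavy, , drop = FALSE]
    d <- as.matrix(dist(xyz))
    for (i in seq_len(nres - 1)) {
      ai <- which(ri$index == i)
      for (j in (i + 1):nres) {
        if (!eligible[i, j]) next
        if (min(d[ai, ri$index == j]) <= cutoff) {
          freq[i, j] <- freq[j, i] <- freq[i, j] + 1
        }
      }
    }
  }
  freq <- freq / length(traj$frames)
  structure(list(residues = res, frequency = freq,
                 cutoff = cutoff, min_sep = min_sep),
            class = "contact_map")
}

#' Pairwise best-fit RMSD matrix over frames
#'
#' @param trajectory `md_trajectory`.
#' @param selection atoms used for fitting and measuring (default C-alpha).
#' @return symmetric matrix of RMSD values (Angstrom).
#' @export
pairwise_rmsd <- function(trajectory, selection = atom_selection(name = "CA")) {
  idx <- select_atoms(trajectory, selection)
  if (length(idx) < 3) stop("selection needs at least 3 atoms")
  n <- n_frames(trajectory)
  xyz <- lapply(trajectory$frames, function(f) f[idx, , drop = FALSE])
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    fit <- kabsch_fit(xyz[[j]], xyz[[i]])
    d[i, j] <- d[j, i] <- sqrt(mean(rowSums((apply_fit(xyz[[j]], fit) - xyz[[i]])^2)))
  }
  d
}

#' Hierarchical clustering of trajectory frames
#'
#' Agglomerative clustering (average linkage) on the pairwise best-fit RMSD
#' matrix.  Clusters are relabelled in order of decreasing size (ties broken
#' by lowest member frame index); the representative of a cluster is its
#' medoid, the frame minimising the summed RMSD to the other members (ties
#' broken by lower frame index).
#'
#' @param trajectory `md_trajectory`.
#' @param n_clusters number of clusters (must not exceed the frame count).
#' @param selection atoms used for RMSD (default C-alpha).
#' @return object of class `cluster_result`: `labels` (per frame), `sizes`
#'   (per cluster, decreasing), `representatives` (medoid frame index per
#'   cluster).
#' @export
cluster_frames <- function(trajectory, n_clusters,
                           selection = atom_selection(name = "CA")) {
  n <- n_frames(trajectory)
  if (n_clusters > n) stop("n_clusters exceeds frame count")
  d <- pairwise_rmsd(trajectory, selection)
  labels <- if (n_clusters == n) seq_len(n) else {
    hc <- hclust(as.dist(d), method = "average")
    unname(cutree(hc, k = n_clusters))
  }
  sizes <- table(labels)
  first_member <- vapply(names(sizes), function(l) min(which(labels == l)), numeric(1))
  ord <- order(-as.numeric(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- as.integer(relabel[as.character(labels)])
  sizes <- as.integer(table(labels))
  reps <- vapply(seq_len(n_clusters), function(k) {
    members <- which(labels == k)
    if (length(members) == 1) return(members)
    tot <- rowSums(d[members, members, drop = FALSE])
    members[which.min(tot)]
  }, integer(1))
  structure(list(labels = labels, sizes = sizes, representatives = reps),
            class = "cluster_result")
}

#' Representatives of the k least-populated clusters
#'
#' Mirrors the practice of seeding fresh sampling cycles from sparse
#' clusters.
#'
#' @param result `cluster_result`.
#' @param k how many clusters, counted from the least populated.
#' @return frame indices of the medoids of the `k` smallest clusters.
#' @export
least_populated_representatives <- function(result, k = 3) {
  k <- min(k, length(result$sizes))
  ord <- order(result$sizes, -seq_along(result$sizes))  # smallest first, later label wins ties
  result$representatives[head(ord, k)]
}
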