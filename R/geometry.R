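# Per-frame geometric observables for helix dimers.

#' Fit the principal axis of a helix
#'
#' The axis direction is the principal eigenvector of the C-alpha coordinate
#' covariance, signed so it points from the N- to the C-terminus; the origin
#' is the C-alpha centroid. When the reference residue's C-beta is present, a
#' unit vector perpendicular to the axis pointing from the axis toward that
#' C-beta is recorded (used as the spin reference of the rotation CV).
#'
#' @param s an [md_structure].
#' @param chain chain identifier.
#' @param residue_range optional integer vector of residue numbers to use.
#' @param ref_residue residue whose C-beta anchors the spin reference
#'   (default 175, the mid-helix interface isoleucine).
#' @return a `helix_axis` list: `origin`, `direction`, `reference_vector`.
#' @export
fit_helix_axis <- function(s, chain, residue_range = NULL,
                           ref_residue = 175L) {
  idx <- atom_select(s, chain = chain, resno = residue_range,
                     atom_name = "CA")
  if (length(idx) < 4L)
    stop("need at least 4 C-alpha atoms to fit a helix axis (got ",
         length(idx), ")")
  ord <- order(s$atoms$residue_number[idx])
  ca <- coords_matrix(s)[idx[ord], , drop = FALSE]
  origin <- colMeans(ca)
  cc <- sweep(ca, 2L, origin)
  direction <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1L]
  if (sum((ca[nrow(ca), ] - ca[1L, ]) * direction) < 0)
    direction <- -direction
  ref_vec <- NULL
  cb_idx <- atom_select(s, chain = chain, resno = ref_residue,
                        atom_name = "CB")
  if (length(cb_idx) == 1L) {
    v <- as.numeric(coords_matrix(s)[cb_idx, ]) - origin
    v <- v - sum(v * direction) * direction
    if (vnorm(v) > 1e-9) ref_vec <- unitv(v)
  }
  structure(list(origin = origin, direction = direction,
                 reference_vector = ref_vec),
            class = "helix_axis")
}

# Signed angle (degrees) from a to b about unit axis d, right-handed.
signed_angle_about <- function(a, b, d) {
  atan2(sum(cross3(a, b) * d), sum(a * b)) * 180 / pi
}

# Project v into the plane perpendicular to unit vector d and normalise.
perp_unit <- function(v, d) {
  w <- v - sum(v * d) * d
  unitv(w)
}

# Spin azimuth of one monomer: angle of its C-beta(ref) direction about its
# axis, measured from the interface anchor (projected direction toward the
# partner monomer's axis origin). Interface-anchored so the reading is
# invariant under global rigid motion of the dimer.
monomer_spin <- function(s, chain, partner_chain, ref_residue) {
  ax <- fit_helix_axis(s, chain, ref_residue = ref_residue)
  if (is.null(ax$reference_vector))
    stop("missing C-beta at reference residue ", ref_residue, " in chain ",
         chain)
  ax_p <- fit_helix_axis(s, partner_chain, ref_residue = ref_residue)
  anchor <- perp_unit(ax_p$origin - ax$origin, ax$direction)
  signed_angle_about(anchor, ax$reference_vector, ax$direction)
}

#' Rotation-angle collective variables of a helix dimer
#'
#' For each monomer, the rotation angle is the spin of its backbone about
#' its own principal axis: the signed azimuth (right-handed about the N->C
#' axis direction) of the axis->C-beta(ref_residue) direction measured from
#' the interface anchor (the projected direction toward the partner
#' monomer), relative to the same reading on the reference dimer. The CV is
#' therefore (0, 0) at the reference structure, recovers scheduled rigid
#' rotations about the monomer axes exactly, and is invariant under global
#' rigid-body motion.
#'
#' @param frame an [md_structure] holding the dimer conformation to measure.
#' @param reference the zero-angle reference dimer (an [md_structure]).
#' @param chains length-2 character vector naming the two monomer chains.
#' @param ref_residue spin-reference residue (default 175).
#' @return list with `alpha` and `beta` in degrees, each in (-180, 180].
#' @export
rotation_cv <- function(frame, reference, chains = c("A", "B"),
                        ref_residue = 175L) {
  a_f <- monomer_spin(frame, chains[1L], chains[2L], ref_residue)
  a_r <- monomer_spin(reference, chains[1L], chains[2L], ref_residue)
  b_f <- monomer_spin(frame, chains[2L], chains[1L], ref_residue)
  b_r <- monomer_spin(reference, chains[2L], chains[1L], ref_residue)
  list(alpha = wrap_angle(a_f - a_r), beta = wrap_angle(b_f - b_r))
}

# sign applied to the inter-axis torsion so that right-handed packing
# (contact stripe of residues spaced i, i+4 on a right-handed alpha helix,
# the GxxxA/GxxxG packing mode) is reported positive.
CROSSING_SIGN <- -1

#' Signed helix-helix crossing angle
#'
#' Magnitude is the angle between the two fitted axis directions (folded to
#' at most 90 degrees); the sign is positive for right-handed crossing, the
#' packing mode of GxxxA/GxxxG interfaces. Computed as the torsion angle
#' about the line of closest approach between the two axes.
#'
#' @param s an [md_structure] containing both monomers.
#' @param chains length-2 character vector of chain ids.
#' @return signed crossing angle in degrees, |value| <= 90.
#' @export
crossing_angle <- function(s, chains = c("A", "B")) {
  ax1 <- fit_helix_axis(s, chains[1L])
  ax2 <- fit_helix_axis(s, chains[2L])
  u1 <- ax1$direction; u2 <- ax2$direction
  w0 <- ax1$origin - ax2$origin
  b <- sum(u1 * u2)
  denom <- 1 - b^2
  if (denom < 1e-12) {
    # parallel axes: closest approach is any perpendicular foot
    p1 <- ax1$origin
    p2 <- ax2$origin + sum(w0 * u2) * u2
    if (vnorm(p1 - p2) < 1e-9) {
      warning("degenerate geometry: parallel coincident axes")
      return(0)
    }
    return(0)
  }
  d <- sum(u1 * w0); e <- sum(u2 * w0)
  t1 <- (b * e - d) / denom
  t2 <- (e - b * d) / denom
  p1 <- ax1$origin + t1 * u1
  p2 <- ax2$origin + t2 * u2
  if (vnorm(p1 - p2) < 1e-9) {
    # axes intersect: torsion still defined via the mutual perpendicular
    nvec <- cross3(u1, u2)
    p2 <- p2 + 1e-6 * nvec
  }
  tor <- dihedral4(p1 + u1, p1, p2, p2 + u2)
  # fold to the acute line-line angle, preserving handedness sign
  if (tor > 90) tor <- tor - 180
  if (tor < -90) tor <- tor + 180
  CROSSING_SIGN * tor
}

#' Backbone RMSD after optimal superposition
#'
#' Least-squares (Kabsch) superposition of the selected backbone atoms of
#' `frame` onto `reference`, then root-mean-square deviation.
#'
#' @param frame,reference [md_structure]s with matching atoms.
#' @param chains chains to include (default: all shared chains).
#' @param atom_names atoms defining "backbone" (default N, CA, C, O).
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(frame, reference, chains = NULL,
                          atom_names = c("N", "CA", "C", "O")) {
  key <- function(s) paste(s$atoms$chain_id, s$atoms$residue_number,
                           s$atoms$atom_name)
  if (is.null(chains))
    chains <- intersect(unique(frame$atoms$chain_id),
                        unique(reference$atoms$chain_id))
  fi <- atom_select(frame, chain = chains, atom_name = atom_names)
  ri <- atom_select(reference, chain = chains, atom_name = atom_names)
  kf <- key(frame)[fi]; kr <- key(reference)[ri]
  common <- intersect(kf, kr)
  if (length(common) != length(kf) || length(common) != length(kr))
    stop("backbone atom mismatch between frame and reference")
  P <- coords_matrix(frame)[fi[match(common, kf)], , drop = FALSE]
  Q <- coords_matrix(reference)[ri[match(common, kr)], , drop = FALSE]
  kabsch_rmsd(P, Q)
}

# Kabsch superposition RMSD of P onto Q (both n x 3).
kabsch_rmsd <- function(P, Q) {
  if (nrow(P) != nrow(Q)) stop("coordinate sets differ in size")
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- Pc %*% t(R)
  sqrt(mean(rowSums((Pr - Qc)^2)))
}

#' Fraction of helical residues from backbone dihedrals
#'
#' A residue is counted helical when phi lies in [-100, -30] and psi in
#' [-67, -7] degrees (a window comfortably containing the canonical
#' alpha-helix at phi ~ -58, psi ~ -47). Terminal residues lacking one of
#' the two dihedrals are excluded from the denominator.
#'
#' @param s an [md_structure].
#' @param chain chain id.
#' @param phi_range,psi_range dihedral windows in degrees.
#' @return helicity percentage in [0, 100].
#' @export
helicity <- function(s, chain, phi_range = c(-100, -30),
                     psi_range = c(-67, -7)) {
  at <- s$atoms[s$atoms$chain_id == chain, , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain, "' not present")
  resnos <- sort(unique(at$residue_number))
  xyz_of <- function(resno, name) {
    i <- which(at$residue_number == resno & at$atom_name == name)
    if (length(i) != 1L) return(NULL)
    as.numeric(at[i, c("x", "y", "z")])
  }
  n_hel <- 0L; n_assign <- 0L
  for (r in resnos) {
    c_prev <- xyz_of(r - 1L, "C")
    n_i <- xyz_of(r, "N"); ca_i <- xyz_of(r, "CA"); c_i <- xyz_of(r, "C")
    n_next <- xyz_of(r + 1L, "N")
    if (is.null(c_prev) || is.null(n_next) || is.null(n_i) ||
        is.null(ca_i) || is.null(c_i)) next
    phi <- dihedral4(c_prev, n_i, ca_i, c_i)
    psi <- dihedral4(n_i, ca_i, c_i, n_next)
    n_assign <- n_assign + 1L
    if (phi >= phi_range[1L] && phi <= phi_range[2L] &&
        psi >= psi_range[1L] && psi <= psi_range[2L])
      n_hel <- n_hel + 1L
  }
  if (!n_assign) stop("no assignable residues in chain '", chain, "'")
  100 * n_hel / n_assign
}

# Atom used for "C-beta" distances: CB, or CA for glycine.
cb_or_ca_index <- function(s, chain, resno) {
  i <- atom_select(s, chain = chain, resno = resno, atom_name = "CB")
  if (!length(i))
    i <- atom_select(s, chain = chain, resno = resno, atom_name = "CA")
  if (length(i) != 1L)
    stop("residue ", resno, " chain ", chain,
         " lacks a unique CB/CA atom")
  i
}

#' Crosslink C-beta distance series
#'
#' Per-frame C-beta to C-beta' distances for residue pairs across the two
#' monomers (C-alpha substituted at glycine), with the fraction of frames at
#' or below the disulfide-linkable threshold.
#'
#' @param x an [md_trajectory] or a single [md_structure].
#' @param pairs integer vector of residue numbers (each paired with the same
#'   number on the partner chain), or a list of length-2 vectors
#'   `c(res_a, res_b)`.
#' @param chains length-2 chain ids (default A, B).
#' @param threshold linkable distance threshold in Angstrom (default 7).
#' @return list of `crosslink_report`s: `pair`, `distance_series` (Angstrom,
#'   one value per frame), `linkable_fraction`, `threshold`, `times` (ps).
#' @export
cb_distance_series <- function(x, pairs, chains = c("A", "B"),
                               threshold = 7.0) {
  traj <- if (inherits(x, "md_structure")) {
    md_trajectory(x, list(coords_matrix(x)), times = 0)
  } else x
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.numeric(pairs)) pairs <- lapply(pairs, function(r) c(r, r))
  topo <- traj$topology
  lapply(pairs, function(pr) {
    ia <- cb_or_ca_index(topo, chains[1L], pr[1L])
    ib <- cb_or_ca_index(topo, chains[2L], pr[2L])
    d <- vapply(traj$coords, function(m)
      vnorm(m[ia, ] - m[ib, ]), numeric(1L))
    structure(list(pair = pr, distance_series = d,
                   linkable_fraction = mean(d <= threshold),
                   threshold = threshold, times = traj$times),
              class = "crosslink_report")
  })
}
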