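# Crosslink-constrained dimer fixtures.
#
# A dimer fixture is two copies of the ideal helix, rigid-body docked by
# minimising the sum of squared C-beta--C-beta' distances over the state's
# crosslinkable residue pairs (C-alpha at glycine), under a hard no-clash
# constraint (no inter-monomer heavy-atom pair closer than 2.5 Angstrom).
# The crossing angle and rotation-CV readings of the fixtures are emergent
# properties of this optimisation, not inputs.

CROSSLINK_PAIRS <- list(
  intersected  = c(175L, 179L, 183L, 187L),
  parallel     = c(171L, 178L, 182L, 185L),
  iso_parallel = c(172L, 186L)
)

CLASH_CUTOFF <- 2.5      # Angstrom, heavy-atom
LINKABLE_CUTOFF <- 7.0   # Angstrom, C-beta--C-beta'

#' Specify a dimer conformational state
#'
#' The three states are defined by the residue pairs that are
#' disulfide-crosslinkable in that state: `intersected` (I175, G179, A183,
#' I187), `parallel` (Q171, A178, T182, L185) and `iso_parallel` (T172,
#' T186).
#'
#' @param label one of "intersected", "parallel", "iso_parallel".
#' @param target_crossing_angle_hint optional magnitude (degrees) used only
#'   to seed initial tilts of the docking restarts.
#' @return a `dimer_state` list with `label` and `crosslink_pairs`.
#' @export
dimer_state <- function(label = c("intersected", "parallel", "iso_parallel"),
                        target_crossing_angle_hint = NULL) {
  label <- match.arg(label)
  structure(list(label = label,
                 crosslink_pairs = CROSSLINK_PAIRS[[label]],
                 target_crossing_angle_hint = target_crossing_angle_hint),
            class = "dimer_state")
}

# rigid transform of monomer-B coordinates: rotation vector (degrees) about
# the monomer centroid, then translation.
apply_rigid <- function(xyz, params) {
  rotvec <- params[1:3]
  ang <- sqrt(sum(rotvec^2))
  cen <- colMeans(xyz)
  xc <- sweep(xyz, 2L, cen)
  if (ang > 1e-12) {
    R <- rotation_matrix(rotvec, ang)
    xc <- xc %*% t(R)
  }
  sweep(xc, 2L, cen + params[4:6], "+")
}

# squared distances between two coordinate blocks
pair_dist2 <- function(xa, xb) {
  outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
}

#' Build a crosslink-constrained dimer fixture
#'
#' Docks a second copy of the ideal helix (chain B) against a fixed first
#' copy (chain A, axis along +z, the membrane normal) by random-restart
#' rigid-body minimisation (6 degrees of freedom) of the summed squared
#' crosslink-pair distances, subject to the no-clash constraint, followed by
#' perturbation-polish rounds that converge the incumbent to the global
#' optimum. Because the two monomers' spin azimuths are only jointly
#' constrained by the pair distances (their difference is a nearly
#' degenerate valley of the objective), a small deterministic tie-break term
#' prefers the more two-fold-symmetric member of the optimal family, which
#' is the physically expected configuration for a homodimer. The best
#' clash-free solution with all declared pairs within the linkable cutoff
#' is returned; docking metadata (objective, achieved distances, seed) is
#' attached as the `"docking"` attribute.
#'
#' The crossing angle and rotation-CV readings of the returned fixture are
#' emergent properties of the optimisation, not inputs.
#'
#' @param state a [dimer_state] (or a state label).
#' @param seed integer seed controlling the random restarts.
#' @param spec [helix_spec] for the monomers.
#' @param n_restarts number of random restarts (default 24).
#' @param n_polish number of perturbation-polish rounds (default 8).
#' @param linkable_cutoff pair-distance feasibility cutoff in Angstrom.
#' @param clash_cutoff minimum allowed inter-monomer heavy-atom distance.
#' @param w_sym weight (per squared degree) of the symmetry tie-break.
#' @return an [md_structure] with chains A and B; attributes `dimer_state`
#'   and `docking`.
#' @export
build_dimer_fixture <- function(state, seed = 1L, spec = helix_spec(),
                                n_restarts = 24L, n_polish = 8L,
                                linkable_cutoff = LINKABLE_CUTOFF,
                                clash_cutoff = CLASH_CUTOFF,
                                w_sym = 0.002) {
  if (is.character(state)) state <- dimer_state(state)
  stopifnot(inherits(state, "dimer_state"))
  mono_a <- build_ideal_helix(spec, chain_id = "A")
  mono_b <- build_ideal_helix(spec, chain_id = "B")
  xa <- coords_matrix(mono_a)
  xb0 <- coords_matrix(mono_b)
  pa <- vapply(state$crosslink_pairs, function(r)
    cb_or_ca_index(mono_a, "A", r), integer(1L))
  pb <- vapply(state$crosslink_pairs, function(r)
    cb_or_ca_index(mono_b, "B", r), integer(1L))

  # fixed monomer-A spin ingredients for the symmetry tie-break
  ref_res <- 175L
  ax_a <- fit_helix_axis(mono_a, "A", ref_residue = ref_res)
  ax_b0 <- fit_helix_axis(mono_b, "B", ref_residue = ref_res)
  cb_a <- as.numeric(xa[cb_or_ca_index(mono_a, "A", ref_res), ])
  cb_b0 <- as.numeric(xb0[cb_or_ca_index(mono_b, "B", ref_res), ])
  cen_b <- colMeans(xb0)

  spin_asymmetry <- function(params) {
    rotvec <- params[1:3]; ang <- sqrt(sum(rotvec^2))
    R <- if (ang > 1e-12) rotation_matrix(rotvec, ang) else diag(3L)
    o_b <- as.numeric(R %*% (ax_b0$origin - cen_b)) + cen_b + params[4:6]
    u_b <- as.numeric(R %*% ax_b0$direction)
    cb_b <- as.numeric(R %*% (cb_b0 - cen_b)) + cen_b + params[4:6]
    s_a <- signed_angle_about(
      perp_unit(o_b - ax_a$origin, ax_a$direction),
      perp_unit(cb_a - ax_a$origin, ax_a$direction), ax_a$direction)
    s_b <- signed_angle_about(
      perp_unit(ax_a$origin - o_b, u_b),
      perp_unit(cb_b - o_b, u_b), u_b)
    wrap_angle(s_a - s_b)
  }

  objective <- function(params) {
    xb <- apply_rigid(xb0, params)
    dp2 <- sum((xa[pa, , drop = FALSE] - xb[pb, , drop = FALSE])^2)
    d2 <- pair_dist2(xa, xb)
    viol <- pmax(0, clash_cutoff + 0.1 - sqrt(pmax(d2, 0)))
    dp2 + 10000 * sum(viol^2) + w_sym * spin_asymmetry(params)^2
  }

  evaluate <- function(params) {
    xb <- apply_rigid(xb0, params)
    pair_d <- sqrt(rowSums((xa[pa, , drop = FALSE] -
                              xb[pb, , drop = FALSE])^2))
    min_d <- min_pair_distance(xa, xb)
    list(par = params, pair_d = pair_d, min_d = min_d,
         feasible = all(pair_d <= linkable_cutoff) &&
           min_d >= clash_cutoff - 1e-6,
         score = objective(params), pure = sum(pair_d^2))
  }
  better <- function(cand, best) {
    is.null(best) || (cand$feasible && !best$feasible) ||
      (cand$feasible == best$feasible && cand$score < best$score)
  }

  tilt_sd <- state$target_crossing_angle_hint %||% 25
  best <- NULL
  with_seed(seed, {
    for (k in seq_len(n_restarts)) {
      axis <- stats::rnorm(3); axis <- axis / max(vnorm(axis), 1e-9)
      tilt <- stats::rnorm(1, 0, tilt_sd)
      spin <- stats::runif(1, -180, 180)
      R0 <- rotation_matrix(axis, tilt) %*% rotation_matrix(c(0, 0, 1), spin)
      ang <- stats::runif(1, -pi, pi)
      p0 <- c(rotmat_to_rotvec(R0),
              9.5 * cos(ang), 9.5 * sin(ang), stats::rnorm(1, 0, 2))
      fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                          control = list(maxit = 600, reltol = 1e-8))
      cand <- evaluate(fit$par)
      if (better(cand, best)) best <- cand
    }
    for (k in seq_len(n_polish)) {
      p0 <- best$par + stats::rnorm(6L, 0, c(rep(2, 3L), rep(0.25, 3L)))
      fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                          control = list(maxit = 1200, reltol = 1e-12))
      cand <- evaluate(fit$par)
      if (better(cand, best)) best <- cand
    }
    fit <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 2500, reltol = 1e-13))
    cand <- evaluate(fit$par)
    if (better(cand, best)) best <- cand
  })
  if (!best$feasible)
    stop("docking failed to satisfy the crosslink constraint (<= ",
         linkable_cutoff, " A); best achieved pair distances: ",
         paste(sprintf("%.2f", best$pair_d), collapse = ", "),
         " A, min inter-monomer distance ", sprintf("%.2f", best$min_d))
  xb <- apply_rigid(xb0, best$par)
  mono_b <- set_coords(mono_b, xb)
  dimer <- md_structure(rbind(mono_a$atoms, mono_b$atoms),
                        title = sprintf("%s dimer fixture", state$label))
  attr(dimer, "dimer_state") <- state
  attr(dimer, "docking") <- list(seed = seed, params = best$par,
                                 pair_distances = best$pair_d,
                                 min_inter_distance = best$min_d,
                                 objective = best$pure)
  dimer
}

# rotation matrix -> rotation vector (axis * angle in degrees)
rotmat_to_rotvec <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-9) return(c(0, 0, 0))
  if (abs(ang - pi) < 1e-6) {
    # 180-degree rotation: axis from the largest diagonal of (R + I)/2
    B <- (R + diag(3L)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    i <- which.max(axis)
    if (axis[i] > 0) {
      axis <- B[, i] / axis[i]
    }
    return(unitv(axis) * 180)
  }
  axis <- c(R[3L, 2L] - R[2L, 3L],
            R[1L, 3L] - R[3L, 1L],
            R[2L, 1L] - R[1L, 2L]) / (2 * sin(ang))
  axis * ang * 180 / pi
}

#' Apply the A183I steric perturbation to a dimer fixture
#'
#' Renames residue 183 from alanine to isoleucine in both chains and adds a
#' pseudo side-chain atom 1.5 Angstrom beyond C-beta along the
#' C-alpha -> C-beta direction (one C-C bond length, standing in for the
#' bulkier isoleucine side chain). If the pseudo atom clashes with the
#' partner monomer, the fixture is re-docked from its current pose with the
#' clash constraint active, so the interface separation can only increase;
#' the crosslink-distance feasibility of the original state is *not*
#' re-imposed (the point of the perturbation is that it may be lost).
#'
#' @param dimer a dimer fixture from [build_dimer_fixture] with Ala183 in
#'   both chains.
#' @param clash_cutoff minimum allowed inter-monomer heavy-atom distance.
#' @return the mutated (possibly re-docked) [md_structure].
#' @export
apply_mutation_A183I <- function(dimer, clash_cutoff = CLASH_CUTOFF) {
  stopifnot(inherits(dimer, "md_structure"))
  at <- dimer$atoms
  for (ch in c("A", "B")) {
    sel <- at$chain_id == ch & at$residue_number == 183L
    if (!any(sel) || unique(at$residue_name[sel]) != "ALA")
      stop("residue 183 of chain ", ch, " is not alanine")
  }
  new_rows <- list()
  for (ch in c("A", "B")) {
    sel <- at$chain_id == ch & at$residue_number == 183L
    at$residue_name[sel] <- "ILE"
    ca <- as.numeric(at[at$chain_id == ch & at$residue_number == 183L &
                          at$atom_name == "CA", c("x", "y", "z")])
    cb <- as.numeric(at[at$chain_id == ch & at$residue_number == 183L &
                          at$atom_name == "CB", c("x", "y", "z")])
    pseudo <- cb + 1.5 * unitv(cb - ca)
    new_rows[[ch]] <- data.frame(
      atom_name = "CG1", element = "C", residue_name = "ILE",
      residue_number = 183L, chain_id = ch,
      x = pseudo[1L], y = pseudo[2L], z = pseudo[3L],
      stringsAsFactors = FALSE)
  }
  # insert pseudo atoms after each chain's CB 183
  out <- list()
  for (ch in unique(at$chain_id)) {
    block <- at[at$chain_id == ch, , drop = FALSE]
    i_cb <- which(block$residue_number == 183L & block$atom_name == "CB")
    out[[ch]] <- rbind(block[seq_len(i_cb), , drop = FALSE],
                       new_rows[[ch]],
                       block[-seq_len(i_cb), , drop = FALSE])
  }
  mut <- md_structure(do.call(rbind, out),
                      title = paste(dimer$title, "+ A183I"))
  attr(mut, "dimer_state") <- attr(dimer, "dimer_state")

  ia <- which(mut$atoms$chain_id == "A")
  ib <- which(mut$atoms$chain_id == "B")
  xyz <- coords_matrix(mut)
  if (min_pair_distance(xyz[ia, , drop = FALSE],
                        xyz[ib, , drop = FALSE]) >= clash_cutoff - 1e-6) {
    attr(mut, "redocked") <- FALSE
    return(mut)
  }
  # clash introduced: locally re-dock monomer B under the clash constraint
  state <- attr(dimer, "dimer_state")
  pairs <- if (!is.null(state)) state$crosslink_pairs else integer(0)
  xa <- xyz[ia, , drop = FALSE]
  xb0 <- xyz[ib, , drop = FALSE]
  mono_a <- md_structure(mut$atoms[ia, , drop = FALSE])
  mono_b <- md_structure(mut$atoms[ib, , drop = FALSE])
  pa <- vapply(pairs, function(r) cb_or_ca_index(mono_a, "A", r),
               integer(1L))
  pb <- vapply(pairs, function(r) cb_or_ca_index(mono_b, "B", r),
               integer(1L))
  objective <- function(params) {
    xb <- apply_rigid(xb0, params)
    dp2 <- if (length(pa))
      sum((xa[pa, , drop = FALSE] - xb[pb, , drop = FALSE])^2) else 0
    d2 <- pair_dist2(xa, xb)
    viol <- pmax(0, clash_cutoff + 0.1 - sqrt(pmax(d2, 0)))
    dp2 + 20000 * sum(viol^2)
  }
  fit <- stats::optim(rep(0, 6L), objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  xb <- apply_rigid(xb0, fit$par)
  if (min_pair_distance(xa, xb) < clash_cutoff - 1e-3)
    stop("re-docking after A183I failed to relieve the steric clash")
  mut$atoms[ib, c("x", "y", "z")] <- xb
  attr(mut, "redocked") <- TRUE
  mut
}
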