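# Brownian lipid dynamics: 2D Gaussian random walk of headgroup beads.

#' Parameters for the Brownian lipid simulator
#'
#' @param D lateral diffusion coefficient(s) in A^2/ps: a scalar or a named
#'   vector per lipid type.
#' @param timestep time between steps in ps.
#' @param n_steps number of steps.
#' @param enrichment_bias radial drift speed toward the protein centroid in
#'   A/ps: named vector per lipid type (types not named get 0).
#' @param seed integer seed.
#' @param save_every store every k-th frame (default 1; frame 0 is always
#'   stored).
#' @return a `brownian_params` list.
#' @export
brownian_params <- function(D, timestep, n_steps, enrichment_bias = NULL,
                            seed = 1L, save_every = 1L) {
  if (any(D < 0)) stop("diffusion coefficients must be >= 0")
  if (timestep <= 0) stop("timestep must be positive")
  structure(list(D = D, timestep = timestep, n_steps = as.integer(n_steps),
                 enrichment_bias = enrichment_bias, seed = seed,
                 save_every = as.integer(save_every)),
            class = "brownian_params")
}

#' Simulate a lipid-bead trajectory
#'
#' Each bead performs an independent 2D Gaussian random walk with per-step
#' lateral variance 2 D dt per dimension, wrapped into the periodic box.
#' For types with a positive enrichment bias (and a protein present), a
#' deterministic radial drift of `bias * dt` per step toward the protein's
#' lateral centroid is added (switched off within 4 A of the centroid), so
#' those types accumulate near the protein at steady state. The protein, if
#' given, is held static and included in the trajectory topology.
#'
#' Output is reproducible bit-for-bit for a given seed.
#'
#' @param membrane a membrane from [build_membrane].
#' @param params a [brownian_params].
#' @param protein optional [md_structure] placed in the box (centred
#'   laterally if `center_protein` is TRUE).
#' @param center_protein move the protein's lateral centroid to the box
#'   centre before simulating (default TRUE).
#' @return an [md_trajectory]; attribute `"ground_truth"` records the true
#'   per-type D and bias.
#' @export
simulate_lipid_trajectory <- function(membrane, params, protein = NULL,
                                      center_protein = TRUE) {
  stopifnot(inherits(membrane, "membrane"),
            inherits(params, "brownian_params"))
  lt <- membrane$lipid_table
  n <- nrow(lt)
  box <- membrane$box
  D_vec <- if (length(params$D) == 1L && is.null(names(params$D))) {
    rep(params$D, n)
  } else {
    miss <- setdiff(unique(lt$type), names(params$D))
    if (length(miss)) stop("no D given for type(s): ",
                           paste(miss, collapse = ", "))
    as.numeric(params$D[lt$type])
  }
  bias_vec <- rep(0, n)
  if (!is.null(params$enrichment_bias)) {
    nm <- intersect(names(params$enrichment_bias), unique(lt$type))
    for (ty in nm)
      bias_vec[lt$type == ty] <- params$enrichment_bias[[ty]]
  }
  if (all(bias_vec == 0)) protein_center <- NULL else {
    if (is.null(protein))
      stop("enrichment_bias needs a protein to drift toward")
    protein_center <- c(box[1L], box[2L]) / 2
  }

  prot_xyz <- NULL
  if (!is.null(protein)) {
    prot_xyz <- coords_matrix(protein)
    if (center_protein) {
      cen <- colMeans(prot_xyz)
      prot_xyz <- sweep(prot_xyz, 2L,
                        c(cen[1L] - box[1L] / 2, cen[2L] - box[2L] / 2, 0))
    }
  }

  pos <- as.matrix(membrane$structure$atoms[, c("x", "y")])
  sd_step <- sqrt(2 * D_vec * params$timestep)
  dt <- params$timestep
  keep <- unique(c(0L, seq_len(params$n_steps)[
    seq_len(params$n_steps) %% params$save_every == 0L]))
  frames <- vector("list", length(keep))
  z <- membrane$structure$atoms$z
  make_frame <- function(p) {
    lip <- cbind(p[, 1L], p[, 2L], z)
    if (is.null(prot_xyz)) lip else rbind(prot_xyz, lip)
  }
  frames[[1L]] <- make_frame(pos)
  fi <- 2L
  with_seed(params$seed, {
    for (step in seq_len(params$n_steps)) {
      disp <- matrix(stats::rnorm(2L * n), n, 2L) * sd_step
      if (!is.null(protein_center)) {
        dvec <- sweep(pos, 2L, protein_center)
        dvec <- dvec - round(dvec / box[1:2][col(dvec)]) * box[1:2][col(dvec)]
        r <- sqrt(rowSums(dvec^2))
        act <- bias_vec > 0 & r > 4
        if (any(act))
          disp[act, ] <- disp[act, ] -
            (bias_vec[act] * dt / r[act]) * dvec[act, , drop = FALSE]
      }
      pos <- pos + disp
      pos[, 1L] <- pos[, 1L] %% box[1L]
      pos[, 2L] <- pos[, 2L] %% box[2L]
      if (step %in% keep) {
        frames[[fi]] <- make_frame(pos)
        fi <- fi + 1L
      }
    }
  })
  topo_atoms <- membrane$structure$atoms
  if (!is.null(protein)) {
    pr <- protein$atoms
    pr[, c("x", "y", "z")] <- prot_xyz
    topo_atoms <- rbind(pr, topo_atoms)
  }
  topo <- md_structure(topo_atoms, title = "bilayer Brownian run")
  traj <- md_trajectory(topo, frames, times = keep * dt, box = box)
  attr(traj, "ground_truth") <- list(D = params$D,
                                     enrichment_bias = params$enrichment_bias,
                                     timestep = dt, seed = params$seed)
  attr(traj, "lipid_atom_offset") <- if (is.null(protein)) 0L else
    nrow(protein$atoms)
  traj
}
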