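# Scheduled monomer rotations: ground-truth trajectories for the
# rotation-angle collective variables.

#' Rotate dimer monomers along angle schedules
#'
#' Frame k holds the input dimer with monomer 1 rotated by
#' `alpha_schedule[k]` degrees about its own fitted principal axis (through
#' its C-alpha centroid, right-handed about the N->C direction) and monomer
#' 2 by `beta_schedule[k]`. Axes are fitted once, on the input dimer.
#'
#' @param dimer an [md_structure] with both monomer chains.
#' @param alpha_schedule,beta_schedule equal-length numeric vectors of
#'   rotation angles in degrees.
#' @param chains length-2 chain ids (default A, B).
#' @param frame_interval time between frames in ps (default 1).
#' @return an [md_trajectory] with one frame per schedule entry; attribute
#'   `"ground_truth"` records the schedules.
#' @export
simulate_cv_rotation <- function(dimer, alpha_schedule, beta_schedule,
                                 chains = c("A", "B"), frame_interval = 1) {
  stopifnot(inherits(dimer, "md_structure"))
  if (length(alpha_schedule) != length(beta_schedule))
    stop("schedules must have equal length")
  ax1 <- fit_helix_axis(dimer, chains[1L])
  ax2 <- fit_helix_axis(dimer, chains[2L])
  xyz <- coords_matrix(dimer)
  i1 <- which(dimer$atoms$chain_id == chains[1L])
  i2 <- which(dimer$atoms$chain_id == chains[2L])
  rotate_about <- function(x, axis, origin, angle) {
    if (abs(angle) < 1e-12) return(x)
    R <- rotation_matrix(axis, angle)
    sweep(sweep(x, 2L, origin) %*% t(R), 2L, origin, "+")
  }
  frames <- lapply(seq_along(alpha_schedule), function(k) {
    m <- xyz
    m[i1, ] <- rotate_about(m[i1, , drop = FALSE], ax1$direction,
                            ax1$origin, alpha_schedule[k])
    m[i2, ] <- rotate_about(m[i2, , drop = FALSE], ax2$direction,
                            ax2$origin, beta_schedule[k])
    m
  })
  traj <- md_trajectory(dimer, frames,
                        times = (seq_along(frames) - 1) * frame_interval)
  attr(traj, "ground_truth") <- list(alpha = alpha_schedule,
                                     beta = beta_schedule)
  traj
}
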