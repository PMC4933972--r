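# Analytic multi-basin free-energy surfaces with known ground truth.

#' Build an analytic Gaussian-basin free-energy surface
#'
#' The energy is a sum of negative Gaussians,
#' E(a, b) = -sum_i depth_i * exp(-d_i^2 / (2 width_i^2)),
#' shifted so the global minimum is zero. Basin parameters, the refined
#' (numeric) minima of the continuous surface and the continuous energy
#' function itself are attached as the `"ground_truth"` attribute, so path
#' and barrier analyses can be validated against closed-form values.
#'
#' @param basins list of basins, each `list(center = c(alpha, beta),
#'   depth, width)` (degrees, kcal/mol, degrees).
#' @param alpha_range,beta_range length-2 extents in degrees.
#' @param spacing grid spacing in degrees (default 1).
#' @return an [fes_grid] with a `"ground_truth"` attribute.
#' @export
make_analytic_fes <- function(basins, alpha_range = c(-30, 100),
                              beta_range = c(-30, 120), spacing = 1) {
  if (!length(basins)) stop("basin list must be non-empty")
  for (b in basins) {
    if (!all(c("center", "depth", "width") %in% names(b)))
      stop("each basin needs center, depth and width")
    if (b$depth <= 0 || b$width <= 0)
      stop("basin depth and width must be positive")
  }
  efun <- function(a, b) {
    e <- 0
    for (bs in basins) {
      d2 <- (a - bs$center[1L])^2 + (b - bs$center[2L])^2
      e <- e - bs$depth * exp(-d2 / (2 * bs$width^2))
    }
    e
  }
  alpha <- seq(alpha_range[1L], alpha_range[2L], by = spacing)
  beta <- seq(beta_range[1L], beta_range[2L], by = spacing)
  energy <- outer(alpha, beta, efun)
  grid <- fes_grid(alpha, beta, energy, shift_to_zero = TRUE)
  minima <- lapply(basins, function(bs) {
    opt <- stats::optim(bs$center, function(p) efun(p[1L], p[2L]),
                        method = "BFGS")
    list(center = opt$par, energy = opt$value)
  })
  attr(grid, "ground_truth") <- list(basins = basins, minima = minima,
                                     energy_function = efun,
                                     offset = grid$offset)
  grid
}

#' Six-state model surface over the rotation angles
#'
#' A ready-made basin layout mimicking a two-pathway-step landscape: four
#' low-energy states (I at the origin, II, IV, VI) connected through two
#' shallow high-energy intermediates (III, V), with the origin basin
#' deepest and the final basin 3.5 kcal/mol higher.
#'
#' @param spacing grid spacing in degrees.
#' @return an [fes_grid] from [make_analytic_fes].
#' @export
fes_six_state_surface <- function(spacing = 1) {
  basins <- list(
    list(center = c(0, 0),   depth = 8.0, width = 9),    # I
    list(center = c(30, 20), depth = 6.3, width = 7),    # II
    list(center = c(45, 28), depth = 4.0, width = 5),    # III
    list(center = c(60, 40), depth = 6.6, width = 7),    # IV
    list(center = c(66, 64), depth = 2.9, width = 5.5),  # V
    list(center = c(70, 90), depth = 4.5, width = 9)     # VI
  )
  make_analytic_fes(basins, alpha_range = c(-30, 100),
                    beta_range = c(-30, 120), spacing = spacing)
}
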