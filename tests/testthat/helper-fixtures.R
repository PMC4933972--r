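# Shared fixtures and independent oracles for the test suite.

# Docked dimer fixtures are expensive; build each (label, seed) once per run.
fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(label, seed = 1L) {
  key <- sprintf("%s_%d", label, seed)
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- build_dimer_fixture(label, seed = seed)
  fixture_cache[[key]]
}

struct_coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

one_frame_traj <- function(s) {
  md_trajectory(s, list(struct_coords(s)), times = 0)
}

frame_from <- function(traj, i) {
  s <- traj$topology
  m <- traj$coords[[i]]
  s$atoms$x <- m[, 1]; s$atoms$y <- m[, 2]; s$atoms$z <- m[, 3]
  s
}

# --- independent internal-coordinate chain builder -------------------------
# Used as the oracle for helicity: builds an N-CA-C backbone with prescribed
# phi/psi dihedrals via sequential atom placement (standard bond geometry).

nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  u <- c - b; u <- u / sqrt(sum(u^2))
  ab <- b - a
  n <- c(ab[2] * u[3] - ab[3] * u[2],
         ab[3] * u[1] - ab[1] * u[3],
         ab[1] * u[2] - ab[2] * u[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + u * d2[1] + m * d2[2] + n * d2[3]
}

build_phi_psi_chain <- function(phi, psi, chain_id = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- nerf_place(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, 60)
  for (i in 2:n) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2,
                         psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
  }
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(atom_name = c("N", "CA", "C"), element = c("N", "C", "C"),
               residue_name = "ALA", residue_number = i, chain_id = chain_id,
               x = c(N[i, 1], CA[i, 1], C[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3]),
               stringsAsFactors = FALSE)
  }))
  md_structure(rows)
}

# random analytic surface for path-dominance checks
random_surface <- function(seed) {
  set.seed(seed)
  k <- sample(2:5, 1)
  basins <- lapply(seq_len(k), function(i)
    list(center = runif(2, -35, 35), depth = runif(1, 2, 8),
         width = runif(1, 5, 12)))
  list(grid = make_analytic_fes(basins, alpha_range = c(-40, 40),
                                beta_range = c(-40, 40), spacing = 2),
       basins = basins)
}
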