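# Helpers to assemble small bead systems by hand.
toy_system <- function(lipid_xy, box = c(100, 100, 80),
                       protein_xy = c(50, 50), types = NULL,
                       leaflet = NULL) {
  n <- nrow(lipid_xy)
  types <- types %||% rep("PC", n)
  leaflet <- leaflet %||% rep("upper", n)
  atoms <- rbind(
    data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
               residue_number = 1L, chain_id = "P",
               x = protein_xy[1], y = protein_xy[2], z = 0,
               stringsAsFactors = FALSE),
    data.frame(atom_name = "P", element = "P", residue_name = types,
               residue_number = seq_len(n) + 1L,
               chain_id = ifelse(leaflet == "upper", "U", "L"),
               x = lipid_xy[, 1], y = lipid_xy[, 2],
               z = ifelse(leaflet == "upper", 18, -18),
               stringsAsFactors = FALSE))
  topo <- md_structure(atoms)
  lt <- data.frame(lipid_id = seq_len(n), type = types, leaflet = leaflet,
                   anionic = types %in% c("PI", "PS", "CL"),
                   area_weight = ifelse(types == "CL", 2, 1),
                   stringsAsFactors = FALSE)
  list(topo = topo, lipid_table = lt, box = box)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("centering removes drift and preserves relative geometry", {
  sys <- toy_system(cbind(c(20, 70, 40), c(30, 60, 80)))
  xyz <- struct_coords(sys$topo)
  frames <- lapply(0:4, function(k) {
    m <- xyz; m[, 1] <- (m[, 1] + k) %% 100; m
  })
  tr <- md_trajectory(sys$topo, frames, times = 0:4 * 1000, box = sys$box)
  attr(tr, "lipid_atom_offset") <- 1L
  cen <- center_and_dewrap(tr, protein_selection = "P")
  # protein centroid pinned at the box centre every frame
  for (i in 1:5)
    expect_equal(unname(cen$coords[[i]][1, 1:2]), c(50, 50),
                 tolerance = 1e-9)
  # already-centred, drift-free input is returned unchanged
  tr2 <- md_trajectory(sys$topo, list(xyz, xyz), times = c(0, 1000),
                       box = sys$box)
  cen2 <- center_and_dewrap(tr2, protein_selection = "P")
  expect_equal(cen2$coords[[1]], xyz)
  expect_equal(cen2$coords[[2]], xyz)
  # lipid positions relative to the protein unchanged by the drift
  rel0 <- sweep(cen$coords[[1]][-1, 1:2], 2, cen$coords[[1]][1, 1:2])
  rel4 <- sweep(cen$coords[[5]][-1, 1:2], 2, cen$coords[[5]][1, 1:2])
  expect_lt(max(abs(rel0 - rel4)), 1e-9)
  expect_error(center_and_dewrap(tr, NULL), "protein_selection")
})

test_that("unwrapped displacements are continuous across the boundary", {
  sys <- toy_system(cbind(99, 50))
  xyz <- struct_coords(sys$topo)
  frames <- lapply(0:3, function(k) {
    m <- xyz; m[2, 1] <- (99 + k * 1.0) %% 100; m
  })
  tr <- md_trajectory(sys$topo, frames, times = 0:3 * 1000, box = sys$box)
  attr(tr, "lipid_atom_offset") <- 1L
  cen <- center_and_dewrap(tr, protein_selection = "P")
  un <- attr(cen, "unwrapped")
  xs <- vapply(un, function(m) m[2, 1], numeric(1))
  expect_equal(diff(xs), rep(1.0, 3), tolerance = 1e-9)  # no box jumps
})

test_that("density maps conserve mass and localise point masses", {
  set.seed(31)
  n <- 200
  frames <- lapply(1:20, function(k) {
    sys0 <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    rbind(c(50, 50, 0), cbind(sys0, 18))
  })
  sys <- toy_system(cbind(runif(n, 0, 100), runif(n, 0, 100)))
  tr <- md_trajectory(sys$topo, frames, times = seq_len(20) * 100,
                      box = sys$box)
  attr(tr, "lipid_atom_offset") <- 1L
  dm <- density_map(tr, sys$lipid_table, "PC", window = c(0, 2),
                    spacing = 10)
  expect_equal(sum(dm$energy), n, tolerance = 1e-9)   # conservation
  # uniform lipids: no cell deviates more than 5 Poisson SDs from the mean
  m <- n / length(dm$energy)
  expect_lt(max(abs(dm$energy - m)), 5 * sqrt(m / 20))

  # all lipids of the type at one point -> a single occupied cell
  pt <- toy_system(cbind(rep(25, 5), rep(75, 5)))
  trp <- md_trajectory(pt$topo, list(struct_coords(pt$topo)), times = 0,
                       box = pt$box)
  attr(trp, "lipid_atom_offset") <- 1L
  dmp <- density_map(trp, pt$lipid_table, "PC", window = c(0, 1e-9),
                     spacing = 10)
  expect_equal(sum(dmp$energy > 0), 1L)
  expect_equal(max(dmp$energy), 5)
})

test_that("radial stoichiometry reproduces hand-counted discs", {
  # 2 CL + 3 PS + 1 PC inside the 20 A disc, extras outside
  xy <- rbind(c(55, 50), c(45, 50),          # CL inside
              c(50, 57), c(50, 43), c(58, 55),  # PS inside
              c(60, 50),                        # PC inside (10 A)
              c(90, 90), c(5, 95))              # PC outside
  sys <- toy_system(xy, types = c("CL", "CL", "PS", "PS", "PS", "PC",
                                  "PC", "PC"))
  tr <- md_trajectory(sys$topo, list(struct_coords(sys$topo)), times = 0,
                      box = sys$box)
  attr(tr, "lipid_atom_offset") <- 1L
  rep1 <- radial_stoichiometry(tr, sys$lipid_table, "P", cutoff = 20,
                               windows = list(c(0, 1e-9)))
  counts <- setNames(rep1$per_type$mean_count, rep1$per_type$type)
  expect_equal(counts[["CL"]], 2)
  expect_equal(counts[["PS"]], 3)
  expect_equal(counts[["PC"]], 1)
  expect_equal(unname(rep1$anionic_percent["mean"]),
               100 * (2 * 2 + 3 * 1) / (2 * 2 + 3 * 1 + 1 * 1))  # 87.5

  # empty disc
  far <- toy_system(cbind(c(5, 95), c(95, 5)), types = c("PC", "PS"))
  trf <- md_trajectory(far$topo, list(struct_coords(far$topo)), times = 0,
                       box = far$box)
  attr(trf, "lipid_atom_offset") <- 1L
  rep0 <- radial_stoichiometry(trf, far$lipid_table, "P", cutoff = 20,
                               windows = list(c(0, 1e-9)))
  expect_true(all(rep0$per_type$mean_count == 0))

  # stationary configuration across three windows: zero SD
  trs <- md_trajectory(sys$topo, rep(list(struct_coords(sys$topo)), 30),
                       times = seq(0, 29) * 1000, box = sys$box)
  attr(trs, "lipid_atom_offset") <- 1L
  rep3 <- radial_stoichiometry(trs, sys$lipid_table, "P", cutoff = 20,
                               windows = list(c(0, 9), c(10, 19),
                                              c(20, 29)))
  expect_true(all(rep3$per_type$sd_count == 0))
  expect_equal(unname(rep3$anionic_percent["sd"]), 0)
})

test_that("the CL area weight changes percentages but never raw counts", {
  xy <- rbind(c(55, 50), c(50, 57), c(60, 50))
  sys <- toy_system(xy, types = c("CL", "PS", "PC"))
  tr <- md_trajectory(sys$topo, list(struct_coords(sys$topo)), times = 0,
                      box = sys$box)
  attr(tr, "lipid_atom_offset") <- 1L
  with_weight <- radial_stoichiometry(tr, sys$lipid_table, "P",
                                      windows = list(c(0, 1e-9)))
  lt_flat <- sys$lipid_table
  lt_flat$area_weight <- 1
  without <- radial_stoichiometry(tr, lt_flat, "P",
                                  windows = list(c(0, 1e-9)))
  expect_equal(with_weight$per_type$mean_count, without$per_type$mean_count)
  expect_equal(unname(with_weight$anionic_percent["mean"]),
               100 * (2 + 1) / 4)
  expect_equal(unname(without$anionic_percent["mean"]), 100 * 2 / 3)
})

test_that("diffusion estimation handles degenerate motion correctly", {
  mem <- build_membrane(membrane_composition(c(PC = 1)), n_lipids = 20,
                        box_xy = 60, seed = 2)
  # immobile lipids
  tr0 <- simulate_lipid_trajectory(
    mem, brownian_params(D = 0, timestep = 10, n_steps = 200, seed = 1,
                         save_every = 2))
  est0 <- lateral_diffusion(tr0, mem$lipid_table, windows = list(c(0, 2)))
  expect_equal(est0$D_A2_per_ps, 0)
  # coherent linear drift: MSD ~ tau^2, flagged as a poor linear fit
  xyz0 <- struct_coords(mem$structure)
  frames <- lapply(0:100, function(k) {
    m <- xyz0; m[, 1] <- m[, 1] + 0.5 * k; m
  })
  topo <- mem$structure
  trd <- md_trajectory(topo, frames, times = 0:100 * 10,
                       box = mem$box)
  estd <- lateral_diffusion(trd, mem$lipid_table,
                            windows = list(c(0, 1)))
  expect_true(estd$poor_linear_fit)
  expect_lt(estd$mean_r2, 0.9)
  # too few lag points
  tr5 <- md_trajectory(topo, frames[1:8], times = 0:7 * 10, box = mem$box)
  expect_error(lateral_diffusion(tr5, mem$lipid_table,
                                 windows = list(c(0, 7e-2))),
               "fewer than 5 lag")
})

test_that("three-window diffusion estimates converge within 2 SD", {
  mem <- build_membrane(membrane_composition(c(PC = 1)), n_lipids = 100,
                        box_xy = 80, seed = 6)
  tr <- simulate_lipid_trajectory(
    mem, brownian_params(D = 0.05, timestep = 10, n_steps = 3000,
                         seed = 13))
  est <- lateral_diffusion(tr, mem$lipid_table,
                           windows = list(c(0, 10), c(10, 20), c(20, 30)))
  ds <- est$D_A2_per_ps
  sds <- est$D_sd_A2_per_ps
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(ds[i] - ds[j]), 2 * max(sds[i], sds[j]))
})
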