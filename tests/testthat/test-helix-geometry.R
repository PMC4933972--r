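test_that("helix axis fitting recovers direction with N->C sign", {
  h <- build_ideal_helix()
  ax <- fit_helix_axis(h, "A")
  expect_lt(sum(abs(ax$direction - c(0, 0, 1))), 0.1)
  expect_gt(ax$direction[3], 0.99)
  # a 90-degree rotation about x maps the axis to -y
  R <- memdimer:::rotation_matrix(c(1, 0, 0), 90)
  h2 <- h; h2$atoms[, c("x", "y", "z")] <- struct_coords(h) %*% t(R)
  ax2 <- fit_helix_axis(h2, "A")
  expect_lt(sum(abs(ax2$direction - as.numeric(R %*% ax$direction))), 1e-6)
  # too few residues
  tiny <- md_structure(h$atoms[h$atoms$residue_number <= 171, ])
  expect_error(fit_helix_axis(tiny, "A"), "at least 4")
  # reference vector is perpendicular to the axis
  expect_lt(abs(sum(ax$reference_vector * ax$direction)), 1e-6)
})

test_that("rotation CV is zero at the reference and recovers rotations", {
  dimer <- cached_fixture("intersected")
  cv0 <- rotation_cv(dimer, dimer)
  expect_equal(cv0$alpha, 0, tolerance = 1e-9)
  expect_equal(cv0$beta, 0, tolerance = 1e-9)

  set.seed(42)
  for (k in 1:12) {
    ab <- runif(2, -170, 170)
    tr <- simulate_cv_rotation(dimer, ab[1], ab[2])
    cv <- rotation_cv(frame_from(tr, 1), dimer)
    expect_lt(abs(cv$alpha - ab[1]), 2)
    expect_lt(abs(cv$beta - ab[2]), 2)
  }
})

test_that("rotation CV is invariant under global rigid motion", {
  dimer <- cached_fixture("intersected")
  tr <- simulate_cv_rotation(dimer, 40, -25)
  f <- frame_from(tr, 1)
  set.seed(7)
  R <- memdimer:::rotation_matrix(rnorm(3), runif(1, 0, 360))
  f2 <- f
  f2$atoms[, c("x", "y", "z")] <-
    sweep(struct_coords(f) %*% t(R), 2, c(5, -3, 11), "+")
  cv <- rotation_cv(f, dimer)
  cv2 <- rotation_cv(f2, dimer)
  expect_lt(abs(cv$alpha - cv2$alpha), 1e-6)
  expect_lt(abs(cv$beta - cv2$beta), 1e-6)
})

test_that("crossing angle reads analytic constructions and conventions", {
  h <- build_ideal_helix(chain_id = "A")
  hb <- build_ideal_helix(chain_id = "B")
  xyz <- struct_coords(hb)
  # exactly parallel copies
  hb0 <- hb; hb0$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(9, 0, 0), "+")
  d0 <- md_structure(rbind(h$atoms, hb0$atoms))
  expect_lt(abs(crossing_angle(d0)), 1e-6)
  # rotate the far helix +25 deg about the near-to-far (+x) direction:
  # a left-handed crossing, reported negative (the right-handed positive
  # sign is anchored by the GxxxA-spacing docked fixture)
  R <- memdimer:::rotation_matrix(c(1, 0, 0), 25)
  cen <- colMeans(xyz)
  hb1 <- hb
  hb1$atoms[, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen + c(9, 0, 0), "+")
  d1 <- md_structure(rbind(h$atoms, hb1$atoms))
  ang <- crossing_angle(d1)
  expect_equal(ang, -25, tolerance = 0.5)
  # mirroring the construction flips the handedness sign
  Rm <- memdimer:::rotation_matrix(c(1, 0, 0), -25)
  hb2 <- hb
  hb2$atoms[, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, cen) %*% t(Rm), 2, cen + c(9, 0, 0), "+")
  expect_equal(crossing_angle(md_structure(rbind(h$atoms, hb2$atoms))),
               25, tolerance = 0.5)
  # invariance under global rigid motion
  set.seed(11)
  Rg <- memdimer:::rotation_matrix(rnorm(3), runif(1, 0, 360))
  d2 <- d1
  d2$atoms[, c("x", "y", "z")] <-
    sweep(struct_coords(d1) %*% t(Rg), 2, c(-4, 8, 2), "+")
  expect_lt(abs(crossing_angle(d2) - ang), 1e-3)
})

test_that("docked fixtures show the packing-mode crossing angles", {
  expect_lt(abs(crossing_angle(cached_fixture("parallel"))), 15)
  ai <- crossing_angle(cached_fixture("intersected"))
  expect_gt(ai, 30); expect_lt(ai, 50)   # right-handed ~40 deg
})

test_that("backbone RMSD is a proper superposition metric", {
  h <- cached_fixture("intersected")
  expect_lt(backbone_rmsd(h, h), 1e-9)
  h2 <- h
  h2$atoms[, c("x", "y", "z")] <- sweep(struct_coords(h), 2, c(3, 4, 0), "+")
  expect_lt(backbone_rmsd(h2, h), 1e-9)
  set.seed(5)
  Rg <- memdimer:::rotation_matrix(rnorm(3), 133)
  h3 <- h
  h3$atoms[, c("x", "y", "z")] <- struct_coords(h) %*% t(Rg)
  expect_lt(backbone_rmsd(h3, h), 1e-9)
  small <- md_structure(h$atoms[1:30, ])
  expect_error(backbone_rmsd(small, h), "mismatch")
})

test_that("Kabsch superposition matches the bio3d oracle", {
  set.seed(99)
  for (k in 1:10) {
    P <- matrix(rnorm(60), 20, 3)
    Q <- P %*% t(memdimer:::rotation_matrix(rnorm(3), runif(1, 0, 360))) +
      matrix(rnorm(3), 20, 3, byrow = TRUE) + matrix(rnorm(60, 0, 0.5),
                                                     20, 3)
    mine <- memdimer:::kabsch_rmsd(P, Q)
    fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                           mobile = as.vector(t(P))))
    Pm <- matrix(fit, ncol = 3, byrow = TRUE)
    oracle <- sqrt(mean(rowSums((Pm - Q)^2)))
    expect_lt(abs(mine - oracle), 1e-6)
  }
})

test_that("helicity classifies canonical, strand and mixed chains", {
  a <- build_phi_psi_chain(rep(-57.8, 15), rep(-47, 15))
  expect_equal(helicity(a, "A"), 100)
  e <- build_phi_psi_chain(rep(-139, 15), rep(135, 15))
  expect_equal(helicity(e, "A"), 0)
  # 21 residues, last 10 at strand dihedrals: 10 of 19 assignable helical
  mix <- build_phi_psi_chain(c(rep(-57.8, 11), rep(-139, 10)),
                             c(rep(-47, 11), rep(135, 10)))
  expect_equal(helicity(mix, "A"), 100 * 10 / 19, tolerance = 1e-6)
  expect_error(helicity(a, "Z"), "not present")
  # rigid-body invariance and bounds
  set.seed(3)
  Rg <- memdimer:::rotation_matrix(rnorm(3), 72)
  a2 <- a; a2$atoms[, c("x", "y", "z")] <- struct_coords(a) %*% t(Rg) + 5
  expect_equal(helicity(a2, "A"), helicity(a, "A"), tolerance = 1e-9)
})

test_that("C-beta distance series implement the crosslink predicate", {
  iso <- cached_fixture("iso_parallel")
  reps <- cb_distance_series(iso, c(172, 186))
  expect_length(reps, 2L)
  for (r in reps) {
    expect_length(r$distance_series, 1L)
    expect_lte(r$distance_series, 7.0)
    expect_equal(r$linkable_fraction, 1)
  }
  # monomers pulled 30 A apart: far beyond linkable
  far <- iso
  ib <- far$atoms$chain_id == "B"
  far$atoms[ib, "x"] <- far$atoms[ib, "x"] + 30
  reps_far <- cb_distance_series(far, c(172, 186, 187))
  for (r in reps_far) {
    expect_gt(r$distance_series, 27)
    expect_equal(r$linkable_fraction, 0)
  }
  # glycine 179 falls back to C-alpha
  inter <- cached_fixture("intersected")
  expect_silent(cb_distance_series(inter, 179))
  expect_error(cb_distance_series(inter, 999), "lacks a unique")
})
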