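two_atom_frame <- function(d, elems = c("N", "O")) {
  md_structure(data.frame(
    atom_name = elems, element = substr(elems, 1, 1),
    residue_name = "ALA", residue_number = c(1L, 2L),
    chain_id = c("A", "B"), x = c(0, d), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

test_that("polar contacts respect the distance threshold and polarity", {
  expect_equal(nrow(detect_polar_contacts(two_atom_frame(3.5), 1L, 2L)), 1L)
  expect_equal(nrow(detect_polar_contacts(two_atom_frame(3.7), 1L, 2L)), 0L)
  # carbon pairs never count, however close
  cc <- two_atom_frame(3.0, elems = c("C", "CA"))
  expect_equal(nrow(detect_polar_contacts(cc, 1L, 2L)), 0L)
  expect_error(detect_polar_contacts(two_atom_frame(3), integer(0), 2L),
               "non-empty")
  # symmetry in the two partners
  f <- two_atom_frame(3.2)
  ab <- detect_polar_contacts(f, 1L, 2L)
  ba <- detect_polar_contacts(f, 2L, 1L)
  expect_equal(ab$distance, ba$distance)
})

test_that("event segmentation reproduces constructed contact patterns", {
  # 10 ns at 1 ps resolution, contact in every frame: one frequent event
  n <- 10000L
  s <- contact_events_from_series(rep(TRUE, n), seq_len(n) - 1)
  expect_equal(s$n_events, 1L)
  expect_equal(s$occupancy, 1)
  expect_equal(s$max_duration_ns, 10)
  expect_equal(s$class, "frequent")

  # 0.4 ns on, off, 0.3 ns on: two transient events
  ser <- c(rep(TRUE, 400), rep(FALSE, 300), rep(TRUE, 300))
  s2 <- contact_events_from_series(ser, seq_along(ser) - 1)
  expect_equal(s2$n_events, 2L)
  expect_equal(s2$max_duration_ns, 0.4)
  expect_equal(s2$events$duration_ns, c(0.4, 0.3))
  expect_equal(s2$class, "transient")

  # never in contact
  s0 <- contact_events_from_series(rep(FALSE, 100), 0:99)
  expect_equal(s0$n_events, 0L)
  expect_equal(s0$occupancy, 0)

  # optional gap bridging absorbs single-frame flicker
  fl <- c(rep(TRUE, 10), FALSE, rep(TRUE, 10))
  expect_equal(contact_events_from_series(fl, 0:20)$n_events, 2L)
  expect_equal(contact_events_from_series(fl, 0:20,
                                          gap_tolerance = 1L)$n_events, 1L)
})

test_that("the transient/frequent boundary is exact at 1 ns", {
  s999 <- contact_events_from_series(c(rep(TRUE, 999), FALSE),
                                     seq_len(1000) - 1)
  expect_equal(s999$max_duration_ns, 0.999)
  expect_equal(s999$class, "transient")
  s1000 <- contact_events_from_series(c(rep(TRUE, 1000), FALSE),
                                      seq_len(1001) - 1)
  expect_equal(s1000$max_duration_ns, 1.0)
  expect_equal(s1000$class, "frequent")
})

test_that("total event duration over trajectory length equals occupancy", {
  set.seed(17)
  for (k in 1:100) {
    n <- sample(50:400, 1)
    ser <- runif(n) < runif(1, 0.05, 0.95)
    s <- contact_events_from_series(ser, seq_len(n) - 1)
    expect_equal(sum(s$events$duration_ns) / s$total_ns, s$occupancy,
                 tolerance = 1e-12)
  }
})

test_that("contact time series work on simulated bead trajectories", {
  mem <- build_membrane(membrane_composition(c(PS = 1)), n_lipids = 12,
                        box_xy = 50, seed = 5)
  prot <- build_ideal_helix()
  tr <- simulate_lipid_trajectory(
    mem, brownian_params(D = 0.02, timestep = 10, n_steps = 100, seed = 8),
    protein = prot)
  prot_polar <- intersect(seq_len(nrow(prot$atoms)),
                          polar_atoms(tr$topology))
  lipid_first <- nrow(prot$atoms) + 1L
  cs <- contact_timeseries(tr, prot_polar, lipid_first)
  expect_s3_class(cs, "contact_summary")
  expect_true(cs$occupancy >= 0 && cs$occupancy <= 1)
  expect_error(contact_timeseries(tr, integer(0), lipid_first),
               "non-empty")
})

test_that("the interface map equals a brute-force recomputation", {
  set.seed(23)
  mk_frame <- function() {
    n <- 6
    data.frame(atom_name = rep(c("N", "O"), n),
               element = rep(c("N", "O"), n),
               residue_name = "ALA",
               residue_number = rep(1:n, each = 2),
               chain_id = rep(c("A", "B"), each = n),
               x = runif(2 * n, 0, 8), y = runif(2 * n, 0, 8),
               z = runif(2 * n, 0, 8), stringsAsFactors = FALSE)
  }
  at <- mk_frame()
  topo <- md_structure(at)
  frames <- lapply(1:3, function(k)
    as.matrix(at[, c("x", "y", "z")]) + matrix(rnorm(nrow(at) * 3, 0, 0.5),
                                               ncol = 3))
  tr <- md_trajectory(topo, frames, times = 0:2)
  m <- interface_contact_map(tr, "A", "B", threshold = 3.6)
  # brute force over frames, residues and atom pairs
  ia <- which(at$chain_id == "A"); ib <- which(at$chain_id == "B")
  res_a <- sort(unique(at$residue_number[ia]))
  res_b <- sort(unique(at$residue_number[ib]))
  ref <- matrix(0, length(res_a), length(res_b))
  for (f in frames) {
    for (p in seq_along(res_a)) for (q in seq_along(res_b)) {
      aa <- ia[at$residue_number[ia] == res_a[p]]
      bb <- ib[at$residue_number[ib] == res_b[q]]
      hit <- FALSE
      for (i in aa) for (j in bb)
        if (sqrt(sum((f[i, ] - f[j, ])^2)) <= 3.6) hit <- TRUE
      ref[p, q] <- ref[p, q] + hit
    }
  }
  expect_equal(unname(m), ref / 3)
})

test_that("dimer fixtures show interface contacts; separated monomers none", {
  fp <- cached_fixture("parallel")
  m <- interface_contact_map(one_frame_traj(fp))
  expect_gt(sum(m), 0)
  # contacts concentrate at this state's own crosslink-set residues
  expect_true(any(m[as.character(c(171, 178, 182, 185)),
                    as.character(c(171, 178, 182, 185))] > 0))
  far <- fp
  ib <- far$atoms$chain_id == "B"
  far$atoms[ib, "x"] <- far$atoms[ib, "x"] + 30
  m0 <- interface_contact_map(one_frame_traj(far))
  expect_true(all(m0 == 0))
  expect_error(interface_contact_map(one_frame_traj(fp), "A", "Z"),
               "missing")
})
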