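# Pipeline orchestration: generate -> analyze -> report with one config.
#
# The config defaults collect the analysis parameters in one reviewable
# block: 20 A radial cutoff, 3.6 A polar contacts, 7 A crosslink distance,
# 1 ns transient boundary, 20 degree path-extraction blocks.

#' Build a run configuration
#'
#' @param path optional YAML file; values found there override defaults,
#'   and `...` overrides both.
#' @param ... named overrides (nested lists merged shallowly per section).
#' @return a `run_config` list with sections `seeds`, `cutoffs`,
#'   `membrane`, `brownian`, `windows_ns`, `stages`, `out_dir`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seeds = list(fixtures = 1L, membrane = 101L, trajectory = 202L),
    cutoffs = list(radial = 20, polar_contact = 3.6, crosslink = 7.0,
                   transient_ns = 1.0, block_degrees = 20),
    membrane = list(n_lipids = 200L, box_xy = 110,
                    fractions = as.list(MOM_FRACTIONS)),
    brownian = list(D = list(PC = 8e-4, PE = 7e-4, PI = 6e-4, PS = 6e-4,
                             CL = 4e-4),
                    timestep = 10, n_steps = 3000, save_every = 10,
                    enrichment_bias = list(CL = 0.002, PS = 0.001,
                                           PI = 0.001)),
    windows_ns = list(c(0, 10), c(10, 20), c(20, 30)),
    stages = list(geometry = TRUE, lipids = TRUE, contacts = TRUE,
                  fes = TRUE),
    docking = list(n_restarts = 24L, n_polish = 8L),
    out_dir = "memdimer_run"
  )
  merge_cfg <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          !is.null(names(upd[[nm]])))
        base[[nm]] <- merge_cfg(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_cfg(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  if (length(dots)) cfg <- merge_cfg(cfg, dots)
  for (nm in names(cfg$cutoffs))
    if (cfg$cutoffs[[nm]] <= 0) stop("cutoff '", nm, "' must be positive")
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  fnv1a_hash(paste(utils::capture.output(utils::str(unclass(cfg))),
                   collapse = "\n"))
}

#' Generate the synthetic input bundle
#'
#' Writes the three dimer-state fixtures plus the A183I perturbation of the
#' iso-parallel fixture, a bilayer with a Brownian lipid trajectory around
#' the intersected dimer, two analytic free-energy surfaces, and a
#' ground-truth sidecar JSON.
#'
#' @param config a [run_config].
#' @param out_dir output directory (default from config).
#' @return invisibly, the manifest (named character vector of paths).
#' @export
run_generate <- function(config = run_config(), out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  manifest <- c()
  fixtures <- list()
  for (lab in names(CROSSLINK_PAIRS)) {
    fx <- build_dimer_fixture(lab, seed = config$seeds$fixtures,
                              n_restarts = config$docking$n_restarts,
                              n_polish = config$docking$n_polish)
    fixtures[[lab]] <- fx
    p <- file.path(out_dir, paste0(lab, ".pdb"))
    write_structure(fx, p)
    manifest[lab] <- p
  }
  mut <- apply_mutation_A183I(fixtures$iso_parallel)
  p <- file.path(out_dir, "iso_parallel_A183I.pdb")
  write_structure(mut, p)
  manifest["iso_parallel_A183I"] <- p

  comp <- membrane_composition(unlist(config$membrane$fractions))
  mem <- build_membrane(comp, n_lipids = config$membrane$n_lipids,
                        box_xy = config$membrane$box_xy,
                        seed = config$seeds$membrane)
  p <- file.path(out_dir, "membrane.pdb")
  write_structure(mem$structure, p)
  manifest["membrane"] <- p
  utils::write.csv(mem$lipid_table, file.path(out_dir, "lipid_table.csv"),
                   row.names = FALSE)
  manifest["lipid_table"] <- file.path(out_dir, "lipid_table.csv")

  bp <- brownian_params(D = unlist(config$brownian$D),
                        timestep = config$brownian$timestep,
                        n_steps = config$brownian$n_steps,
                        enrichment_bias =
                          unlist(config$brownian$enrichment_bias),
                        seed = config$seeds$trajectory,
                        save_every = config$brownian$save_every)
  traj <- simulate_lipid_trajectory(mem, bp, protein = fixtures$intersected)
  p <- file.path(out_dir, "trajectory.pdb")
  write_trajectory(traj, p)
  manifest["trajectory"] <- p

  g2 <- make_analytic_fes(
    list(list(center = c(0, 0), depth = 8, width = 9),
         list(center = c(70, 90), depth = 4.5, width = 9)),
    alpha_range = c(-30, 100), beta_range = c(-30, 120))
  p <- file.path(out_dir, "fes_double_well.dat")
  write_fes_grid(g2, p)
  manifest["fes_double_well"] <- p
  g6 <- fes_six_state_surface()
  p <- file.path(out_dir, "fes_six_state.dat")
  write_fes_grid(g6, p)
  manifest["fes_six_state"] <- p

  gt <- list(
    crosslink_pairs = CROSSLINK_PAIRS,
    diffusion_A2_per_ps = config$brownian$D,
    enrichment_bias = config$brownian$enrichment_bias,
    timestep_ps = config$brownian$timestep,
    fes_six_state_basins = attr(g6, "ground_truth")$basins,
    fes_double_well_basins = attr(g2, "ground_truth")$basins,
    seeds = config$seeds,
    config_hash = config_hash(config))
  p <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest["ground_truth"] <- p
  invisible(manifest)
}

#' Run the analysis stages on a generated bundle
#'
#' @param config a [run_config].
#' @param out_dir directory holding [run_generate] outputs; reports are
#'   written next to them.
#' @return invisibly, a named vector of report paths.
#' @export
run_analyze <- function(config = run_config(), out_dir = config$out_dir) {
  need <- c("intersected.pdb", "parallel.pdb", "iso_parallel.pdb")
  if (isTRUE(config$stages$lipids) || isTRUE(config$stages$contacts))
    need <- c(need, "membrane.pdb", "trajectory.pdb", "lipid_table.csv")
  if (isTRUE(config$stages$fes))
    need <- c(need, "fes_double_well.dat", "fes_six_state.dat")
  missing_files <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing_files))
    stop("missing input file(s): ", paste(missing_files, collapse = ", "),
         " — run run_generate() first")
  reports <- c()
  states <- c("intersected", "parallel", "iso_parallel")
  fx <- lapply(stats::setNames(states, states), function(s)
    read_structure(file.path(out_dir, paste0(s, ".pdb"))))
  if (file.exists(file.path(out_dir, "iso_parallel_A183I.pdb")))
    fx$iso_parallel_A183I <-
      read_structure(file.path(out_dir, "iso_parallel_A183I.pdb"))

  if (isTRUE(config$stages$geometry)) {
    rows <- lapply(names(fx), function(nm) {
      s <- fx[[nm]]
      cv <- rotation_cv(s, fx$intersected)
      data.frame(state = nm,
                 crossing_angle_deg = crossing_angle(s),
                 cv_alpha_deg = cv$alpha, cv_beta_deg = cv$beta,
                 helicity_A = helicity(s, "A"),
                 helicity_B = helicity(s, "B"),
                 rmsd_vs_intersected_A =
                   backbone_rmsd(s, fx$intersected),
                 stringsAsFactors = FALSE)
    })
    p <- file.path(out_dir, "geometry.csv")
    write_table(do.call(rbind, rows), p)
    reports["geometry"] <- p

    xrows <- list()
    for (nm in names(fx)) {
      for (st in names(CROSSLINK_PAIRS)) {
        reps <- cb_distance_series(fx[[nm]], CROSSLINK_PAIRS[[st]],
                                   threshold = config$cutoffs$crosslink)
        for (r in reps)
          xrows[[length(xrows) + 1L]] <- data.frame(
            state = nm, pair_set = st, residue = r$pair[1L],
            distance_A = r$distance_series[1L],
            linkable = r$distance_series[1L] <= config$cutoffs$crosslink,
            stringsAsFactors = FALSE)
      }
    }
    p <- file.path(out_dir, "crosslinks.csv")
    write_table(do.call(rbind, xrows), p)
    reports["crosslinks"] <- p
  }

  if (isTRUE(config$stages$lipids) || isTRUE(config$stages$contacts)) {
    lipid_table <- utils::read.csv(file.path(out_dir, "lipid_table.csv"),
                                   stringsAsFactors = FALSE)
    n_prot <- sum(!read_structure(
      file.path(out_dir, "trajectory.pdb"))$atoms$chain_id %in% c("U", "L"))
    traj <- read_trajectory(file.path(out_dir, "trajectory.pdb"),
                            frame_interval = config$brownian$timestep *
                              config$brownian$save_every,
                            box = c(config$membrane$box_xy,
                                    config$membrane$box_xy, 80))
    attr(traj, "lipid_atom_offset") <- n_prot
    prot_sel <- which(!traj$topology$atoms$chain_id %in% c("U", "L"))
    traj <- center_and_dewrap(traj, prot_sel)
  }

  if (isTRUE(config$stages$lipids)) {
    windows <- config$windows_ns
    stoich <- radial_stoichiometry(traj, lipid_table, prot_sel,
                                   cutoff = config$cutoffs$radial,
                                   windows = windows)
    p <- file.path(out_dir, "stoichiometry.csv")
    write_table(stoich$per_type, p)
    reports["stoichiometry"] <- p
    jsonlite::write_json(
      list(anionic_percent = as.list(stoich$anionic_percent),
           neutral_percent = as.list(stoich$neutral_percent),
           cutoff_A = stoich$cutoff),
      file.path(out_dir, "stoichiometry_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    reports["stoichiometry_summary"] <-
      file.path(out_dir, "stoichiometry_summary.json")

    diff_rep <- lateral_diffusion(traj, lipid_table, windows = windows)
    p <- file.path(out_dir, "diffusion.csv")
    write_table(diff_rep, p)
    reports["diffusion"] <- p

    dm <- density_map(traj, lipid_table, "CL",
                      window = c(windows[[length(windows)]][1L],
                                 windows[[length(windows)]][2L]))
    p <- file.path(out_dir, "density_CL.dat")
    write_fes_grid(dm, p)
    reports["density_CL"] <- p
  }

  if (isTRUE(config$stages$contacts)) {
    prot_polar <- intersect(prot_sel, polar_atoms(traj$topology))
    crows <- list()
    for (ty in sort(unique(lipid_table$type))) {
      ids <- lipid_atom_indices(traj, lipid_table)[lipid_table$type == ty]
      n_contact <- 0L; n_transient <- 0L; occ <- 0
      max_dur <- 0
      for (id in ids) {
        cs <- contact_timeseries(traj, prot_polar, id,
                                 threshold = config$cutoffs$polar_contact,
                                 transient_ns = config$cutoffs$transient_ns)
        if (cs$n_events > 0L) {
          n_contact <- n_contact + 1L
          if (cs$class == "transient") n_transient <- n_transient + 1L
          occ <- occ + cs$occupancy
          max_dur <- max(max_dur, cs$max_duration_ns)
        }
      }
      crows[[ty]] <- data.frame(
        type = ty, n_lipids_contacting = n_contact,
        n_transient = n_transient,
        n_frequent = n_contact - n_transient,
        mean_occupancy = if (n_contact) occ / n_contact else 0,
        max_duration_ns = max_dur, stringsAsFactors = FALSE)
    }
    p <- file.path(out_dir, "contacts.csv")
    write_table(do.call(rbind, crows), p)
    reports["contacts"] <- p
  }

  if (isTRUE(config$stages$fes)) {
    g6 <- read_fes_grid(file.path(out_dir, "fes_six_state.dat"))
    st <- detect_states(g6)
    path <- extract_block_minimum_path(
      g6, start = c(0, 0), end = c(70, 90),
      block_size = config$cutoffs$block_degrees)
    oracle <- minimax_cell_path(g6, c(0, 0), c(70, 90))
    bar <- barrier_analysis(oracle, st)
    p <- file.path(out_dir, "fes_path.csv")
    write_table(path$points, p)
    reports["fes_path"] <- p
    jsonlite::write_json(
      list(states = lapply(st, function(s)
        list(label = s$label, alpha = s$center[1L], beta = s$center[2L],
             free_energy = s$free_energy)),
        segments = bar$segments,
        overall_barrier = bar$overall_barrier,
        endpoint_delta_g = bar$endpoint_delta_g,
        block_bottleneck = path$bottleneck,
        oracle_bottleneck = oracle$bottleneck),
      file.path(out_dir, "fes_states.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    reports["fes_states"] <- file.path(out_dir, "fes_states.json")
  }

  meta <- list(config = unclass(config), config_hash = config_hash(config),
               package_version =
                 as.character(utils::packageVersion("memdimer")),
               reports = as.list(reports))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  reports["run_metadata"] <- file.path(out_dir, "run_metadata.json")
  invisible(reports)
}

#' Write a human-readable summary of an analysis run
#'
#' @param config a [run_config].
#' @param out_dir directory holding [run_analyze] outputs.
#' @return invisibly, the path of the markdown summary.
#' @export
run_report <- function(config = run_config(), out_dir = config$out_dir) {
  meta_path <- file.path(out_dir, "run_metadata.json")
  if (!file.exists(meta_path))
    stop("missing run_metadata.json — run run_analyze() first")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  lines <- c("# Helix-dimer membrane analysis summary", "",
             paste0("Config hash: `", meta$config_hash, "`"),
             paste0("Package version: ", meta$package_version), "")
  geom_path <- file.path(out_dir, "geometry.csv")
  if (file.exists(geom_path)) {
    g <- utils::read.csv(geom_path)
    lines <- c(lines, "## Dimer geometry", "",
               "| state | crossing angle (deg) | alpha (deg) | beta (deg) |",
               "|---|---|---|---|",
               sprintf("| %s | %.1f | %.1f | %.1f |", g$state,
                       g$crossing_angle_deg, g$cv_alpha_deg, g$cv_beta_deg),
               "")
  }
  xl_path <- file.path(out_dir, "crosslinks.csv")
  if (file.exists(xl_path)) {
    x <- utils::read.csv(xl_path)
    own <- x[mapply(function(s, p) identical(s, p), x$state, x$pair_set), ]
    lines <- c(lines, "## Crosslinkable pairs (own state)", "",
               "| state | residue | distance (A) | linkable |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %.2f | %s |", own$state, own$residue,
                       own$distance_A, own$linkable),
               "")
  }
  st_path <- file.path(out_dir, "stoichiometry.csv")
  if (file.exists(st_path)) {
    s <- utils::read.csv(st_path)
    js <- jsonlite::read_json(file.path(out_dir,
                                        "stoichiometry_summary.json"),
                              simplifyVector = TRUE)
    lines <- c(lines, "## Radial stoichiometry", "",
               sprintf("Anionic area-weighted percentage within %g A: %.1f +/- %.1f %%",
                       js$cutoff_A, js$anionic_percent$mean,
                       js$anionic_percent$sd), "",
               "| type | mean count | sd |", "|---|---|---|",
               sprintf("| %s | %.2f | %.2f |", s$type, s$mean_count,
                       s$sd_count), "")
  }
  df_path <- file.path(out_dir, "diffusion.csv")
  if (file.exists(df_path)) {
    d <- utils::read.csv(df_path)
    lines <- c(lines, "## Lateral diffusion (per window)", "",
               "| window (ns) | type | D (A^2/ps) | sd | D (cm^2/s) |",
               "|---|---|---|---|---|",
               sprintf("| %g-%g | %s | %.4g | %.4g | %.3g |",
                       d$window_start_ns, d$window_end_ns, d$type,
                       d$D_A2_per_ps, d$D_sd_A2_per_ps, d$D_cm2_per_s), "")
  }
  ct_path <- file.path(out_dir, "contacts.csv")
  if (file.exists(ct_path)) {
    cc <- utils::read.csv(ct_path)
    lines <- c(lines, "## Protein-lipid polar contacts", "",
               "| type | contacting | transient | frequent | max duration (ns) |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %d | %d | %.2f |", cc$type,
                       cc$n_lipids_contacting, cc$n_transient,
                       cc$n_frequent, cc$max_duration_ns), "")
  }
  fs_path <- file.path(out_dir, "fes_states.json")
  if (file.exists(fs_path)) {
    fs <- jsonlite::read_json(fs_path, simplifyVector = FALSE)
    lines <- c(lines, "## Free-energy landscape", "",
               "| state | alpha | beta | free energy (kcal/mol) |",
               "|---|---|---|---|",
               vapply(fs$states, function(s)
                 sprintf("| %s | %g | %g | %.2f |", s$label, s$alpha,
                         s$beta, s$free_energy), character(1L)),
               "",
               sprintf("Overall barrier: %.2f kcal/mol; endpoint dG: %.2f kcal/mol.",
                       fs$overall_barrier, fs$endpoint_delta_g), "")
  }
  out <- file.path(out_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
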