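# Trajectory container and readers (multi-model PDB natively, DCD via bio3d).

#' Construct a trajectory
#'
#' Ordered frames of coordinates over a fixed topology, with per-frame times
#' (ps) and orthorhombic box lengths (Angstrom).
#'
#' @param topology an [md_structure] defining the atoms.
#' @param coords list of n_atoms x 3 coordinate matrices, one per frame.
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @param box matrix (n_frames x 3) of box lengths, or a single length-3
#'   vector recycled over frames; NA for non-periodic systems.
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, times, box = NA) {
  stopifnot(inherits(topology, "md_structure"))
  n_atoms <- nrow(topology$atoms)
  if (!length(coords)) stop("trajectory needs at least one frame")
  ok <- vapply(coords, function(m) is.matrix(m) && nrow(m) == n_atoms &&
                 ncol(m) == 3L, logical(1L))
  if (!all(ok))
    stop("every frame must be an n_atoms x 3 matrix matching the topology (",
         n_atoms, " atoms)")
  if (length(times) != length(coords))
    stop("times length must equal the number of frames")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.matrix(box)) {
    if (nrow(box) != length(coords)) stop("box must have one row per frame")
  } else if (length(box) == 3L) {
    box <- matrix(box, length(coords), 3L, byrow = TRUE)
  } else {
    box <- matrix(NA_real_, length(coords), 3L)
  }
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = %.1f..%.1f ps\n",
              length(x$coords), nrow(x$topology$atoms),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) length(traj$coords)

frame_structure <- function(traj, i) {
  set_coords(traj$topology, traj$coords[[i]])
}

#' Read a trajectory
#'
#' Multi-model PDB files are read natively; `.dcd` files are read through
#' bio3d against a PDB topology. Frame times come from the `frame_interval`
#' argument (ps between frames) since neither format stores physical time
#' reliably.
#'
#' @param topology_path PDB file providing the topology.
#' @param traj_path trajectory file (`.pdb` multi-model or `.dcd`); when
#'   omitted, `topology_path` itself is read as a multi-model PDB.
#' @param frame_interval time between frames in ps (default 1).
#' @param box orthorhombic box lengths (length-3, Angstrom) or NA.
#' @return an [md_trajectory]; frame count is reported via `message()`.
#' @export
read_trajectory <- function(topology_path, traj_path = NULL,
                            frame_interval = 1, box = NA) {
  topo <- read_structure(topology_path)
  if (is.null(traj_path)) traj_path <- topology_path
  ext <- tolower(tools::file_ext(traj_path))
  if (ext == "pdb") {
    frames <- read_multimodel_pdb_coords(traj_path)
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(traj_path, verbose = FALSE)
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  } else {
    stop("unsupported trajectory format: .", ext,
         " (supported: multi-model .pdb, .dcd)")
  }
  n_atoms <- nrow(topo$atoms)
  bad <- which(vapply(frames, nrow, integer(1L)) != n_atoms)
  if (length(bad))
    stop("atom-count mismatch: topology has ", n_atoms, " atoms but frame ",
         bad[1L], " has ", nrow(frames[[bad[1L]]]))
  message(sprintf("read_trajectory: %d frames x %d atoms from %s",
                  length(frames), n_atoms, basename(traj_path)))
  md_trajectory(topo, frames,
                times = (seq_along(frames) - 1) * frame_interval, box = box)
}

# Parse MODEL/ENDMDL blocks of a PDB into a list of coordinate matrices.
read_multimodel_pdb_coords <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    idx_list <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) < length(model_starts))
      stop("truncated multi-model PDB: MODEL without matching ENDMDL in ",
           path)
    idx_list <- mapply(function(s, e) {
      ii <- which(is_atom)
      ii[ii > s & ii < e]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  lapply(idx_list, function(ii) {
    if (!length(ii)) stop("empty MODEL block in ", path)
    parse_coords_fields(lines[ii], path)
  })
}

parse_coords_fields <- function(atom_lines, path) {
  x <- suppressWarnings(as.numeric(substr(atom_lines, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 47L, 54L)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed ATOM record (coordinates) at line ", bad[1L],
         " of a model block in ", path)
  cbind(x, y, z)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an [md_trajectory].
#' @param path output path (.pdb).
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    m <- traj$coords[[i]]
    recs <- sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)),
      formatC(a$atom_name, width = 3, flag = "-"),
      a$residue_name, substr(a$chain_id, 1L, 1L), a$residue_number,
      m[, 1L], m[, 2L], m[, 3L], a$element)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
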