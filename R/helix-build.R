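# Ideal alpha-helix construction.
#
# Backbone atoms are placed in a per-residue cylindrical frame (radial,
# tangential, axial) using offsets extracted once from a canonical
# internal-coordinate alpha helix (phi = -57.8, psi = -47.0, omega = 180,
# standard bond lengths/angles). Because the helix is screw-symmetric the
# offsets are identical for every residue, so the construction places the
# helix axis exactly along +z with the requested rise and twist.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# (radial, tangential, axial) offsets from CA, Angstrom
HELIX_OFFSETS <- list(
  N  = c(-0.8745, -0.7332, -0.9071),
  C  = c(-0.8036,  0.7310,  1.0702),
  O  = c(-0.4791,  0.6670,  2.2559),
  CB = c( 0.8605,  0.9861, -0.7748)
)

# Default transmembrane helix: the Bax alpha9 segment, residues 169-189.
ALPHA9_SEQUENCE <- "TWQTVTIFVAGVLTASLTIWK"
ALPHA9_FIRST_RESIDUE <- 169L

#' Specify an ideal helix
#'
#' @param sequence one-letter amino-acid string; default is the Bax
#'   C-terminal transmembrane helix alpha9 (residues 169-189).
#' @param first_residue_number residue number of the first residue.
#' @param rise_per_residue axial rise per residue in Angstrom (default 1.5).
#' @param twist_per_residue rotation per residue in degrees (default 100).
#' @param radius C-alpha helix radius in Angstrom (default 2.3).
#' @return a `helix_spec` list.
#' @export
helix_spec <- function(sequence = ALPHA9_SEQUENCE,
                       first_residue_number = ALPHA9_FIRST_RESIDUE,
                       rise_per_residue = 1.5,
                       twist_per_residue = 100.0,
                       radius = 2.3) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  letters1 <- strsplit(sequence, "")[[1L]]
  unknown <- setdiff(letters1, names(AA1TO3))
  if (length(unknown))
    stop("unknown amino-acid letter(s): ", paste(unique(unknown),
                                                 collapse = ", "))
  structure(list(sequence = sequence,
                 first_residue_number = as.integer(first_residue_number),
                 rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 radius = radius),
            class = "helix_spec")
}

#' Build an ideal alpha helix
#'
#' Places backbone N, CA, C, O plus CB (for non-glycine residues) on a
#' canonical alpha helix whose axis is the +z axis, with CA(i) -> CA(i+1)
#' axial displacement equal to `rise_per_residue`.
#'
#' @param spec a [helix_spec].
#' @param chain_id chain identifier (default "A").
#' @return an [md_structure].
#' @export
build_ideal_helix <- function(spec = helix_spec(), chain_id = "A") {
  stopifnot(inherits(spec, "helix_spec"))
  letters1 <- strsplit(spec$sequence, "")[[1L]]
  n <- length(letters1)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- (i - 1L) * spec$twist_per_residue * pi / 180
    er <- c(cos(theta), sin(theta), 0)
    et <- c(-sin(theta), cos(theta), 0)
    ez <- c(0, 0, 1)
    ca <- spec$radius * er + c(0, 0, (i - 1L) * spec$rise_per_residue)
    place <- function(off) ca + off[1L] * er + off[2L] * et + off[3L] * ez
    atoms <- c("N", "CA", "C", "O")
    coords <- rbind(place(HELIX_OFFSETS$N), ca,
                    place(HELIX_OFFSETS$C), place(HELIX_OFFSETS$O))
    if (letters1[i] != "G") {
      atoms <- c(atoms, "CB")
      coords <- rbind(coords, place(HELIX_OFFSETS$CB))
    }
    rows[[i]] <- data.frame(
      atom_name = atoms,
      element = substr(atoms, 1L, 1L),
      residue_name = AA1TO3[[letters1[i]]],
      residue_number = spec$first_residue_number + i - 1L,
      chain_id = chain_id,
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE
    )
  }
  md_structure(do.call(rbind, rows),
               title = sprintf("ideal helix %s (%d-%d)", spec$sequence,
                               spec$first_residue_number,
                               spec$first_residue_number + n - 1L))
}
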