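# Synthetic mitochondrial-outer-membrane bilayer: headgroup-bead lipids.
#
# Lipids are single headgroup beads: every analysis in scope (density maps,
# radial stoichiometry, MSD diffusion, bead polar contacts) works on the
# headgroup position, so acyl tails are not represented. Cardiolipin's
# larger footprint enters through its area weight (2) in stoichiometry
# percentages, not through geometry.

MOM_FRACTIONS <- c(PC = 0.465, PE = 0.284, PI = 0.089, PS = 0.089,
                   CL = 0.073)
ANIONIC_TYPES <- c("PI", "PS", "CL")

#' Specify a membrane lipid composition
#'
#' Defaults to the mitochondrial-outer-membrane model mixture: 46.5% PC,
#' 28.4% PE, 8.9% PI, 8.9% PS and 7.3% cardiolipin (mole fractions). PI,
#' PS and CL are flagged anionic.
#'
#' @param fractions named numeric vector of mole fractions summing to 1.
#' @param anionic character vector of anionic type names.
#' @return a `membrane_composition` list.
#' @export
membrane_composition <- function(fractions = MOM_FRACTIONS,
                                 anionic = ANIONIC_TYPES) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be a named vector")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", sum(fractions), ")")
  if (any(fractions < 0)) stop("mole fractions must be non-negative")
  structure(list(fractions = fractions,
                 anionic = intersect(names(fractions), anionic)),
            class = "membrane_composition")
}

# Largest-remainder apportionment of n among the given fractions.
apportion_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Build a synthetic bilayer of headgroup beads
#'
#' Lipid type counts follow largest-remainder apportionment of the mole
#' fractions (so they sum exactly to `n_lipids`); lipids are split evenly
#' across two leaflets at z = +/- `half_thickness` and placed laterally at
#' random without overlap (periodic minimal-image separation of at least
#' `min_separation`).
#'
#' @param composition a [membrane_composition].
#' @param n_lipids total lipid count (even; split across leaflets).
#' @param box_xy lateral box edge in Angstrom.
#' @param seed integer seed (placement and leaflet assignment).
#' @param half_thickness headgroup plane |z| in Angstrom (default 18).
#' @param min_separation minimum lateral headgroup separation (default 6).
#' @param box_z box height in Angstrom (default 80).
#' @return a `membrane` list: `structure` ([md_structure], one "P" bead per
#'   lipid, chains U/L by leaflet), `lipid_table` (data.frame with lipid_id,
#'   type, leaflet, anionic, area_weight), `box` (length-3).
#' @export
build_membrane <- function(composition = membrane_composition(),
                           n_lipids, box_xy, seed = 1L,
                           half_thickness = 18, min_separation = 6,
                           box_z = 80) {
  stopifnot(inherits(composition, "membrane_composition"))
  if (n_lipids %% 2L != 0L)
    stop("n_lipids must be even (two leaflets); got ", n_lipids)
  counts <- apportion_counts(composition$fractions, n_lipids)
  # sanity: the box must plausibly hold n/2 disks of the exclusion radius
  if (box_xy^2 < (n_lipids / 2) * (min_separation^2))
    stop("box too small to place ", n_lipids / 2, " lipids per leaflet at ",
         min_separation, " A separation in a ", box_xy, " A box")
  types <- rep(names(counts), counts)
  with_seed(seed, {
    types <- sample(types)
    leaflet <- rep(c("upper", "lower"), each = n_lipids / 2)
    pos <- matrix(NA_real_, n_lipids, 2L)
    for (lf in c("upper", "lower")) {
      idx <- which(leaflet == lf)
      placed <- matrix(numeric(0), 0L, 2L)
      for (i in idx) {
        ok <- FALSE
        for (try in seq_len(4000L)) {
          p <- stats::runif(2L, 0, box_xy)
          if (!nrow(placed)) { ok <- TRUE; break }
          d <- sweep(placed, 2L, p)
          d <- d - round(d / box_xy) * box_xy   # minimal image
          if (min(rowSums(d^2)) >= min_separation^2) { ok <- TRUE; break }
        }
        if (!ok)
          stop("packing failed: could not place lipid ", i,
               " without overlap; enlarge box_xy")
        placed <- rbind(placed, p)
        pos[i, ] <- p
      }
    }
  })
  z <- ifelse(leaflet == "upper", half_thickness, -half_thickness)
  atoms <- data.frame(
    atom_name = "P", element = "P", residue_name = types,
    residue_number = seq_len(n_lipids),
    chain_id = ifelse(leaflet == "upper", "U", "L"),
    x = pos[, 1L], y = pos[, 2L], z = z,
    stringsAsFactors = FALSE)
  lipid_table <- data.frame(
    lipid_id = seq_len(n_lipids), type = types, leaflet = leaflet,
    anionic = types %in% composition$anionic,
    area_weight = ifelse(types == "CL", 2, 1),
    stringsAsFactors = FALSE)
  structure(list(structure = md_structure(atoms, title = "bilayer beads"),
                 lipid_table = lipid_table,
                 box = c(box_xy, box_xy, box_z),
                 composition = composition, seed = seed),
            class = "membrane")
}
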