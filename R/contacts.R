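# Polar-contact detection, occupancy/duration statistics, and the
# frequent/transient classification.

TRANSIENT_NS <- 1.0       # contacts with max duration below this are transient
POLAR_CONTACT_CUTOFF <- 3.6

#' Polar atoms of a structure
#'
#' Protein polar atoms are nitrogens and oxygens (backbone and side chain);
#' lipid headgroup beads (phosphorus "P" beads) count as polar sites.
#' Carbons and other apolar atoms never participate in polar contacts.
#'
#' @param s an [md_structure].
#' @return integer atom indices.
#' @export
polar_atoms <- function(s) {
  which(s$atoms$element %in% c("N", "O", "P"))
}

#' Detect polar contacts in one frame
#'
#' A contact is a pair of polar atoms, one from each set, at distance at
#' most `threshold` (default 3.6 Angstrom).
#'
#' @param frame an [md_structure].
#' @param set_a,set_b integer atom indices of the two polar-atom sets.
#' @param threshold contact cutoff in Angstrom.
#' @return data.frame of contacting pairs: `atom_a`, `atom_b`,
#'   `distance`.
#' @export
detect_polar_contacts <- function(frame, set_a, set_b,
                                  threshold = POLAR_CONTACT_CUTOFF) {
  stopifnot(inherits(frame, "md_structure"))
  if (!length(set_a) || !length(set_b))
    stop("polar-atom sets must be non-empty")
  pol <- polar_atoms(frame)
  set_a <- intersect(set_a, pol)
  set_b <- intersect(set_b, pol)
  if (!length(set_a) || !length(set_b))
    return(data.frame(atom_a = integer(0), atom_b = integer(0),
                      distance = numeric(0)))
  xyz <- coords_matrix(frame)
  d2 <- pair_dist2(xyz[set_a, , drop = FALSE], xyz[set_b, , drop = FALSE])
  hit <- which(d2 <= threshold^2, arr.ind = TRUE)
  data.frame(atom_a = set_a[hit[, 1L]], atom_b = set_b[hit[, 2L]],
             distance = sqrt(pmax(0, d2[hit])))
}

#' Contact time series, events and summary for one pair of groups
#'
#' Marks each frame as in contact when any polar atom of group A is within
#' `threshold` of any polar atom of group B, merges consecutive in-contact
#' frames into maximal events (zero gap tolerance by default), and
#' classifies the pair: transient when the longest event is shorter than
#' 1 ns, frequent otherwise.
#'
#' @param traj an [md_trajectory].
#' @param set_a,set_b integer atom indices (or chain-id vectors).
#' @param threshold contact cutoff in Angstrom.
#' @param gap_tolerance number of off frames bridged inside an event
#'   (default 0).
#' @param transient_ns class boundary on the maximum event duration in ns.
#' @return a `contact_summary`: `events` (data.frame start_ns, end_ns,
#'   duration_ns), `occupancy`, `n_events`, `max_duration_ns`, `class`,
#'   `in_contact` (logical per frame).
#' @export
contact_timeseries <- function(traj, set_a, set_b,
                               threshold = POLAR_CONTACT_CUTOFF,
                               gap_tolerance = 0L,
                               transient_ns = TRANSIENT_NS) {
  stopifnot(inherits(traj, "md_trajectory"))
  resolve <- function(sel) {
    if (is.character(sel))
      sel <- which(traj$topology$atoms$chain_id %in% sel)
    sel
  }
  set_a <- resolve(set_a); set_b <- resolve(set_b)
  pol <- polar_atoms(traj$topology)
  set_a <- intersect(set_a, pol); set_b <- intersect(set_b, pol)
  if (!length(set_a) || !length(set_b))
    stop("polar-atom sets must be non-empty")
  thr2 <- threshold^2
  in_contact <- vapply(traj$coords, function(m) {
    d2 <- pair_dist2(m[set_a, , drop = FALSE], m[set_b, , drop = FALSE])
    any(d2 <= thr2)
  }, logical(1L))
  contact_events_from_series(in_contact, traj$times,
                             gap_tolerance = gap_tolerance,
                             transient_ns = transient_ns)
}

#' Build contact events and summary from a per-frame boolean series
#'
#' Each maximal run of in-contact frames is one event; an event of k
#' frames spans k frame intervals of occupancy (duration = k * dt), so
#' that total event duration over trajectory length equals the occupancy
#' fraction exactly.
#'
#' @param in_contact logical vector, one entry per frame.
#' @param times frame times in ps (uniform spacing assumed for durations).
#' @param gap_tolerance number of off frames bridged inside an event.
#' @param transient_ns class boundary in ns.
#' @return a `contact_summary` (see [contact_timeseries]).
#' @export
contact_events_from_series <- function(in_contact, times,
                                       gap_tolerance = 0L,
                                       transient_ns = TRANSIENT_NS) {
  n <- length(in_contact)
  stopifnot(length(times) == n)
  dt <- if (n > 1L) stats::median(diff(times)) else 1
  series <- in_contact
  if (gap_tolerance > 0L && n > 2L) {
    r <- rle(series)
    off <- !r$values & r$lengths <= gap_tolerance
    # interior gaps only
    if (length(r$values) > 2L) {
      interior <- seq_along(r$values) > 1L &
        seq_along(r$values) < length(r$values)
      r$values[off & interior] <- TRUE
    }
    series <- inverse.rle(r)
  }
  r <- rle(series)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  events <- data.frame(
    start_ns = times[starts[on]] / 1000,
    end_ns = (times[ends[on]] + dt) / 1000,
    duration_ns = r$lengths[on] * dt / 1000)
  occupancy <- mean(in_contact)
  max_dur <- if (nrow(events)) max(events$duration_ns) else 0
  structure(list(events = events, occupancy = occupancy,
                 n_events = nrow(events), max_duration_ns = max_dur,
                 class = if (max_dur < transient_ns) "transient"
                         else "frequent",
                 in_contact = in_contact,
                 total_ns = n * dt / 1000),
            class = "contact_summary")
}

#' Inter-monomer residue-pair contact occupancy map
#'
#' Occupancy (fraction of frames) of polar contacts between every residue
#' of chain A and every residue of chain B.
#'
#' @param traj an [md_trajectory].
#' @param chain_a,chain_b chain ids.
#' @param threshold contact cutoff in Angstrom.
#' @return numeric matrix (residues of `chain_a` x residues of `chain_b`,
#'   dimnames = residue numbers).
#' @export
interface_contact_map <- function(traj, chain_a = "A", chain_b = "B",
                                  threshold = POLAR_CONTACT_CUTOFF) {
  at <- traj$topology$atoms
  if (!any(at$chain_id == chain_a)) stop("chain '", chain_a, "' missing")
  if (!any(at$chain_id == chain_b)) stop("chain '", chain_b, "' missing")
  pol <- polar_atoms(traj$topology)
  ia <- intersect(which(at$chain_id == chain_a), pol)
  ib <- intersect(which(at$chain_id == chain_b), pol)
  res_a <- sort(unique(at$residue_number[at$chain_id == chain_a]))
  res_b <- sort(unique(at$residue_number[at$chain_id == chain_b]))
  occ <- matrix(0, length(res_a), length(res_b),
                dimnames = list(res_a, res_b))
  if (!length(ia) || !length(ib)) return(occ)
  ra <- match(at$residue_number[ia], res_a)
  rb <- match(at$residue_number[ib], res_b)
  thr2 <- threshold^2
  for (m in traj$coords) {
    d2 <- pair_dist2(m[ia, , drop = FALSE], m[ib, , drop = FALSE])
    hit <- which(d2 <= thr2, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- unique(cbind(ra[hit[, 1L]], rb[hit[, 2L]]))
      occ[pairs] <- occ[pairs] + 1
    }
  }
  occ / n_frames(traj)
}
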