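# Lipid headgroup analyses: centering/dewrapping, density maps, radial
# stoichiometry and lateral diffusion from mean-square displacement.

lipid_atom_indices <- function(traj, lipid_table) {
  off <- attr(traj, "lipid_atom_offset") %||% 0L
  off + lipid_table$lipid_id
}

# Minimal-image lateral difference a - b under box lengths (bx, by).
mi_lateral <- function(dxy, box_xy) {
  dxy - round(dxy / rep(box_xy, each = nrow(dxy))) *
    rep(box_xy, each = nrow(dxy))
}

#' Centre the protein and unwrap periodic lipid displacements
#'
#' Shifts every frame so the protein centroid sits at the box centre
#' (removing the overall drift of the system), re-wraps lateral coordinates
#' by minimal image, and reconstructs continuous (unwrapped) lateral
#' displacements across the periodic boundary for later MSD use (stored in
#' the `"unwrapped"` attribute).
#'
#' @param traj an [md_trajectory] with a periodic box.
#' @param protein_selection integer atom indices of the protein (or a chain
#'   id vector); must be supplied.
#' @return the centred [md_trajectory] with an `"unwrapped"` attribute
#'   (list of n_atoms x 3 matrices).
#' @export
center_and_dewrap <- function(traj, protein_selection) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (missing(protein_selection) || is.null(protein_selection) ||
      !length(protein_selection))
    stop("protein_selection is required for centering")
  if (is.character(protein_selection))
    protein_selection <- which(traj$topology$atoms$chain_id %in%
                                 protein_selection)
  box <- traj$box[1L, ]
  if (any(!is.finite(box[1:2])))
    stop("centering requires a periodic box")
  # lateral centering only: the bilayer fixes the z frame
  target <- box[1:2] / 2
  centered <- lapply(seq_len(n_frames(traj)), function(i) {
    m <- traj$coords[[i]]
    cen <- colMeans(m[protein_selection, 1:2, drop = FALSE])
    m[, 1L] <- (m[, 1L] - (cen[1L] - target[1L])) %% box[1L]
    m[, 2L] <- (m[, 2L] - (cen[2L] - target[2L])) %% box[2L]
    m
  })
  out <- md_trajectory(traj$topology, centered, traj$times, traj$box)
  attr(out, "lipid_atom_offset") <- attr(traj, "lipid_atom_offset")
  attr(out, "ground_truth") <- attr(traj, "ground_truth")
  attr(out, "unwrapped") <- dewrap_frames(centered, box)
  out
}

# Accumulate minimal-image lateral increments into continuous coordinates.
dewrap_frames <- function(frames, box) {
  un <- vector("list", length(frames))
  un[[1L]] <- frames[[1L]]
  if (length(frames) > 1L) {
    for (i in 2L:length(frames)) {
      d <- frames[[i]] - frames[[i - 1L]]
      d[, 1L] <- d[, 1L] - round(d[, 1L] / box[1L]) * box[1L]
      d[, 2L] <- d[, 2L] - round(d[, 2L] / box[2L]) * box[2L]
      un[[i]] <- un[[i - 1L]] + d
    }
  }
  un
}

frames_in_window <- function(traj, window_ns) {
  idx <- which(traj$times >= window_ns[1L] * 1000 - 1e-9 &
                 traj$times <= window_ns[2L] * 1000 + 1e-9)
  if (!length(idx))
    stop("no frames in window [", window_ns[1L], ", ", window_ns[2L],
         "] ns")
  idx
}

#' Time-averaged lateral headgroup density map
#'
#' Bins headgroup positions of one lipid type on a lateral grid over the
#' box and averages over the frames of the window. The sum over cells
#' equals the mean in-box count of that type (conservation).
#'
#' @param traj a centred [md_trajectory].
#' @param lipid_table the membrane's lipid table.
#' @param type lipid type to map.
#' @param window `c(start, end)` in ns.
#' @param spacing grid spacing in Angstrom (default 1).
#' @return a `density_map` (also an [fes_grid], value = mean count per
#'   cell) with fields `type` and `window`.
#' @export
density_map <- function(traj, lipid_table, type, window, spacing = 1) {
  idx <- frames_in_window(traj, window)
  box <- traj$box[1L, ]
  sel <- lipid_atom_indices(traj, lipid_table)[lipid_table$type == type]
  if (!length(sel)) stop("no lipids of type ", type)
  nx <- max(1L, ceiling(box[1L] / spacing))
  ny <- max(1L, ceiling(box[2L] / spacing))
  counts <- matrix(0, nx, ny)
  for (i in idx) {
    m <- traj$coords[[i]][sel, , drop = FALSE]
    ix <- pmin(nx, pmax(1L, floor(m[, 1L] %% box[1L] / spacing) + 1L))
    iy <- pmin(ny, pmax(1L, floor(m[, 2L] %% box[2L] / spacing) + 1L))
    tab <- table(factor(ix, levels = seq_len(nx)),
                 factor(iy, levels = seq_len(ny)))
    counts <- counts + tab
  }
  counts <- counts / length(idx)
  g <- fes_grid((seq_len(nx) - 0.5) * spacing, (seq_len(ny) - 0.5) * spacing,
                counts, shift_to_zero = FALSE)
  g$type <- type
  g$window <- window
  class(g) <- c("density_map", class(g))
  g
}

#' Radial lipid stoichiometry around the dimer
#'
#' Counts, per lipid type and leaflet, the headgroups whose lateral
#' (minimal-image) distance to the dimer centroid is at most `cutoff`;
#' time-averages within each window, and reports mean +/- SD across
#' windows. The anionic area-weighted percentage uses the CL-counts-twice
#' rule: sum(weight x count, anionic) / sum(weight x count, all) x 100,
#' computed per leaflet and averaged.
#'
#' @param traj a centred [md_trajectory].
#' @param lipid_table the membrane's lipid table.
#' @param dimer_selection protein atom indices (or chain ids).
#' @param cutoff radial cutoff in Angstrom (default 20).
#' @param windows list of `c(start, end)` windows in ns.
#' @return a `stoichiometry_report`: `per_type` (data.frame of mean/sd
#'   counts), `anionic_percent`, `neutral_percent` (means and SDs),
#'   `per_window`, `cutoff`, `windows`.
#' @export
radial_stoichiometry <- function(traj, lipid_table, dimer_selection,
                                 cutoff = 20, windows = list(c(0, Inf))) {
  stopifnot(cutoff > 0)
  if (is.character(dimer_selection))
    dimer_selection <- which(traj$topology$atoms$chain_id %in%
                               dimer_selection)
  box <- traj$box[1L, ]
  sel <- lipid_atom_indices(traj, lipid_table)
  types <- sort(unique(lipid_table$type))
  leaflets <- sort(unique(lipid_table$leaflet))
  wt <- lipid_table$area_weight
  per_window <- list()
  for (w in seq_along(windows)) {
    idx <- frames_in_window(traj, windows[[w]])
    acc <- matrix(0, length(types), length(leaflets),
                  dimnames = list(types, leaflets))
    an_pct <- 0
    for (i in idx) {
      m <- traj$coords[[i]]
      cen <- colMeans(m[dimer_selection, 1:2, drop = FALSE])
      d <- mi_lateral(sweep(m[sel, 1:2, drop = FALSE], 2L, cen), box[1:2])
      inside <- sqrt(rowSums(d^2)) <= cutoff
      pct_leaf <- numeric(0)
      for (lf in leaflets) {
        in_lf <- inside & lipid_table$leaflet == lf
        for (ty in types)
          acc[ty, lf] <- acc[ty, lf] + sum(in_lf & lipid_table$type == ty)
        wa <- sum(wt[in_lf & lipid_table$anionic])
        wall <- sum(wt[in_lf])
        pct_leaf <- c(pct_leaf, if (wall > 0) 100 * wa / wall else NA_real_)
      }
      an_pct <- an_pct + mean(pct_leaf, na.rm = TRUE)
    }
    per_window[[w]] <- list(counts = acc / length(idx),
                            anionic_percent = an_pct / length(idx))
  }
  count_mat <- sapply(per_window, function(pw) rowSums(pw$counts))
  if (is.null(dim(count_mat)))
    count_mat <- matrix(count_mat, nrow = length(types),
                        dimnames = list(types, NULL))
  an <- vapply(per_window, function(pw) pw$anionic_percent, numeric(1L))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  per_type <- data.frame(
    type = types,
    mean_count = apply(count_mat, 1L, mean),
    sd_count = apply(count_mat, 1L, sd0),
    anionic = types %in% lipid_table$type[lipid_table$anionic],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_type = per_type,
                 anionic_percent = c(mean = mean(an), sd = sd0(an)),
                 neutral_percent = c(mean = 100 - mean(an), sd = sd0(an)),
                 per_window = per_window,
                 cutoff = cutoff, windows = windows),
            class = "stoichiometry_report")
}

#' Lateral diffusion coefficients from mean-square displacement
#'
#' Per lipid, the lateral MSD over lag time within each window (averaged
#' over all time origins) is fitted linearly over lags in `fit_range` of
#' the window length; the slope over 4 gives D (2D Einstein relation).
#' Per-type means and standard deviations are taken over molecules, and
#' each window is reported separately so convergence across windows can be
#' checked. The fit quality (R-squared of the through-origin fit, which is
#' exact for diffusive motion since MSD(0) = 0) is reported, with types
#' flagged when the mean R-squared drops below 0.9 (e.g. ballistic drift,
#' for which MSD grows quadratically).
#'
#' @param traj an [md_trajectory]; uses its `"unwrapped"` attribute when
#'   present (from [center_and_dewrap]), otherwise dewraps without
#'   centering.
#' @param lipid_table the membrane's lipid table.
#' @param windows list of `c(start, end)` windows in ns.
#' @param fit_range lag range as fractions of the window span.
#' @return data.frame with one row per window x type: D in A^2/ps (mean,
#'   sd over molecules) and cm^2/s, molecule count, mean R-squared and the
#'   poor-fit flag.
#' @export
lateral_diffusion <- function(traj, lipid_table, windows,
                              fit_range = c(0.1, 0.5)) {
  un <- attr(traj, "unwrapped")
  if (is.null(un)) un <- dewrap_frames(traj$coords, traj$box[1L, ])
  sel <- lipid_atom_indices(traj, lipid_table)
  types <- sort(unique(lipid_table$type))
  out <- list()
  for (w in seq_along(windows)) {
    idx <- frames_in_window(traj, windows[[w]])
    times <- traj$times[idx]
    L <- length(idx)
    x <- sapply(un[idx], function(m) m[sel, 1L])  # n x L after transpose
    y <- sapply(un[idx], function(m) m[sel, 2L])
    lag_min <- max(1L, floor(fit_range[1L] * (L - 1L)))
    lag_max <- max(lag_min, floor(fit_range[2L] * (L - 1L)))
    lags <- lag_min:lag_max
    if (length(lags) < 5L)
      stop("fewer than 5 lag points in window ", w,
           "; use a longer window or finer frames")
    msd <- matrix(NA_real_, length(sel), length(lags))
    for (j in seq_along(lags)) {
      l <- lags[j]
      dx <- x[, (1L + l):L, drop = FALSE] - x[, 1L:(L - l), drop = FALSE]
      dy <- y[, (1L + l):L, drop = FALSE] - y[, 1L:(L - l), drop = FALSE]
      msd[, j] <- rowMeans(dx^2 + dy^2)
    }
    tau <- (times[1L + lags] - times[1L])
    # least-squares with intercept for the slope (per molecule)
    txc <- tau - mean(tau)
    slope <- (msd %*% txc) / sum(txc^2)
    D_mol <- as.vector(slope) / 4
    for (ty in types) {
      ii <- which(lipid_table$type == ty)
      Dm <- mean(D_mol[ii]); Ds <- if (length(ii) > 1L)
        stats::sd(D_mol[ii]) else 0
      # fit quality on the type-averaged MSD; the through-origin line is
      # exact for diffusive motion (MSD(0) = 0, MSD linear in lag)
      msd_ty <- colMeans(msd[ii, , drop = FALSE])
      b0 <- sum(msd_ty * tau) / sum(tau^2)
      ss_tot <- sum((msd_ty - mean(msd_ty))^2)
      r2 <- if (ss_tot > 0)
        1 - sum((msd_ty - b0 * tau)^2) / ss_tot else 1
      out[[length(out) + 1L]] <- data.frame(
        window_start_ns = windows[[w]][1L],
        window_end_ns = windows[[w]][2L],
        type = ty, n_molecules = length(ii),
        D_A2_per_ps = Dm, D_sd_A2_per_ps = Ds,
        D_cm2_per_s = Dm * 1e-4, D_sd_cm2_per_s = Ds * 1e-4,
        mean_r2 = r2,
        poor_linear_fit = r2 < 0.9,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
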