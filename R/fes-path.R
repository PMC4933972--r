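# Free-energy landscape analysis: basin/state detection, block-minimum
# minimum-free-energy path extraction, a cell-resolution minimax oracle,
# and barrier analysis.

roman <- function(i) as.character(utils::as.roman(i))

# 8-connected neighbour offsets
NEIGH8 <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Detect low-energy states (basins) on a free-energy grid
#'
#' Local minima on the 8-connected grid seed basins; every cell is assigned
#' to a basin by steepest descent; minima whose depth (lowest boundary
#' saddle to a deeper neighbouring basin, minus the minimum energy) is
#' below `min_depth` are merged into that neighbour. States are labelled
#' with roman numerals in order of increasing minimum energy.
#'
#' @param grid an [fes_grid].
#' @param min_depth merge threshold in kcal/mol (default 0.5).
#' @param energy_ceiling ignore minima above `global min + energy_ceiling`
#'   (default Inf).
#' @return list of `state` lists: `label`, `center` (alpha, beta),
#'   `free_energy`, `cells` (matrix of i, j), `min_cell`; the basin map is
#'   attached as attribute `"basin_map"`.
#' @export
detect_states <- function(grid, min_depth = 0.5, energy_ceiling = Inf) {
  stopifnot(inherits(grid, "fes_grid"))
  E <- grid$energy
  na <- nrow(E); nb <- ncol(E)
  if (max(E) - min(E) < 1e-12) {
    warning("constant energy grid: single degenerate state")
    return(structure(list(list(
      label = "I", center = c(mean(grid$alpha), mean(grid$beta)),
      free_energy = E[1L], cells = as.matrix(expand.grid(seq_len(na),
                                                         seq_len(nb))),
      min_cell = c(1L, 1L))),
      basin_map = matrix(1L, na, nb)))
  }
  # steepest-descent target for every cell; exact-value ties broken toward
  # the lower linear index so plateaus drain to a single representative
  pad <- matrix(Inf, na + 2L, nb + 2L)
  pad[2:(na + 1L), 2:(nb + 1L)] <- E
  self_idx <- matrix(seq_along(E), na, nb)
  ipad <- matrix(NA_integer_, na + 2L, nb + 2L)
  ipad[2:(na + 1L), 2:(nb + 1L)] <- self_idx
  best_val <- E
  best_idx <- self_idx
  for (k in seq_len(nrow(NEIGH8))) {
    nv <- pad[2:(na + 1L) + NEIGH8[k, 1L], 2:(nb + 1L) + NEIGH8[k, 2L]]
    ni <- ipad[2:(na + 1L) + NEIGH8[k, 1L], 2:(nb + 1L) + NEIGH8[k, 2L]]
    upd <- nv < best_val | (nv == best_val & !is.na(ni) & ni < best_idx)
    upd[is.na(upd)] <- FALSE
    best_val[upd] <- nv[upd]
    best_idx[upd] <- ni[upd]
  }
  succ <- as.vector(best_idx)
  minima <- which(succ == seq_along(succ))
  # follow descent by pointer jumping (vectorised)
  repeat {
    succ2 <- succ[succ]
    if (identical(succ2, succ)) break
    succ <- succ2
  }
  basin <- matrix(match(succ, minima), na, nb)
  min_ij <- arrayInd(minima, dim(E))
  min_e <- E[minima]
  # merge shallow basins into the neighbour over their lowest saddle
  M <- length(minima)
  bpad <- matrix(NA_integer_, na + 2L, nb + 2L)
  repeat {
    labs <- sort(unique(as.vector(basin)))
    if (length(labs) <= 1L) break
    # boundary saddle between basin pairs: lowest max(cell, neighbour)
    # energy over the shared boundary (vectorised over all 8 directions)
    keys <- integer(0); vals <- numeric(0)
    bpad[2:(na + 1L), 2:(nb + 1L)] <- basin
    for (k in seq_len(nrow(NEIGH8))) {
      nbb <- bpad[2:(na + 1L) + NEIGH8[k, 1L], 2:(nb + 1L) + NEIGH8[k, 2L]]
      epad <- pad[2:(na + 1L) + NEIGH8[k, 1L], 2:(nb + 1L) + NEIGH8[k, 2L]]
      sel <- which(!is.na(nbb) & nbb != basin)
      if (length(sel)) {
        keys <- c(keys, basin[sel] * (M + 1L) + nbb[sel])
        vals <- c(vals, pmax(E[sel], epad[sel]))
      }
    }
    smin <- tapply(vals, keys, min)
    key_ab <- as.integer(names(smin))
    sa <- key_ab %/% (M + 1L); sb_ <- key_ab %% (M + 1L)
    saddle <- matrix(Inf, M, M)
    saddle[cbind(sa, sb_)] <- pmin(saddle[cbind(sa, sb_)], smin)
    saddle <- pmin(saddle, t(saddle))
    e_of <- rep(Inf, M); e_of[seq_along(min_e)] <- min_e
    depth <- vapply(labs, function(l) {
      deeper <- labs[e_of[labs] < e_of[l]]
      if (!length(deeper)) return(Inf)
      min(saddle[l, deeper]) - e_of[l]
    }, numeric(1L))
    shallow <- labs[depth < min_depth & is.finite(depth)]
    if (!length(shallow)) break
    l <- shallow[which.min(depth[match(shallow, labs)])]
    deeper <- labs[e_of[labs] < e_of[l]]
    target <- deeper[which.min(saddle[l, deeper])]
    basin[basin == l] <- target
  }
  labs <- sort(unique(as.vector(basin)))
  labs <- labs[min_e[labs] <= min(E) + energy_ceiling]
  if (!length(labs))
    stop("no state minimum lies below the energy ceiling")
  ord <- labs[order(min_e[labs])]
  states <- lapply(seq_along(ord), function(r) {
    l <- ord[r]
    cells <- which(basin == l, arr.ind = TRUE)
    mc <- min_ij[l, ]
    list(label = roman(r),
         center = c(grid$alpha[mc[1L]], grid$beta[mc[2L]]),
         free_energy = E[mc[1L], mc[2L]],
         cells = cells, min_cell = mc)
  })
  relabel <- match(basin, ord)
  attr(states, "basin_map") <- matrix(relabel, na, nb)
  states
}

# index of the grid cell nearest a point c(alpha, beta)
nearest_cell <- function(grid, point) {
  c(which.min(abs(grid$alpha - point[1L])),
    which.min(abs(grid$beta - point[2L])))
}

#' Block-minimum minimum-free-energy path
#'
#' Tiles the landscape into blocks of `block_size` degrees (default 20 x
#' 20), takes the minimum-energy cell of each block as that block's
#' candidate point, and chains candidate points from the start block to
#' the end block through 8-connected block moves, minimising the maximum
#' candidate energy en route (ties broken by total energy, then by
#' lexicographic block index).
#'
#' @param grid an [fes_grid].
#' @param start,end `c(alpha, beta)` endpoints in degrees.
#' @param block_size block edge in degrees (default 20).
#' @return a `fes_path`: data.frame `points` (alpha, beta, energy),
#'   `bottleneck` (max energy), `method`.
#' @export
extract_block_minimum_path <- function(grid, start, end, block_size = 20) {
  stopifnot(inherits(grid, "fes_grid"))
  sp <- diff(grid$alpha[1:2])
  cells_per <- max(1L, round(block_size / sp))
  na <- length(grid$alpha); nb <- length(grid$beta)
  bi <- (seq_len(na) - 1L) %/% cells_per + 1L
  bj <- (seq_len(nb) - 1L) %/% cells_per + 1L
  nbi <- max(bi); nbj <- max(bj)
  cand_e <- matrix(Inf, nbi, nbj)
  cand_i <- matrix(NA_integer_, nbi, nbj)
  cand_j <- matrix(NA_integer_, nbi, nbj)
  for (a in seq_len(nbi)) {
    ii <- which(bi == a)
    for (b in seq_len(nbj)) {
      jj <- which(bj == b)
      sub <- grid$energy[ii, jj, drop = FALSE]
      m <- arrayInd(which.min(sub), dim(sub))
      cand_e[a, b] <- sub[m]
      cand_i[a, b] <- ii[m[1L]]
      cand_j[a, b] <- jj[m[2L]]
    }
  }
  sb <- c(bi[nearest_cell(grid, start)[1L]], bj[nearest_cell(grid, start)[2L]])
  eb <- c(bi[nearest_cell(grid, end)[1L]], bj[nearest_cell(grid, end)[2L]])
  if (all(sb == eb)) {
    # both endpoints in one block: route start -> block candidate -> end
    sc <- nearest_cell(grid, start)
    ec <- nearest_cell(grid, end)
    if (all(sc == ec)) {
      pts <- data.frame(alpha = grid$alpha[sc[1L]], beta = grid$beta[sc[2L]],
                        energy = grid$energy[sc[1L], sc[2L]])
      return(structure(list(points = pts, bottleneck = pts$energy,
                            method = "block_minimum"),
                       class = "fes_path"))
    }
    cc <- c(cand_i[sb[1L], sb[2L]], cand_j[sb[1L], sb[2L]])
    route <- rbind(line_cells(sc, cc), line_cells(cc, ec))
    ci <- c(sc[1L], cc[1L], ec[1L])
    cj <- c(sc[2L], cc[2L], ec[2L])
    keep <- c(TRUE, ci[-1L] != ci[-3L] | cj[-1L] != cj[-3L])
    pts <- data.frame(alpha = grid$alpha[ci[keep]],
                      beta = grid$beta[cj[keep]],
                      energy = grid$energy[cbind(ci[keep], cj[keep])])
    return(structure(list(points = pts,
                          bottleneck = max(grid$energy[route]),
                          method = "block_minimum"),
                     class = "fes_path"))
  }
  # edge weight between adjacent blocks: maximum grid energy along the
  # straight cell-line connecting the two candidate cells (so the reported
  # bottleneck reflects the terrain actually crossed between the extracted
  # points, and dominates the cell-resolution minimax bottleneck)
  nodes <- which(is.finite(cand_e))
  node_ij <- arrayInd(nodes, dim(cand_e))
  node_id <- matrix(NA_integer_, nbi, nbj)
  node_id[nodes] <- seq_along(nodes)
  edges <- list()
  for (q in seq_along(nodes)) {
    a <- node_ij[q, 1L]; b <- node_ij[q, 2L]
    for (k in seq_len(nrow(NEIGH8))) {
      a2 <- a + NEIGH8[k, 1L]; b2 <- b + NEIGH8[k, 2L]
      if (a2 < 1L || a2 > nbi || b2 < 1L || b2 > nbj) next
      q2 <- node_id[a2, b2]
      if (is.na(q2) || q2 <= q) next
      seg <- line_cells(c(cand_i[a, b], cand_j[a, b]),
                        c(cand_i[a2, b2], cand_j[a2, b2]))
      w <- max(grid$energy[seg])
      edges[[length(edges) + 1L]] <- c(q, q2, w)
    }
  }
  edges <- do.call(rbind, edges)
  s_id <- node_id[sb[1L], sb[2L]]
  e_id <- node_id[eb[1L], eb[2L]]
  path_nodes <- minimax_graph_path(length(nodes), edges, s_id, e_id,
                                   node_energy = cand_e[nodes])
  path_blocks <- node_ij[path_nodes, , drop = FALSE]
  seg_max <- if (length(path_nodes) < 2L) {
    cand_e[nodes[path_nodes[1L]]]
  } else {
    vapply(seq_len(length(path_nodes) - 1L), function(q) {
      u <- path_blocks[q, ]; v <- path_blocks[q + 1L, ]
      seg <- line_cells(c(cand_i[u[1L], u[2L]], cand_j[u[1L], u[2L]]),
                        c(cand_i[v[1L], v[2L]], cand_j[v[1L], v[2L]]))
      max(grid$energy[seg])
    }, numeric(1L))
  }
  ci <- cand_i[cbind(path_blocks[, 1L], path_blocks[, 2L])]
  cj <- cand_j[cbind(path_blocks[, 1L], path_blocks[, 2L])]
  # the route runs from the true start cell through the chain of block
  # candidates to the true end cell; include the end-segments so the
  # reported bottleneck covers the whole connecting route
  sc <- nearest_cell(grid, start)
  ec <- nearest_cell(grid, end)
  head_max <- max(grid$energy[line_cells(sc, c(ci[1L], cj[1L]))])
  nlast <- length(ci)
  tail_max <- max(grid$energy[line_cells(c(ci[nlast], cj[nlast]), ec)])
  ci <- c(sc[1L], ci, ec[1L])
  cj <- c(sc[2L], cj, ec[2L])
  keep <- c(TRUE, ci[-1L] != ci[-length(ci)] | cj[-1L] != cj[-length(cj)])
  ci <- ci[keep]; cj <- cj[keep]
  pts <- data.frame(
    alpha = grid$alpha[ci],
    beta = grid$beta[cj],
    energy = grid$energy[cbind(ci, cj)])
  structure(list(points = pts,
                 bottleneck = max(c(pts$energy, seg_max, head_max,
                                    tail_max)),
                 segment_max = seg_max, method = "block_minimum"),
            class = "fes_path")
}

# cells of the straight line between two grid cells (supercover walk)
line_cells <- function(a, b) {
  n <- max(abs(b - a)) + 1L
  ii <- round(seq(a[1L], b[1L], length.out = n))
  jj <- round(seq(a[2L], b[2L], length.out = n))
  cbind(ii, jj)
}

# minimax path on a small node/edge graph; ties broken by total node
# energy along the path, then by node index (deterministic).
minimax_graph_path <- function(n_nodes, edges, s, e, node_energy) {
  if (s == e) return(s)
  ws <- sort(unique(edges[, 3L]))
  adj_at <- function(thr) edges[edges[, 3L] <= thr + 1e-12, , drop = FALSE]
  connected <- function(thr) {
    ed <- adj_at(thr)
    if (!nrow(ed)) return(FALSE)
    reach <- rep(FALSE, n_nodes); reach[s] <- TRUE
    repeat {
      hit <- reach[ed[, 1L]] | reach[ed[, 2L]]
      new_reach <- reach
      new_reach[ed[hit, 1L]] <- TRUE
      new_reach[ed[hit, 2L]] <- TRUE
      if (identical(new_reach, reach)) break
      reach <- new_reach
    }
    reach[e]
  }
  lo <- 1L; hi <- length(ws)
  if (!connected(ws[hi])) stop("endpoints not connected on the block graph")
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected(ws[mid])) hi <- mid else lo <- mid + 1L
  }
  ed <- adj_at(ws[lo])
  # Dijkstra by total node energy among admissible edges
  dist <- rep(Inf, n_nodes); dist[s] <- node_energy[s]
  prev <- rep(NA_integer_, n_nodes)
  done <- rep(FALSE, n_nodes)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    if (u == e) break
    done[u] <- TRUE
    nb <- c(ed[ed[, 1L] == u, 2L], ed[ed[, 2L] == u, 1L])
    for (v in nb) {
      alt <- dist[u] + node_energy[v]
      if (alt < dist[v] - 1e-12) { dist[v] <- alt; prev[v] <- u }
    }
  }
  path <- e
  while (path[1L] != s) path <- c(prev[path[1L]], path)
  path
}

#' Cell-resolution minimax path (independent oracle)
#'
#' Finds the path between two cells on the 8-connected grid that minimises
#' the maximum energy en route (shortest-bottleneck path), by bisection on
#' the sorted energy levels with flood-fill connectivity, then a
#' breadth-first path through the admissible region. Serves as the
#' independent oracle for [extract_block_minimum_path]: its bottleneck is a
#' lower bound for any coarser path.
#'
#' @param grid an [fes_grid].
#' @param start,end `c(alpha, beta)` endpoints in degrees.
#' @return a `fes_path` with `method = "minimax_cell"`.
#' @export
minimax_cell_path <- function(grid, start, end) {
  stopifnot(inherits(grid, "fes_grid"))
  sc <- nearest_cell(grid, start)
  ec <- nearest_cell(grid, end)
  path_cells <- minimax_grid_path(grid$energy, sc, ec)
  pts <- data.frame(alpha = grid$alpha[path_cells[, 1L]],
                    beta = grid$beta[path_cells[, 2L]],
                    energy = grid$energy[path_cells])
  structure(list(points = pts, bottleneck = max(pts$energy),
                 method = "minimax_cell"),
            class = "fes_path")
}

# Minimax (bottleneck) path on a value matrix between cells s and e
# (each c(i, j)). Returns a 2-column matrix of cells along the path.
minimax_grid_path <- function(E, s, e) {
  levels <- sort(unique(c(E[E >= max(E[s[1L], s[2L]], E[e[1L], e[2L]])],
                          max(E[s[1L], s[2L]], E[e[1L], e[2L]]))))
  connected_at <- function(thr) {
    ok <- E <= thr
    if (!ok[s[1L], s[2L]] || !ok[e[1L], e[2L]]) return(FALSE)
    reach <- flood_fill(ok, s)
    reach[e[1L], e[2L]]
  }
  lo <- 1L; hi <- length(levels)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected_at(levels[mid])) hi <- mid else lo <- mid + 1L
  }
  thr <- levels[lo]
  ok <- E <= thr
  bfs_path(ok, E, s, e)
}

# matrix flood fill (8-connectivity) by iterative dilation
flood_fill <- function(ok, s) {
  na <- nrow(ok); nb <- ncol(ok)
  reach <- matrix(FALSE, na, nb)
  reach[s[1L], s[2L]] <- TRUE
  pad <- matrix(FALSE, na + 2L, nb + 2L)
  ri <- 2:(na + 1L); rj <- 2:(nb + 1L)
  repeat {
    pad[ri, rj] <- reach
    grown <- reach
    for (k in seq_len(nrow(NEIGH8)))
      grown <- grown | pad[ri + NEIGH8[k, 1L], rj + NEIGH8[k, 2L]]
    grown <- (grown & ok) | reach
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

# BFS shortest path through admissible cells; deterministic neighbour order.
bfs_path <- function(ok, E, s, e) {
  na <- nrow(ok); nb <- ncol(ok)
  prev <- matrix(NA_integer_, na, nb)
  visited <- matrix(FALSE, na, nb)
  visited[s[1L], s[2L]] <- TRUE
  queue <- matrix(s, 1L, 2L)
  lin <- function(i, j) (j - 1L) * na + i
  found <- all(s == e)
  while (nrow(queue) && !found) {
    nxt <- list()
    for (q in seq_len(nrow(queue))) {
      i <- queue[q, 1L]; j <- queue[q, 2L]
      for (k in seq_len(nrow(NEIGH8))) {
        i2 <- i + NEIGH8[k, 1L]; j2 <- j + NEIGH8[k, 2L]
        if (i2 < 1L || i2 > na || j2 < 1L || j2 > nb) next
        if (!ok[i2, j2] || visited[i2, j2]) next
        visited[i2, j2] <- TRUE
        prev[i2, j2] <- lin(i, j)
        if (i2 == e[1L] && j2 == e[2L]) { found <- TRUE }
        nxt[[length(nxt) + 1L]] <- c(i2, j2)
      }
    }
    queue <- if (length(nxt)) do.call(rbind, nxt) else
      matrix(integer(0), 0L, 2L)
  }
  if (!found && !all(s == e))
    stop("endpoints are not connected through the admissible region")
  # walk back
  cells <- list(c(e[1L], e[2L]))
  cur <- e
  while (!(cur[1L] == s[1L] && cur[2L] == s[2L])) {
    p <- prev[cur[1L], cur[2L]]
    cur <- c((p - 1L) %% na + 1L, (p - 1L) %/% na + 1L)
    cells[[length(cells) + 1L]] <- cur
  }
  do.call(rbind, rev(cells))
}

#' Barriers and state free-energy differences along a path
#'
#' For each consecutive pair of states visited by the path, the barrier is
#' the maximum path energy between the two state centres minus the energy
#' at the origin state's centre. The endpoint free-energy difference and
#' the overall barrier (max path energy minus start-centre energy) are
#' also reported.
#'
#' @param path a `fes_path`.
#' @param states states from [detect_states].
#' @return a `barrier_table`: data.frame `segments` (from, to, barrier,
#'   delta_g), `overall_barrier`, `endpoint_delta_g`.
#' @export
barrier_analysis <- function(path, states) {
  stopifnot(inherits(path, "fes_path"))
  pts <- path$points
  # map each path point to the nearest state centre among states whose
  # centre the path visits (within half a block)
  centers <- t(vapply(states, function(s) s$center, numeric(2L)))
  labels <- vapply(states, function(s) s$label, character(1L))
  energies <- vapply(states, function(s) s$free_energy, numeric(1L))
  # a state is "visited" at the path index minimising distance to its centre
  visit_idx <- vapply(seq_along(states), function(k) {
    d2 <- (pts$alpha - centers[k, 1L])^2 + (pts$beta - centers[k, 2L])^2
    i <- which.min(d2)
    if (sqrt(d2[i]) <= attr(path, "visit_radius") %||% 15) i else NA_integer_
  }, integer(1L))
  ord <- order(visit_idx, na.last = NA)
  visited <- ord[!is.na(visit_idx[ord])]
  if (length(visited) < 1L)
    stop("path does not pass near any detected state centre")
  segs <- NULL
  if (length(visited) > 1L) {
    segs <- do.call(rbind, lapply(seq_len(length(visited) - 1L), function(q) {
      a <- visited[q]; b <- visited[q + 1L]
      i1 <- visit_idx[a]; i2 <- visit_idx[b]
      emax <- max(pts$energy[min(i1, i2):max(i1, i2)])
      data.frame(from = labels[a], to = labels[b],
                 barrier = emax - energies[a],
                 delta_g = energies[b] - energies[a],
                 stringsAsFactors = FALSE)
    }))
  } else {
    segs <- data.frame(from = character(0), to = character(0),
                       barrier = numeric(0), delta_g = numeric(0))
  }
  first <- visited[1L]; last <- visited[length(visited)]
  structure(list(segments = segs,
                 overall_barrier = max(pts$energy) - energies[first],
                 endpoint_delta_g = energies[last] - energies[first],
                 states_visited = labels[visited]),
            class = "barrier_table")
}
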