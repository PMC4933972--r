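# Free-energy-surface grid container and plain-text I/O.
#
# Grid dialect: whitespace-delimited rows "alpha beta energy" covering a full
# rectangular grid; alpha and beta in degrees, energy in kcal/mol.

#' Construct a free-energy grid over two rotation angles
#'
#' @param alpha,beta uniform ascending axis values in degrees.
#' @param energy matrix of free energies (kcal/mol), dimensions
#'   `length(alpha) x length(beta)`.
#' @param shift_to_zero if TRUE (default) the global minimum is shifted to
#'   zero; the original offset is kept in the `offset` field.
#' @return an object of class `fes_grid`.
#' @export
fes_grid <- function(alpha, beta, energy, shift_to_zero = TRUE) {
  if (!is.matrix(energy) || nrow(energy) != length(alpha) ||
      ncol(energy) != length(beta))
    stop("energy must be a length(alpha) x length(beta) matrix")
  if (!all(is.finite(energy))) stop("energy grid contains non-finite cells")
  check_uniform <- function(ax, nm) {
    if (length(ax) > 1L) {
      d <- diff(ax)
      if (any(d <= 0)) stop(nm, " axis must be strictly ascending")
      if (max(d) - min(d) > 1e-6 * max(abs(d)))
        stop(nm, " axis must be uniformly spaced")
    }
  }
  check_uniform(alpha, "alpha")
  check_uniform(beta, "beta")
  offset <- 0
  if (shift_to_zero) {
    offset <- min(energy)
    energy <- energy - offset
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 energy = energy, minimum_shifted = shift_to_zero,
                 offset = offset),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf(
    "<fes_grid> %d x %d, alpha [%g, %g], beta [%g, %g], E [%g, %g] kcal/mol\n",
    length(x$alpha), length(x$beta), min(x$alpha), max(x$alpha),
    min(x$beta), max(x$beta), min(x$energy), max(x$energy)))
  invisible(x)
}

#' Read a free-energy grid from a plain-text file
#'
#' Expects whitespace-delimited rows `alpha beta energy` forming a complete
#' rectangular grid. The energy is shifted so the global minimum is zero
#' (the free-energy convention for landscape plots); the offset removed is
#' retained in the returned object.
#'
#' @param path input path.
#' @param shift_to_zero shift the minimum to zero on load (default TRUE).
#' @return an [fes_grid].
#' @export
read_fes_grid <- function(path, shift_to_zero = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("alpha", "beta", "energy"))
  if (any(!is.finite(as.matrix(tab))))
    stop("non-finite value in FES grid file ", path)
  alpha <- sort(unique(tab$alpha))
  beta <- sort(unique(tab$beta))
  if (nrow(tab) != length(alpha) * length(beta))
    stop("FES grid is not rectangular: ", nrow(tab), " rows but ",
         length(alpha), " x ", length(beta), " cells expected")
  energy <- matrix(NA_real_, length(alpha), length(beta))
  energy[cbind(match(tab$alpha, alpha), match(tab$beta, beta))] <- tab$energy
  if (anyNA(energy)) stop("FES grid has duplicate/missing cells in ", path)
  fes_grid(alpha, beta, energy, shift_to_zero = shift_to_zero)
}

#' Write a free-energy grid to a plain-text file
#'
#' @param grid an [fes_grid].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fes_grid <- function(grid, path) {
  stopifnot(inherits(grid, "fes_grid"))
  idx <- expand.grid(i = seq_along(grid$alpha), j = seq_along(grid$beta))
  # row-major in alpha for readability: all beta for first alpha, etc.
  idx <- idx[order(idx$i, idx$j), ]
  lines <- sprintf("%.8g %.8g %.8g",
                   grid$alpha[idx$i], grid$beta[idx$j],
                   grid$energy[cbind(idx$i, idx$j)])
  writeLines(lines, path)
  invisible(path)
}
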