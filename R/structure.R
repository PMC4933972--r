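# Structure container and PDB I/O (delegated to bio3d).

#' Construct a molecular structure
#'
#' A light container for a set of atoms with names, residue identity, chain
#' ids and Cartesian coordinates in Angstrom. This is the common currency of
#' all geometry operations in the package.
#'
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_number` (integer), `chain_id`, `x`, `y`, `z`.
#' @param title optional character title.
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms, title = "") {
  required <- c("atom_name", "element", "residue_name", "residue_number",
                "chain_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms$residue_number <- as.integer(atoms$residue_number)
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  # residue numbers must identify a residue uniquely within a chain
  key <- paste(atoms$chain_id, atoms$residue_number)
  rn <- tapply(atoms$residue_name, key, function(v) length(unique(v)))
  if (any(rn > 1))
    stop("residue_number maps to multiple residue names within a chain")
  structure(list(atoms = atoms, title = title), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("<md_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
              paste(unique(x$atoms$chain_id), collapse = ", ")))
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  invisible(x)
}

coords_matrix <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

set_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1L]
  s$atoms$y <- xyz[, 2L]
  s$atoms$z <- xyz[, 3L]
  s
}

# Row indices of atoms matching the given chain / residue / atom-name filters.
atom_select <- function(s, chain = NULL, resno = NULL, atom_name = NULL) {
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(chain)) keep <- keep & s$atoms$chain_id %in% chain
  if (!is.null(resno)) keep <- keep & s$atoms$residue_number %in% resno
  if (!is.null(atom_name)) keep <- keep & s$atoms$atom_name %in% atom_name
  which(keep)
}

element_from_name <- function(atom_name) {
  # first alphabetic character of a (protein/bead) atom name
  e <- substr(gsub("[^A-Za-z].*$", "", atom_name), 1L, 1L)
  e[e == ""] <- "X"
  e
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (first model of a multi-model file), preserving
#' chain identity and the file's residue numbering.
#'
#' @param path path to a PDB file.
#' @return an [md_structure].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  elem <- a$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- element_from_name(a$elety[bad])
  atoms <- data.frame(
    atom_name = a$elety,
    element = trimws(elem),
    residue_name = a$resid,
    residue_number = as.integer(a$resno),
    chain_id = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  md_structure(atoms, title = basename(path))
}

#' Write a structure to a PDB file
#'
#' @param s an [md_structure].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "md_structure"))
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords_matrix(s))),
    resno = a$residue_number,
    resid = a$residue_name,
    eleno = seq_len(nrow(a)),
    elety = a$atom_name,
    chain = a$chain_id,
    elesy = a$element
  )
  invisible(path)
}

# All-atom pairwise minimum distance between two coordinate blocks.
min_pair_distance <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}
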