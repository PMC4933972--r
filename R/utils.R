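# Small vector/rotation helpers shared across the geometry code.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: right-handed rotation by `angle` degrees about the
#' (normalised) `axis`.
#'
#' @param axis numeric length-3 axis vector (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- unitv(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal rotation taking unit vector a onto unit vector b.
minimal_rotation <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3L))
    # antiparallel: rotate 180 degrees about any perpendicular
    p <- if (abs(a[1L]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_matrix(p, 180))
  }
  rotation_matrix(v, atan2(s, c_) * 180 / pi)
}

# Signed dihedral angle p1-p2-p3-p4 in degrees (IUPAC sign convention).
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Run code with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# FNV-1a hash of a character scalar; used to fingerprint run configurations.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
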