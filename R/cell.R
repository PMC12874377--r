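#' Triclinic unit cells
#'
#' A unit cell is parameterised by the conventional lattice constants
#' `a, b, c` (Angstrom) and angles `alpha, beta, gamma` (degrees).
#' Cartesian coordinates follow the crystallographic convention of a
#' lower-triangular cell matrix with the a-vector along x, so fractional
#' coordinates round-trip unambiguously with CIF files.
#'
#' @param a,b,c lattice lengths in Angstrom, all `> 0`.
#' @param alpha,beta,gamma lattice angles in degrees, each in `(0, 180)`.
#' @return An object of class `unit_cell`.
#' @examples
#' cell <- unit_cell(13.905, 13.905, 8.515, 90, 90, 120)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(len)) || any(len <= 0)) {
    stop("invalid cell: lengths must be finite and > 0")
  }
  if (!all(is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("invalid cell: angles must lie strictly inside (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("invalid cell: degenerate metric (angle combination)")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4f b=%.4f c=%.4f A  alpha=%.2f beta=%.2f gamma=%.2f deg  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Unit-cell volume
#'
#' Volume of a triclinic cell,
#' `V = abc * sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`.
#'
#' @param cell a [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("invalid cell: degenerate metric")
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Cell matrix (lattice vectors as rows)
#'
#' Lower-triangular row matrix `M` with the a-vector along x; Cartesian
#' coordinates are `x = f %*% M` for fractional row vectors `f`.
#'
#' @param cell a [unit_cell()].
#' @return A 3x3 numeric matrix (Angstrom).
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  v <- sqrt(disc)
  m <- rbind(
    c(cell$a, 0, 0),
    c(cell$b * cg, cell$b * sg, 0),
    c(cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg)
  )
  dimnames(m) <- NULL
  m
}

## inverse transform helpers ------------------------------------------------

frac_to_cart <- function(frac, cell) {
  frac <- matrix(frac, ncol = 3)
  frac %*% cell_matrix(cell)
}

cart_to_frac <- function(cart, cell) {
  cart <- matrix(cart, ncol = 3)
  cart %*% solve(cell_matrix(cell))
}

## reciprocal lattice vectors as rows, 2*pi convention (1/Angstrom)
reciprocal_matrix <- function(cell) {
  2 * pi * t(solve(cell_matrix(cell)))
}
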