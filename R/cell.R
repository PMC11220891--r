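#' Unit cell
#'
#' Construct a (possibly triclinic) crystallographic unit cell from the six
#' cell parameters. Lengths are in Angstrom, angles in degrees.
#'
#' @param a,b,c Cell edge lengths (Angstrom), all `> 0`.
#' @param alpha,beta,gamma Cell angles (degrees), each in `(0, 180)`.
#'
#' @return An object of class `unit_cell`: a list with the six parameters and
#'   the real-space basis matrix `basis` (rows are the Cartesian a, b, c
#'   vectors in the standard crystallographic frame: a along x, b in the
#'   xy plane).
#' @examples
#' cubic <- unit_cell(2 * pi, 2 * pi, 2 * pi, 90, 90, 90)
#' reciprocal_basis(cubic)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0))
    stop("cell lengths must be positive", call. = FALSE)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  al <- alpha * pi / 180; be <- beta * pi / 180; ga <- gamma * pi / 180
  # cz^2 > 0 iff the metric tensor is positive definite (non-degenerate cell)
  cz2 <- 1 - cos(be)^2 - ((cos(al) - cos(be) * cos(ga)) / sin(ga))^2
  if (!is.finite(cz2) || cz2 <= 0)
    stop("invalid cell: angle combination gives a degenerate metric tensor",
         call. = FALSE)
  av <- c(a, 0, 0)
  bv <- c(b * cos(ga), b * sin(ga), 0)
  cv <- c(c * cos(be), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
          c * sqrt(cz2))
  basis <- rbind(a = av, b = bv, c = cv)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 basis = basis),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f Angstrom\n", x$a, x$b, x$c))
  cat(sprintf("           alpha=%.3f beta=%.3f gamma=%.3f deg (V=%.2f A^3)\n",
              x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Unit-cell volume in cubic Angstrom
#' @param cell A [unit_cell()].
#' @return Scalar volume.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  abs(det(cell$basis))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Reciprocal basis (2*pi convention)
#'
#' The dual basis of the real-space cell under the crystallographic 2*pi
#' convention, i.e. `dot(a_i, a*_j) = 2*pi * delta_ij`.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 matrix with rows `a*`, `b*`, `c*` (Cartesian, 1/Angstrom),
#'   of class `reciprocal_basis`.
#' @export
reciprocal_basis <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  av <- cell$basis[1, ]; bv <- cell$basis[2, ]; cv <- cell$basis[3, ]
  V <- sum(av * cross3(bv, cv))
  out <- rbind(`a*` = 2 * pi * cross3(bv, cv) / V,
               `b*` = 2 * pi * cross3(cv, av) / V,
               `c*` = 2 * pi * cross3(av, bv) / V)
  class(out) <- c("reciprocal_basis", class(out))
  out
}

#' Resolution / q_max conversions (2*pi convention)
#'
#' `q = 2*pi / d`: the scattering-vector magnitude corresponding to a minimum
#' real-space resolution `d`, and its inverse.
#'
#' @param d Resolution in Angstrom (`> 0`).
#' @param q_max Scattering magnitude in 1/Angstrom (`> 0`).
#' @return The converted scalar (or vector).
#' @export
resolution_to_qmax <- function(d) {
  if (any(d <= 0)) stop("resolution must be positive", call. = FALSE)
  2 * pi / d
}

#' @rdname resolution_to_qmax
#' @export
qmax_to_resolution <- function(q_max) {
  if (any(q_max <= 0)) stop("q_max must be positive", call. = FALSE)
  2 * pi / q_max
}
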