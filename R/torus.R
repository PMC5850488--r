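#' Wrap angles onto [-pi, pi)
#'
#' Maps arbitrary finite angles (radians) onto the half-open interval
#' \eqn{[-\pi, \pi)}, the canonical chart of the torus used throughout the
#' package. The mapping is the unique representative congruent mod \eqn{2\pi};
#' by the half-open convention \eqn{\pi} maps to \eqn{-\pi}.
#'
#' @param x numeric vector of angles in radians; must be finite.
#' @return numeric vector of the same length, each entry in \eqn{[-\pi, \pi)}.
#' @examples
#' wrap_angle(3 * pi / 2)  # -pi/2
#' wrap_angle(pi)          # -pi
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wrap_angle: input angles must be finite numeric values")
  }
  ((x + pi) %% (2 * pi)) - pi
}

#' Construct a point on the torus T^2
#'
#' A torus point is a (phi, psi) dihedral-angle pair; both coordinates are
#' wrapped onto \eqn{[-\pi, \pi)} at construction.
#'
#' @param phi,psi angles in radians.
#' @return numeric vector `c(phi, psi)` with class `"torus_point"`.
#' @export
torus_point <- function(phi, psi) {
  p <- wrap_angle(c(phi, psi))
  names(p) <- c("phi", "psi")
  class(p) <- "torus_point"
  p
}

# Wrapped per-coordinate difference, vectorized over rows of n x 2 matrices.
.wrapped_diff <- function(a, b) {
  wrap_angle(a - b)
}

#' Angular distance between two dihedral-angle pairs
#'
#' The chord metric on the torus: for each coordinate the chord length
#' \eqn{2 \sin(\Delta\theta / 2)} of the wrapped difference is taken, and the
#' two chords are combined in quadrature,
#' \deqn{d(p, q) = \sqrt{\sum_{\theta \in \{\phi,\psi\}}
#'   \left(2 \sin(\Delta\theta / 2)\right)^2}.}
#' This is the Euclidean distance between the embeddings of p and q on the
#' product of two unit circles in R^4, hence a true metric. Its supremum,
#' attained when both coordinates differ by \eqn{\pi}, is \eqn{2\sqrt{2}}.
#'
#' @param p,q torus points (length-2 numerics `c(phi, psi)`), or n x 2
#'   matrices of points (row-wise), in radians.
#' @return non-negative numeric: the distance(s), in `[0, 2 * sqrt(2)]`.
#' @examples
#' angular_distance(c(-1.63, -0.06), c(1.40, 0.22))  # about 2.02
#' angular_distance(c(-pi/2, -pi/2), c(pi/2, pi/2))  # 2 * sqrt(2)
#' @export
angular_distance <- function(p, q) {
  p <- .as_point_matrix(p)
  q <- .as_point_matrix(q)
  if (nrow(p) != nrow(q)) {
    if (nrow(p) == 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
    else if (nrow(q) == 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
    else stop("angular_distance: point counts differ")
  }
  d <- 2 * sin(.wrapped_diff(p, q) / 2)
  sqrt(rowSums(d^2))
}

.as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("torus points must have two coordinates (phi, psi)")
    m <- p
  } else {
    if (length(p) != 2L) stop("torus points must have two coordinates (phi, psi)")
    m <- matrix(as.numeric(p), nrow = 1L)
  }
  if (any(!is.finite(m))) stop("torus points must be finite")
  wrap_angle(m)
}

#' Mean angular distance between two dihedral-angle tracks
#'
#' Arithmetic mean of the per-site [angular_distance()] over two equal-length
#' tracks of (phi, psi) pairs. Used as the evaluation metric for predicted
#' dihedral angles.
#'
#' @param track_a,track_b n x 2 matrices of (phi, psi) rows, radians.
#' @return non-negative numeric scalar.
#' @export
mean_angular_distance <- function(track_a, track_b) {
  a <- .as_point_matrix(track_a)
  b <- .as_point_matrix(track_b)
  if (nrow(a) != nrow(b)) stop("mean_angular_distance: track lengths differ")
  if (nrow(a) == 0L) stop("mean_angular_distance: empty tracks")
  mean(angular_distance(a, b))
}
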