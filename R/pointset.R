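#' Closed-interface point set in spherical coordinates
#'
#' Locates the geometric center of an atomic point cloud describing one
#' closed interface (a vesicle leaflet, a micelle shell, a pore wall) and
#' expresses every atom in spherical coordinates about that center.  The
#' average radius \eqn{R_a} and the surface atomic density
#' \eqn{\sigma = n / (4 \pi R_a^2)} (atoms per nm\eqn{^2}) are derived here;
#' \eqn{\sigma} drives the automatic choice of the Gaussian fitting width.
#'
#' @param xyz numeric matrix (n x 3) of Cartesian coordinates in nm.
#' @param center optional fixed center; by default the arithmetic mean of
#'   the coordinates (the geometric center of the interface).
#' @return An object of class `surface_point_set`: a list with `xyz`,
#'   `center`, spherical coordinates `r`, `theta` (azimuth, `[0, 2pi)`),
#'   `phi` (colatitude, `[0, pi]`), atom count `n`, average radius `R_a`
#'   (nm) and surface density `sigma` (atoms/nm^2).
#' @examples
#' octa <- rbind(diag(3), -diag(3))
#' ps <- surface_point_set(octa)
#' ps$R_a       # 1
#' @export
surface_point_set <- function(xyz, center = NULL) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3)
    stop("'xyz' must be an n x 3 numeric matrix")
  if (nrow(xyz) < 4)
    stop("a closed interface needs at least 4 points")
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  if (is.null(center)) center <- colMeans(xyz)
  sph <- cart2sph(xyz, center)
  if (max(sph$r) <= .Machine$double.eps)
    stop("degenerate input: all points coincide with the center")
  R_a <- mean(sph$r)
  structure(list(
    xyz = xyz, center = as.numeric(center),
    r = sph$r, theta = sph$theta, phi = sph$phi,
    n = nrow(xyz), R_a = R_a,
    sigma = nrow(xyz) / (4 * pi * R_a^2)
  ), class = "surface_point_set")
}

#' @export
print.surface_point_set <- function(x, ...) {
  cat(sprintf(
    "surface_point_set: %d atoms, center (%.3f, %.3f, %.3f) nm, R_a = %.3f nm, sigma = %.3f /nm^2\n",
    x$n, x$center[1], x$center[2], x$center[3], x$R_a, x$sigma))
  invisible(x)
}

#' Radius of gyration of a point set
#'
#' Root-mean-square distance of the points from the geometric center,
#' \eqn{\sqrt{\langle |r - C_0|^2 \rangle}}.
#'
#' @param ps a [surface_point_set()].
#' @return radius of gyration in nm.
#' @export
radius_of_gyration <- function(ps) {
  stopifnot(inherits(ps, "surface_point_set"))
  sqrt(mean(ps$r^2))
}
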