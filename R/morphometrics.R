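#' Triangulate a spherical grid into flat triangular partitions
#'
#' Each square grid cell `(i, j)` with `i = 1..bin`, `j = 1..bin/2` is
#' split into two flat triangles with vertex nodes
#' `{G(i,j), G(i+1,j), G(i,j+1)}` and `{G(i+1,j+1), G(i+1,j), G(i,j+1)}`,
#' giving `2 * bin * (bin/2)` triangles that cover the closed surface
#' exactly once (the duplicated seam column closes the azimuth; the cells
#' adjacent to a pole contribute one zero-area triangle each).  Triangle
#' normals use a consistent winding; the whole set is flipped outward if
#' the signed enclosed volume comes out negative.
#'
#' @param grid a `spherical_grid`.
#' @return list of parallel vectors/matrices over triangles: Heron `area`
#'   (nm^2), flat outward unit `normal` (L x 3) with `cos_flat` its cosine
#'   against the radial direction at the centroid, `centroid` (L x 3),
#'   mean vertex radius `rbar` (nm), `cos_theta` = cosine of the
#'   deflection angle between the normal of the differentiable fitted
#'   surface (from the angular gradient of the node radii) and the radial
#'   vector -- exactly 1 on a constant-radius grid -- plus a `degenerate`
#'   flag for zero-area triangles and the vertex node indices `v_idx`.
#' @export
triangulate <- function(grid) {
  stopifnot(inherits(grid, "spherical_grid"))
  bin <- grid$bin
  nth <- bin + 1L
  xyz <- grid_nodes(grid)$xyz
  node <- function(i, j) xyz[(j - 1L) * nth + i, , drop = FALSE]
  i <- rep(seq_len(bin), times = bin / 2)
  j <- rep(seq_len(bin / 2), each = bin)
  # triangle 1: (i,j) (i+1,j) (i,j+1); triangle 2: (i,j+1) (i+1,j) (i+1,j+1)
  v1 <- rbind(node(i, j), node(i, j + 1L))
  v2 <- rbind(node(i + 1L, j), node(i + 1L, j))
  v3 <- rbind(node(i, j + 1L), node(i + 1L, j + 1L))
  a <- sqrt(rowSums((v2 - v1)^2))
  b <- sqrt(rowSums((v3 - v2)^2))
  cc <- sqrt(rowSums((v3 - v1)^2))
  s <- (a + b + cc) / 2
  area <- sqrt(pmax(0, s * (s - a) * (s - b) * (s - cc)))
  cr <- row_cross(v2 - v1, v3 - v1)
  nrm <- sqrt(rowSums(cr^2))
  degenerate <- nrm <= .Machine$double.eps * pmax(1, s)^2
  normal <- cr / ifelse(degenerate, 1, nrm)
  centroid <- (v1 + v2 + v3) / 3
  rel <- sweep(centroid, 2, grid$center)
  rl <- sqrt(rowSums(rel^2))
  radial <- rel / ifelse(rl > 0, rl, 1)
  cos_flat <- rowSums(normal * radial)
  sph1 <- cart2sph(v1, grid$center)
  sph2 <- cart2sph(v2, grid$center)
  sph3 <- cart2sph(v3, grid$center)
  rbar <- (sph1$r + sph2$r + sph3$r) / 3
  # orient flat normals outward: signed volume of the pyramid fan
  vsign <- sum(area * rbar * cos_flat, na.rm = TRUE)
  if (vsign < 0) {
    normal <- -normal
    cos_flat <- -cos_flat
  }
  # deflection of the differentiable surface r(theta, phi): its outward
  # normal is rhat - (dr/dphi)/r phihat - (dr/dtheta)/(r sin phi) thetahat,
  # evaluated per triangle from one-sided differences of the node radii at
  # the triangle's mean direction; exact (cos = 1) for a constant radius
  delta <- 2 * pi / bin
  rg <- grid$r
  r00 <- rg[cbind(i, j)]; r10 <- rg[cbind(i + 1L, j)]
  r01 <- rg[cbind(i, j + 1L)]; r11 <- rg[cbind(i + 1L, j + 1L)]
  dth <- c(r10 - r00, r11 - r01) / delta
  dph <- c(r01 - r00, r11 - r10) / delta
  th_v <- grid$theta; ph_v <- grid$phi
  thbar <- c((2 * th_v[i] + th_v[i + 1L]) / 3, (th_v[i] + 2 * th_v[i + 1L]) / 3)
  phbar <- c((2 * ph_v[j] + ph_v[j + 1L]) / 3, (ph_v[j] + 2 * ph_v[j + 1L]) / 3)
  cos_theta <- 1 / sqrt(1 + (dph / rbar)^2 + (dth / (rbar * sin(phbar)))^2)
  lin <- function(ii, jj) (jj - 1L) * nth + ii
  v_idx <- rbind(cbind(lin(i, j), lin(i + 1L, j), lin(i, j + 1L)),
                 cbind(lin(i, j + 1L), lin(i + 1L, j), lin(i + 1L, j + 1L)))
  list(area = area, normal = normal, centroid = centroid, rbar = rbar,
       cos_theta = cos_theta, cos_flat = cos_flat,
       degenerate = degenerate, v_idx = v_idx,
       n_triangles = length(area))
}

#' Total area of the closed grid surface
#'
#' Sum of the Heron areas of all flat triangular partitions,
#' \eqn{A_g = \sum_l A_{tp}(l)}.
#'
#' @param grid a `spherical_grid` (or a precomputed [triangulate()] list).
#' @return area in nm^2.
#' @export
total_area <- function(grid) {
  tp <- if (inherits(grid, "spherical_grid")) triangulate(grid) else grid
  sum(tp$area)
}

#' Enclosed volume of the closed grid surface
#'
#' Sum over triangular partitions of pyramid volumes with apex at the
#' center, \eqn{V_g = \sum_l \frac13 A_{tp}(l)\, \bar r_{tp}(l)
#' \cos\theta_{tp}(l)}, where \eqn{\bar r_{tp}} is the mean vertex radius
#' and \eqn{\theta_{tp}} the deflection angle between the outward normal
#' and the radial vector.  Negative \eqn{\cos\theta_{tp}} indicates a
#' region not star-shaped about the center and triggers a warning.
#'
#' @inheritParams total_area
#' @return volume in nm^3.
#' @export
grid_volume <- function(grid) {
  tp <- if (inherits(grid, "spherical_grid")) triangulate(grid) else grid
  bad <- sum(tp$cos_flat < 0 & !tp$degenerate & tp$area > 0, na.rm = TRUE)
  if (bad > 0)
    warning(sprintf("%d triangle(s) face inward: surface is not star-shaped about the center", bad))
  sum(tp$area * tp$rbar * tp$cos_theta) / 3
}

#' Sphericity of a closed surface
#'
#' Area of the sphere with the same volume over the actual surface area,
#' \eqn{\Psi_g = \pi^{1/3} (6 V_g)^{2/3} / A_g}; 1 for a perfect sphere
#' and below 1 otherwise (isoperimetric inequality).
#'
#' @param A_g surface area (nm^2) or a `spherical_grid` (then `V_g` is
#'   ignored and both are computed from it).
#' @param V_g enclosed volume (nm^3).
#' @return dimensionless sphericity.
#' @export
sphericity <- function(A_g, V_g = NULL) {
  if (inherits(A_g, "spherical_grid")) {
    tp <- triangulate(A_g)
    V_g <- grid_volume(tp)
    A_g <- total_area(tp)
  }
  if (A_g <= 0 || V_g <= 0) stop("area and volume must be positive")
  pi^(1 / 3) * (6 * V_g)^(2 / 3) / A_g
}

#' Area per lipid
#'
#' Leaflet surface area divided by the number of lipids in that leaflet.
#' Outer and inner leaflets are treated independently
#' (`A_g^up / n_up`, `A_g^down / n_down`).
#'
#' @param A_g leaflet grid area, nm^2.
#' @param n_lipids lipid count in the same leaflet (> 0).
#' @return nm^2 per lipid.
#' @export
area_per_lipid <- function(A_g, n_lipids) {
  if (n_lipids <= 0) stop("n_lipids must be positive")
  A_g / n_lipids
}

#' Deflection angles of the triangular partitions
#'
#' Angle between the outward surface normal and the radial vector from
#' the center, per triangle.  Zero everywhere on a perfect sphere; the
#' histogram of these angles characterizes departure from sphericity.
#' Zero-area (pole) triangles have no defined normal and are excluded.
#'
#' @param grid a `spherical_grid`.
#' @return list with `angles` (radians), per-triangle `area` weights for
#'   the retained triangles, and `n_excluded`.
#' @export
deflection_angles <- function(grid) {
  tp <- triangulate(grid)
  keep <- !tp$degenerate
  list(angles = acos(clamp1(tp$cos_theta[keep])),
       area = tp$area[keep],
       n_excluded = sum(!keep))
}

#' Curvature order parameter
#'
#' Second-Legendre-polynomial average of the deflection-angle cosine over
#' the surface, \eqn{S_C = \langle (3\cos^2\theta - 1)/2 \rangle},
#' area-weighted over the triangular partitions by default.  Equals 1.0
#' when the fitted interface is a perfect sphere (all deflection angles
#' zero) and decreases toward -0.5 as normals tilt to 90 degrees.
#'
#' @param grid a `spherical_grid`.
#' @param area_weighted average over triangles weighted by area (default)
#'   or unweighted.
#' @return dimensionless order parameter in `[-0.5, 1]`.
#' @export
curvature_order_parameter <- function(grid, area_weighted = TRUE) {
  da <- deflection_angles(grid)
  p2 <- (3 * cos(da$angles)^2 - 1) / 2
  if (area_weighted) sum(p2 * da$area) / sum(da$area) else mean(p2)
}

#' Principal moments of inertia of the fitted surface
#'
#' Eigenvalues (ascending) of the inertia tensor of the grid surface
#' about its center.  By default each triangular partition contributes
#' its area as mass at its centroid, so the tensor represents a shell of
#' uniform surface density independent of the angular node layout;
#' `mass = "node"` instead places unit mass on each distinct grid node.
#'
#' @param x a `spherical_grid` or a [surface_point_set()] (point sets
#'   always use unit masses).
#' @param mass `"area"` (default) or `"node"`.
#' @return numeric `c(I1, I2, I3)` with `I1 <= I2 <= I3` (mass nm^2).
#' @export
inertia_principal_moments <- function(x, mass = c("area", "node")) {
  mass <- match.arg(mass)
  if (inherits(x, "surface_point_set")) {
    pts <- sweep(x$xyz, 2, x$center)
    m <- rep(1, nrow(pts))
  } else if (inherits(x, "spherical_grid")) {
    if (mass == "area") {
      tp <- triangulate(x)
      keep <- !tp$degenerate
      pts <- sweep(tp$centroid[keep, , drop = FALSE], 2, x$center)
      m <- tp$area[keep]
    } else {
      nd <- grid_nodes(x)
      pts <- sweep(nd$xyz[nd$unique_mask, , drop = FALSE], 2, x$center)
      m <- rep(1, nrow(pts))
    }
  } else stop("'x' must be a spherical_grid or surface_point_set")
  if (nrow(pts) < 3) stop("degenerate geometry: need at least 3 points")
  r2 <- rowSums(pts^2)
  I <- diag(c(sum(m * r2), sum(m * r2), sum(m * r2))) -
    t(pts * m) %*% pts
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[3] <= .Machine$double.eps) stop("degenerate geometry: collinear points")
  ev
}

# perimeter of the cross-section of the grid surface by the plane through
# the center with unit normal e, traced with n_dir directions
cross_section_perimeter <- function(grid, e, n_dir = 720) {
  e <- e / sqrt(sum(e^2))
  a <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * e) * e; u <- u / sqrt(sum(u^2))
  v <- c(e[2] * u[3] - e[3] * u[2], e[3] * u[1] - e[1] * u[3], e[1] * u[2] - e[2] * u[1])
  t <- seq(0, 2 * pi, length.out = n_dir + 1)[-(n_dir + 1)]
  dirs <- outer(cos(t), u) + outer(sin(t), v)
  sph <- cart2sph(dirs)
  r <- grid_interpolate(grid, sph$theta, sph$phi)
  p <- dirs * r
  sum(sqrt(rowSums((p - p[c(2:n_dir, 1), ])^2)))
}

#' Roundness indices of a closed surface
#'
#' Three complementary measures, each equal to 1 for a perfect sphere:
#' \describe{
#' \item{method 1}{circumference of the equal-area ideal sphere,
#'   `2 pi sqrt(A_g / 4 pi)`, over the mean perimeter of the three
#'   cross-sections through the center normal to the principal inertia
#'   axes;}
#' \item{method 2}{ratio of the largest inscribed to the smallest
#'   enclosing concentric circle, `min(r_g) / max(r_g)`;}
#' \item{method 3}{smallest over largest principal moment of inertia,
#'   `I_1 / I_3`.}
#' }
#'
#' @param grid a `spherical_grid`.
#' @param method 1, 2 or 3.
#' @return dimensionless roundness.
#' @export
roundness <- function(grid, method) {
  stopifnot(inherits(grid, "spherical_grid"))
  if (!length(method) == 1 || !method %in% 1:3) stop("unknown roundness method; use 1, 2 or 3")
  if (method == 2) return(min(grid$r) / max(grid$r))
  I <- inertia_principal_moments(grid)
  if (method == 3) return(I[1] / I[3])
  # method 1: principal axes from the inertia tensor eigenvectors
  tp <- triangulate(grid)
  keep <- !tp$degenerate
  pts <- sweep(tp$centroid[keep, , drop = FALSE], 2, grid$center)
  m <- tp$area[keep]
  r2 <- rowSums(pts^2)
  Imat <- diag(rep(sum(m * r2), 3)) - t(pts * m) %*% pts
  axes <- eigen(Imat, symmetric = TRUE)$vectors
  # trace cross-sections at the grid's own angular resolution so the
  # polygonal perimeter deficit matches the faceted-area deficit
  per <- mean(vapply(1:3, function(k)
    cross_section_perimeter(grid, axes[, k], n_dir = max(16, grid$bin)),
    numeric(1)))
  ideal <- 2 * pi * sqrt(total_area(tp) / (4 * pi))
  ideal / per
}

#' Full morphometry report for one fitted surface
#'
#' Convenience wrapper collecting area, volume, sphericity, mean radius,
#' optional area per lipid, curvature order parameter, principal inertia
#' moments and the three roundness indices.
#'
#' @param grid a `spherical_grid`.
#' @param n_lipids optional lipid count for the area-per-lipid column.
#' @return a one-row `data.frame`.
#' @export
morphometry_report <- function(grid, n_lipids = NULL) {
  tp <- triangulate(grid)
  A <- total_area(tp)
  V <- grid_volume(tp)
  I <- inertia_principal_moments(grid)
  data.frame(
    A_g = A, V_g = V, psi_g = sphericity(A, V),
    R_a = grid_mean_radius(grid),
    A_L = if (is.null(n_lipids)) NA_real_ else area_per_lipid(A, n_lipids),
    S_C = curvature_order_parameter(grid),
    I1 = I[1], I2 = I[2], I3 = I[3],
    round1 = roundness(grid, 1), round2 = roundness(grid, 2),
    round3 = roundness(grid, 3)
  )
}
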