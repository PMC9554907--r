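#' Gaussian width from surface atomic density
#'
#' Empirical power law linking the width \eqn{\alpha} of the Gaussian
#' weighting kernel to the surface atomic density \eqn{\sigma}:
#' \eqn{\alpha = \beta \sigma^{-\gamma}}.  Denser interfaces are fitted
#' with narrower kernels.  The default coefficients were calibrated for
#' closed surfaces; [calibrate_alpha()] re-derives them for any synthetic
#' shape family.
#'
#' @param sigma surface atomic density, atoms/nm^2 (> 0).
#' @param beta,gamma power-law coefficients (defaults 0.0382, 0.9968).
#' @return Gaussian width alpha in nm.
#' @export
alpha_from_sigma <- function(sigma, beta = 0.0382, gamma = 0.9968) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  beta * sigma^(-gamma)
}

#' Cutoff radius for the grid fit
#'
#' Three times the average circumference of the closed surface divided by
#' the square root of the number of interface atoms:
#' \eqn{r_c = 3 \cdot 2\pi R_a / \sqrt{n_s}}.  Atoms farther than this
#' geodesic distance from a grid node do not enter its weighted average.
#'
#' @param ps a [surface_point_set()].
#' @return cutoff radius in nm.
#' @export
cutoff_radius <- function(ps) {
  stopifnot(inherits(ps, "surface_point_set"))
  if (ps$R_a <= 0 || ps$n <= 0) stop("R_a and n must be positive")
  3 * (2 * pi * ps$R_a) / sqrt(ps$n)
}

#' Central angle between two directions on the sphere
#'
#' Spherical law of cosines,
#' \eqn{\cos\Delta\Phi = \cos\phi_1\cos\phi_2 +
#' \sin\phi_1\sin\phi_2\cos(\theta_1-\theta_2)}, clamped for numerical
#' stability.  Multiplying by the atomic radius gives the geodesic
#' distance used in the Gaussian weights.
#'
#' @param theta1,phi1 first direction (azimuth, colatitude), radians.
#' @param theta2,phi2 second direction.
#' @return central angle in `[0, pi]`.
#' @export
central_angle <- function(theta1, phi1, theta2, phi2) {
  acos(clamp1(cos(phi1) * cos(phi2) + sin(phi1) * sin(phi2) * cos(theta1 - theta2)))
}

#' Fitting parameters for the spherical grid
#'
#' Bundles the angular resolution `bin` and the kernel parameters.  When
#' `alpha` or `r_c` are not given they are derived from the point set via
#' [alpha_from_sigma()] and [cutoff_radius()].  When `bin` is not given it
#' is chosen from the atomic density as
#' `max(12, round(sqrt(4 pi R_a^2 sigma)))`, rounded up to even, so the
#' grid spacing tracks the typical inter-atom spacing.
#'
#' @param ps a [surface_point_set()] (may be omitted when `bin`, `alpha`
#'   and `r_c` are all supplied).
#' @param bin even number of angular partitions (>= 4).
#' @param beta,gamma power-law coefficients for [alpha_from_sigma()].
#' @param alpha Gaussian width in nm (overrides the power law).
#' @param r_c cutoff radius in nm (overrides [cutoff_radius()]).
#' @return object of class `fit_parameters`.
#' @export
fit_parameters <- function(ps = NULL, bin = NULL, beta = 0.0382, gamma = 0.9968,
                           alpha = NULL, r_c = NULL) {
  if (is.null(bin)) {
    if (is.null(ps)) stop("either 'bin' or a point set must be given")
    bin <- max(12, round(sqrt(4 * pi * ps$R_a^2 * ps$sigma)))
    if (bin %% 2 == 1) bin <- bin + 1
  }
  bin <- as.integer(bin)
  if (bin < 4 || bin %% 2 != 0) stop("'bin' must be an even integer >= 4")
  if (is.null(alpha)) {
    if (is.null(ps)) stop("either 'alpha' or a point set must be given")
    alpha <- alpha_from_sigma(ps$sigma, beta, gamma)
  }
  if (is.null(r_c)) {
    if (is.null(ps)) stop("either 'r_c' or a point set must be given")
    r_c <- cutoff_radius(ps)
  }
  if (alpha <= 0 || r_c <= 0) stop("alpha and r_c must be positive")
  structure(list(bin = bin, beta = beta, gamma = gamma, alpha = alpha, r_c = r_c),
            class = "fit_parameters")
}

# all (bin+1) x (bin/2+1) node angles of a grid with given bin
grid_angles <- function(bin) {
  d <- 2 * pi / bin
  list(theta = d * (seq_len(bin + 1) - 1), phi = d * (seq_len(bin / 2 + 1) - 1))
}

new_spherical_grid <- function(bin, r, center) {
  ang <- grid_angles(bin)
  structure(list(bin = as.integer(bin), theta = ang$theta, phi = ang$phi,
                 r = r, center = as.numeric(center),
                 n_nodes = (bin + 1) * (bin / 2 + 1)),
            class = "spherical_grid")
}

#' @export
print.spherical_grid <- function(x, ...) {
  cat(sprintf("spherical_grid: bin = %d (%d nodes), mean radius %.3f nm, center (%.3f, %.3f, %.3f)\n",
              x$bin, x$n_nodes, grid_mean_radius(x),
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Node coordinates of a spherical grid
#'
#' Cartesian positions of all `(bin+1)(bin/2+1)` grid nodes, in node-major
#' order (i fastest).  The seam column (i = bin+1) duplicates column 1 and
#' the pole rows repeat a single point; `unique_mask` flags one
#' representative per distinct surface point.
#'
#' @param grid a `spherical_grid`.
#' @return list with `xyz` (n x 3 matrix, nm) and logical `unique_mask`.
#' @export
grid_nodes <- function(grid) {
  bin <- grid$bin
  th <- matrix(grid$theta, bin + 1, bin / 2 + 1)
  ph <- matrix(grid$phi, bin + 1, bin / 2 + 1, byrow = TRUE)
  xyz <- sph2cart(as.vector(grid$r), as.vector(th), as.vector(ph), grid$center)
  im <- matrix(seq_len(bin + 1), bin + 1, bin / 2 + 1)
  jm <- matrix(seq_len(bin / 2 + 1), bin + 1, bin / 2 + 1, byrow = TRUE)
  uniq <- (im <= bin) & !(jm %in% c(1, bin / 2 + 1)) |
    (im == 1 & jm == 1) | (im == 1 & jm == bin / 2 + 1)
  list(xyz = xyz, unique_mask = as.vector(uniq))
}

#' Average radius of a grid surface
#'
#' Mean node radius over the distinct surface points (seam and pole
#' duplicates counted once).
#'
#' @param grid a `spherical_grid`.
#' @return average radius in nm.
#' @export
grid_mean_radius <- function(grid) {
  nd <- grid_nodes(grid)
  sph <- cart2sph(nd$xyz[nd$unique_mask, , drop = FALSE], grid$center)
  mean(sph$r)
}

#' Fit a closed spherical grid surface to an interface point cloud
#'
#' Builds an angular lattice `theta(i) = (i-1) 2pi/bin`,
#' `phi(j) = (j-1) 2pi/bin` about the point-set center and adjusts each
#' node radius as a Gaussian-weighted average of the atomic radii,
#' \deqn{r_g(i,j) = \sum_k w(i,j,k) r_s(k) / \sum_k w(i,j,k),}
#' with \eqn{w = \exp(-d^2 / 2\alpha^2)} a Gaussian of the geodesic
#' distance \eqn{d(i,j,k) = r_s(k)\,\Delta\Phi(i,j,k)} and the sum
#' restricted to atoms within the cutoff \eqn{r_c}.  Weights are
#' normalized in shifted log space so very narrow kernels cannot
#' underflow.  Nodes whose cutoff neighbourhood is empty fall back to an
#' unbounded cutoff (all atoms) with a warning, which preserves surface
#' continuity.  The seam column and the two pole rows are made exactly
#' single-valued.
#'
#' @param ps a [surface_point_set()].
#' @param params a [fit_parameters()]; defaults derived from `ps`.
#' @param weight_fn optional replacement weight function (used by the
#'   pore-wall fit); signature `function(d2, mask, r_s)` returning a
#'   weight matrix congruent with `d2`.
#' @return a `spherical_grid` with node radii matrix `r`
#'   (`(bin+1) x (bin/2+1)`).
#' @seealso [grid_rmsd()], [calibrate_alpha()]
#' @export
fit_grid <- function(ps, params = fit_parameters(ps), weight_fn = NULL) {
  stopifnot(inherits(ps, "surface_point_set"), inherits(params, "fit_parameters"))
  bin <- params$bin
  ang <- grid_angles(bin)
  nth <- bin + 1L; nph <- bin / 2 + 1L
  # node angle vectors, i-major
  th_g <- rep(ang$theta, times = nph)
  ph_g <- rep(ang$phi, each = nth)
  # cos of central angle: nodes x atoms
  cosd <- outer(cos(ph_g), cos(ps$phi)) +
    outer(sin(ph_g), sin(ps$phi)) * cos(outer(th_g, ps$theta, "-"))
  dphi <- acos(clamp1(cosd))
  d <- sweep(dphi, 2, ps$r, "*")                      # geodesic distances
  mask <- d <= params$r_c
  empty <- rowSums(mask) == 0
  if (any(empty)) {
    warning(sprintf("%d grid node(s) had no atom within r_c = %.3g nm; using all atoms there",
                    sum(empty), params$r_c))
    mask[empty, ] <- TRUE
  }
  d2 <- d * d
  if (is.null(weight_fn)) {
    # stable Gaussian weights: shift by the per-node minimum before exp
    d2m <- d2
    d2m[!mask] <- Inf
    shift <- apply(d2m, 1, min)
    w <- exp(-(d2m - shift) / (2 * params$alpha^2))
    w[!mask] <- 0
  } else {
    w <- weight_fn(d2, mask, ps$r)
  }
  r_g <- as.vector(w %*% ps$r) / rowSums(w)
  r <- matrix(r_g, nth, nph)
  # poles single-valued, seam closed
  r[, 1] <- mean(r[seq_len(bin), 1])
  r[, nph] <- mean(r[seq_len(bin), nph])
  r[nth, ] <- r[1, ]
  new_spherical_grid(bin, r, ps$center)
}

#' Bilinear interpolation of grid radii at arbitrary directions
#'
#' @param grid a `spherical_grid`.
#' @param theta,phi query directions (radians); theta wraps at 2pi via the
#'   duplicated seam column.
#' @return interpolated radii (nm).
#' @export
grid_interpolate <- function(grid, theta, phi) {
  bin <- grid$bin
  d <- 2 * pi / bin
  u <- (theta %% (2 * pi)) / d
  v <- pmin(pmax(phi, 0), pi) / d
  i0 <- pmin(floor(u), bin - 1); fi <- u - i0
  j0 <- pmin(floor(v), bin / 2 - 1); fj <- v - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  r <- grid$r
  idx <- function(i, j) r[cbind(i + 1L, j + 1L)]
  (1 - fi) * (1 - fj) * idx(i0, j0) +
    fi * (1 - fj) * idx(i0 + 1L, j0) +
    (1 - fi) * fj * idx(i0, j0 + 1L) +
    fi * fj * idx(i0 + 1L, j0 + 1L)
}

#' Root-mean-square deviation between grid surface and atoms
#'
#' RMS of the radial residuals `r_s(k) - r_interp(theta_s, phi_s)` with
#' the grid radius bilinearly interpolated at each atom's direction.  This
#' is the objective the Gaussian width calibration minimizes.
#'
#' @param grid a `spherical_grid`.
#' @param ps the [surface_point_set()] it was fitted to (same center).
#' @return RMSD in nm.
#' @export
grid_rmsd <- function(grid, ps) {
  stopifnot(inherits(grid, "spherical_grid"), inherits(ps, "surface_point_set"))
  sqrt(mean((ps$r - grid_interpolate(grid, ps$theta, ps$phi))^2))
}

#' Calibrate the Gaussian-width power law on a synthetic shape family
#'
#' For each surface density sigma, generates a test cloud with
#' `make_cloud`, finds the width alpha that minimizes the RMSD between
#' the fitted grid and the test surface by bounded one-dimensional search
#' on log(alpha), then fits the power law `alpha = beta * sigma^-gamma`
#' by least squares on the log-log table.  When the generator supplies
#' the analytic radius function of the test surface (as
#' [gen_surface_cloud()] does) the RMSD is taken against that surface at
#' the node directions; otherwise [grid_rmsd()] against the atoms is
#' used.  Families whose RMSD is insensitive to alpha (e.g. perfect
#' spheres, where any weighted average of a constant radius is exact) are
#' flagged degenerate rather than fitted.
#'
#' @param make_cloud function of `sigma` (and optionally a replicate
#'   index) returning either a [surface_point_set()] or a list with
#'   elements `points` (the point set) and `radius_fn(theta, phi)` (the
#'   analytic test surface).
#' @param sigmas >= 3 surface densities (atoms/nm^2) spanning the range of
#'   interest.
#' @param bin grid resolution used during calibration.
#' @param alpha_bounds search interval for alpha in nm; default
#'   `c(1e-3, 10 * R_a)`.
#' @param tol RMSD tolerance of the scalar search (nm).
#' @param n_rep independent clouds per sigma whose RMSD is averaged
#'   before minimization (used only when `make_cloud` accepts a second
#'   argument); stabilizes the per-sigma optimum.
#' @return list with the per-sigma `table` (sigma, alpha, rmsd), the
#'   fitted `beta`, `gamma`, the log-log `r_squared`, and `degenerate`.
#' @export
calibrate_alpha <- function(make_cloud, sigmas, bin, alpha_bounds = NULL,
                            tol = 1e-4, n_rep = 3) {
  if (length(sigmas) < 3) stop("need at least 3 sigma values")
  ang <- grid_angles(bin)
  th_g <- rep(ang$theta, times = bin / 2 + 1)
  ph_g <- rep(ang$phi, each = bin + 1)
  replicated <- length(formals(make_cloud)) >= 2
  if (!replicated) n_rep <- 1L
  rows <- lapply(sigmas, function(s) {
    clouds <- lapply(seq_len(n_rep), function(r) {
      cl <- if (replicated) make_cloud(s, r) else make_cloud(s)
      if (inherits(cl, "surface_point_set")) list(points = cl, radius_fn = NULL)
      else cl
    })
    ps1 <- clouds[[1]]$points
    bounds <- alpha_bounds %||% c(1e-3, 10 * ps1$R_a)
    obj <- function(la) {
      mean(vapply(clouds, function(cl) {
        pars <- fit_parameters(cl$points, bin = bin, alpha = exp(la))
        g <- fit_grid(cl$points, pars)
        if (is.null(cl$radius_fn)) grid_rmsd(g, cl$points)
        else sqrt(mean((as.vector(g$r) - cl$radius_fn(th_g, ph_g))^2))
      }, numeric(1)))
    }
    opt <- stats::optimize(obj, log(bounds), tol = tol)
    # degeneracy probe: RMSD at the bounds vs the optimum
    span <- max(abs(obj(log(bounds[1])) - opt$objective),
                abs(obj(log(bounds[2])) - opt$objective))
    data.frame(sigma = s, alpha = exp(opt$minimum), rmsd = opt$objective,
               span = span)
  })
  tab <- do.call(rbind, rows)
  degenerate <- all(tab$span < 10 * tol)
  if (degenerate) {
    return(list(table = tab, beta = NA_real_, gamma = NA_real_,
                r_squared = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(log(alpha) ~ log(sigma), data = tab)
  list(table = tab,
       beta = exp(unname(stats::coef(fit)[1])),
       gamma = -unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       degenerate = FALSE)
}
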