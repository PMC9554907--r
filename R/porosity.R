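# Bondi-style van der Waals radii (nm) for common framework elements;
# user-overridable via the `radii` argument of unit_cell().
.vdw_table <- c(
  H = 0.120, He = 0.140, B = 0.192, C = 0.170, N = 0.155, O = 0.152,
  F = 0.147, Ne = 0.154, Na = 0.227, Mg = 0.173, Al = 0.184, Si = 0.210,
  P = 0.180, S = 0.180, Cl = 0.175, Ar = 0.188, K = 0.275, Ca = 0.231,
  Sc = 0.211, Ti = 0.200, V = 0.200, Cr = 0.200, Mn = 0.200, Fe = 0.200,
  Co = 0.200, Ni = 0.163, Cu = 0.140, Zn = 0.139, Ga = 0.187, Ge = 0.211,
  Br = 0.185, Zr = 0.200, Mo = 0.200, Ag = 0.172, Cd = 0.158, In = 0.193,
  Sn = 0.217, I = 0.198
)

#' Van der Waals radius lookup
#'
#' @param elements character vector of element symbols.
#' @param table named numeric vector of radii in nm; defaults to the
#'   bundled Bondi-style table.
#' @return radii in nm; unknown elements error.
#' @export
vdw_radii <- function(elements, table = NULL) {
  tab <- .vdw_table
  if (!is.null(table)) tab[names(table)] <- table
  r <- tab[elements]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Crystal unit cell for porosity analysis
#'
#' Wraps the framework atoms into an orthorhombic periodic box and
#' attaches per-atom van der Waals radii.
#'
#' @param xyz atom coordinates (n x 3, nm).
#' @param box orthorhombic box lengths `c(a, b, c)` in nm.
#' @param elements element symbols (used to look up radii) or `NULL` when
#'   `radii` is given directly.
#' @param radii optional per-atom radii in nm, or a named table passed to
#'   [vdw_radii()].
#' @param periodic use minimum-image distances (default TRUE).
#' @return object of class `unit_cell`.
#' @export
unit_cell <- function(xyz, box, elements = NULL, radii = NULL, periodic = TRUE) {
  xyz <- as.matrix(xyz)
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths (nm)")
  if (is.null(radii)) {
    if (is.null(elements)) stop("give either 'elements' or per-atom 'radii'")
    radii <- vdw_radii(elements)
  } else if (!is.null(names(radii))) {
    radii <- vdw_radii(elements, table = radii)
  }
  if (nrow(xyz) > 0) {
    if (length(radii) == 1) radii <- rep(radii, nrow(xyz))
    if (length(radii) != nrow(xyz)) stop("one radius per atom required")
    if (any(radii <= 0)) stop("radii must be positive")
    xyz <- sweep(xyz, 2, box, function(x, b) x %% b)   # wrap into the cell
  }
  structure(list(xyz = xyz, box = box, radii = radii, elements = elements,
                 periodic = periodic, volume = prod(box)),
            class = "unit_cell")
}

# minimum-image distances from each point (m x 3) to every atom, chunked;
# returns for each point the minimum of (distance - t * r_vdw) and the
# occupancy indicator
.clearance <- function(points, cell, t, chunk = 20000L) {
  n <- nrow(points)
  out <- numeric(n)
  if (nrow(cell$xyz) == 0) return(rep(Inf, n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- points[s:e, , drop = FALSE]
    d2 <- matrix(0, nrow(p), nrow(cell$xyz))
    for (dim in 1:3) {
      dd <- outer(p[, dim], cell$xyz[, dim], "-")
      if (cell$periodic) {
        b <- cell$box[dim]
        dd <- dd - b * round(dd / b)
      }
      d2 <- d2 + dd * dd
    }
    cl <- sweep(sqrt(d2), 2, t * cell$radii, "-")
    out[s:e] <- do.call(pmin, as.data.frame(cl))
  }
  out
}

#' Heaviside occupancy of sampling points
#'
#' A point is void (value 1) unless its minimum-image distance to some
#' framework atom is smaller than `t` times that atom's van der Waals
#' radius (value 0).  The default threshold factor `t = 1/2` follows the
#' geometric pore-volume convention of half the vdW radius; `t = 1` uses
#' the full radius.  A point exactly at the threshold distance is void
#' (strict "smaller than" is occupied).
#'
#' @param points sampling coordinates (m x 3, nm), inside the cell.
#' @param cell a [unit_cell()].
#' @param t threshold factor multiplying the per-atom vdW radius.
#' @return integer vector of 0 (occupied) / 1 (void).
#' @export
occupancy <- function(points, cell, t = 0.5) {
  stopifnot(inherits(cell, "unit_cell"))
  points <- matrix(as.numeric(points), ncol = 3)
  as.integer(.clearance(points, cell, t) >= 0)
}

#' Monte-Carlo void fraction of a unit cell
#'
#' Displaces `N_sp` points uniformly at random in the cell and returns
#' the fraction flagged void by [occupancy()],
#' \eqn{\theta_{Gm} = \sum H / N_{sp}}, with its binomial standard error
#' and the total void volume `V_T = theta * cell volume`.
#'
#' @param cell a [unit_cell()].
#' @param N_sp number of sampling points (>= 1).
#' @param seed RNG seed for reproducible sampling.
#' @param t threshold factor, see [occupancy()].
#' @return list with `theta`, `se`, `V_T` (nm^3), `N_sp`, `seed`, `t`.
#' @export
void_fraction <- function(cell, N_sp, seed = 1L, t = 0.5) {
  stopifnot(inherits(cell, "unit_cell"), N_sp >= 1)
  set.seed(seed)
  pts <- cbind(stats::runif(N_sp, 0, cell$box[1]),
               stats::runif(N_sp, 0, cell$box[2]),
               stats::runif(N_sp, 0, cell$box[3]))
  occ <- occupancy(pts, cell, t)
  theta <- mean(occ)
  list(theta = theta,
       se = sqrt(theta * (1 - theta) / N_sp),
       V_T = theta * cell$volume,
       N_sp = as.integer(N_sp), seed = as.integer(seed), t = t)
}

#' Void-fraction convergence with sampling density
#'
#' For each sampling density (points per cubic angstrom), estimates the
#' void fraction and reports the relative deviation from the estimate at
#' the highest density, per seed, averaged over `n_seeds` independent
#' seeds.
#'
#' @param cell a [unit_cell()].
#' @param densities >= 2 sampling densities in points per cubic angstrom.
#' @param seed base RNG seed; seeds `seed, seed+1, ...` are used.
#' @param n_seeds number of independent repeats (>= 3 recommended).
#' @param t threshold factor.
#' @return data.frame with `density`, `N_sp`, mean `theta` and mean
#'   relative `deviation` from the highest-density estimate.
#' @export
convergence_curve <- function(cell, densities, seed = 1L, n_seeds = 3L, t = 0.5) {
  if (length(densities) < 2) stop("need at least 2 sampling densities")
  densities <- sort(densities)
  vol_A3 <- cell$volume * 1e3                    # nm^3 -> Angstrom^3
  N <- pmax(1L, as.integer(round(densities * vol_A3)))
  dev <- matrix(0, n_seeds, length(N))
  th <- matrix(0, n_seeds, length(N))
  for (s in seq_len(n_seeds)) {
    ths <- vapply(seq_along(N), function(i)
      void_fraction(cell, N[i], seed = seed + (s - 1L) * length(N) + i - 1L, t = t)$theta,
      numeric(1))
    th[s, ] <- ths
    dev[s, ] <- abs(ths - ths[length(N)]) / ths[length(N)]
  }
  data.frame(density = densities, N_sp = N,
             theta = colMeans(th), deviation = colMeans(dev))
}

#' Fit a closed grid surface to a pore wall
#'
#' Centers a spherical grid at a seed point inside a cavity and fits each
#' node radius to the first shell of framework atoms around the seed.
#' Atoms are taken at their minimum-image positions relative to the seed;
#' each node's weighted average uses the Gaussian of geodesic distance
#' (as in [fit_grid()]) multiplied by a radial Gaussian centred on the
#' smallest atomic radius within the node's cutoff neighbourhood, so
#' atoms beyond the first wall shell are suppressed.  The fitted wall
#' radius is then reduced by `t` times the weighted vdW radius so the
#' surface traces the void boundary.
#'
#' @param cell a [unit_cell()].
#' @param seed_point coordinates (nm) of a void point inside the cavity.
#' @param bin grid resolution (default 20).
#' @param t threshold factor (same convention as [occupancy()]).
#' @param alpha optional angular Gaussian width (nm); defaults to the
#'   geodesic length of one grid cell at the nearest-wall radius,
#'   `2 pi r_near / bin`, so each node averages over its own angular
#'   neighbourhood of wall atoms.
#' @param shell_width radial width (nm) of the first-shell Gaussian;
#'   defaults to the mean thresholded van der Waals radius `t * r_vdW`,
#'   the thickness scale of a single atomic wall layer.
#' @return a `spherical_grid` tracing the cavity boundary.
#' @export
fit_pore_grid <- function(cell, seed_point, bin = 20, t = 0.5, alpha = NULL,
                          shell_width = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  seed_point <- as.numeric(seed_point)
  if (occupancy(matrix(seed_point, 1), cell, t) == 0)
    stop("seed point lies inside an atom")
  # minimum-image images of all atoms about the seed point
  d <- sweep(cell$xyz, 2, seed_point)
  if (cell$periodic)
    d <- d - sweep(round(sweep(d, 2, cell$box, "/")), 2, cell$box, "*")
  ps <- surface_point_set(sweep(d, 2, -seed_point), center = seed_point)
  if (is.null(alpha)) alpha <- 2 * pi * min(ps$r) / bin
  if (is.null(shell_width)) shell_width <- mean(t * cell$radii)
  radii <- cell$radii
  pore_weights <- function(d2, mask, r_s) {
    # first-shell preference: per node, favour the smallest atomic radius
    # among atoms in the angular neighbourhood; both Gaussian exponents are
    # combined and shifted jointly in log space so narrow kernels cannot
    # underflow to an all-zero row
    rmat <- matrix(r_s, nrow(d2), length(r_s), byrow = TRUE)
    rmin <- apply(ifelse(mask, rmat, Inf), 1, min)
    ex <- d2 / (2 * alpha^2) +
      (sweep(rmat, 1, rmin, "-"))^2 / (2 * shell_width^2)
    ex[!mask] <- Inf
    w <- exp(-(ex - apply(ex, 1, min)))
    w[!mask] <- 0
    w
  }
  params <- fit_parameters(ps, bin = bin, alpha = alpha)
  wall <- fit_grid(ps, params, weight_fn = pore_weights)
  # pull the surface back from atom centers to the void boundary using the
  # same weights' mean vdW radius; a single global mean is adequate for
  # homogeneous walls, per-node refinement uses the nearest atom's radius
  nd <- grid_nodes(wall)
  sphn <- cart2sph(nd$xyz, wall$center)
  near <- .nearest_atom_radius(cell, wall$center, sphn$theta, sphn$phi)
  r <- matrix(pmax(sphn$r - t * near, 0), nrow(wall$r), ncol(wall$r))
  r[, 1] <- mean(r[seq_len(bin), 1])
  r[, ncol(r)] <- mean(r[seq_len(bin), ncol(r)])
  r[bin + 1, ] <- r[1, ]
  g <- new_spherical_grid(bin, pmin(r, max(cell$box)), wall$center)
  g
}

# vdW radius of the atom nearest in direction to each grid node
.nearest_atom_radius <- function(cell, center, theta, phi) {
  d <- sweep(cell$xyz, 2, center)
  if (cell$periodic)
    d <- d - sweep(round(sweep(d, 2, cell$box, "/")), 2, cell$box, "*")
  sph <- cart2sph(d)
  cosang <- outer(cos(phi), cos(sph$phi)) +
    outer(sin(phi), sin(sph$phi)) * cos(outer(theta, sph$theta, "-"))
  cell$radii[max.col(cosang, ties.method = "first")]
}

#' Geometric metrics of a fitted pore
#'
#' Diameter `D_P = 2 R_a` of the pore grid, internal void volume `V_P`,
#' wall area `A_P` and pore sphericity.
#'
#' @param pore_grid a `spherical_grid` from [fit_pore_grid()].
#' @return one-row data.frame with `D_P` (nm), `V_P` (nm^3), `A_P`
#'   (nm^2), `sphericity`.
#' @export
pore_metrics <- function(pore_grid) {
  stopifnot(inherits(pore_grid, "spherical_grid"))
  tp <- triangulate(pore_grid)
  A <- total_area(tp)
  V <- grid_volume(tp)
  data.frame(D_P = 2 * grid_mean_radius(pore_grid), V_P = V, A_P = A,
             sphericity = sphericity(A, V))
}

#' Full porosity report for a unit cell
#'
#' Monte-Carlo void fraction and total void volume, then locates the
#' largest pore as the sampled void point with maximum clearance (distance
#' to the nearest atom surface), fits a closed grid to its wall and
#' reports the pore metrics.  The inscribed-sphere diameter
#' `2 * max clearance` is reported alongside the grid-based `D_P`.
#'
#' @param cell a [unit_cell()].
#' @param N_sp Monte-Carlo sampling points (default 500000).
#' @param seed RNG seed.
#' @param t threshold factor.
#' @param bin pore-grid resolution.
#' @return object of class `pore_report`: one-row data.frame with
#'   `D_P`, `D_inscribed`, `V_P`, `A_P`, `sphericity`, `V_T`, `theta_Gm`,
#'   `theta_se`, `N_sp`, `seed`.
#' @export
pore_report <- function(cell, N_sp = 500000L, seed = 1L, t = 0.5, bin = 20) {
  vf <- void_fraction(cell, N_sp, seed = seed, t = t)
  set.seed(seed + 1L)
  # reuse a fresh (smaller) void sample to locate the largest cavity
  n_probe <- min(N_sp, 20000L)
  pts <- cbind(stats::runif(n_probe, 0, cell$box[1]),
               stats::runif(n_probe, 0, cell$box[2]),
               stats::runif(n_probe, 0, cell$box[3]))
  clear <- .clearance(pts, cell, t)
  best <- which.max(clear)
  pm <- pore_metrics(fit_pore_grid(cell, pts[best, ], bin = bin, t = t))
  out <- cbind(pm[, "D_P", drop = FALSE],
               data.frame(D_inscribed = 2 * max(clear, 0)),
               pm[, c("V_P", "A_P", "sphericity")],
               data.frame(V_T = vf$V_T, theta_Gm = vf$theta, theta_se = vf$se,
                          N_sp = vf$N_sp, seed = as.integer(seed)))
  class(out) <- c("pore_report", class(out))
  out
}
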