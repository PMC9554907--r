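# Synthetic closed-surface fixtures with analytic ground truth.  Every
# generator is deterministic under its seed and returns the analytic
# radius function alongside the sampled cloud, so oracle tests can state
# exact expectations.

# analytic radius functions r(theta, phi) for the three shape families
.shape_radius_fn <- function(family, radius, axes, amplitude, freq) {
  switch(family,
    sphere = function(theta, phi) rep(radius, length(theta)),
    ellipsoid = function(theta, phi) {
      sp <- sin(phi)
      1 / sqrt((sp * cos(theta) / axes[1])^2 +
               (sp * sin(theta) / axes[2])^2 +
               (cos(phi) / axes[3])^2)
    },
    sinusoid = function(theta, phi) {
      # azimuthal terms are damped by sin(phi)^m so the radius is
      # single-valued and smooth at the poles
      radius * (1 +
        amplitude * (0.6 * sin(freq[1] * theta) * sin(phi)^freq[1] * cos(freq[2] * phi) +
                     0.4 * cos((freq[1] + 1) * theta) * sin(phi)^(freq[1] + 1) *
                       sin(freq[2] * phi) +
                     0.3 * cos(freq[2] * phi)))
    },
    stop("unknown shape family: ", family)
  )
}

#' Sample a closed-surface point cloud with known analytic radius
#'
#' Points are sampled uniformly in solid angle (inverse-CDF on the
#' colatitude cosine, so poles are not over-represented) at the analytic
#' radius of the requested shape, with optional Gaussian radial noise.
#' The analytic radius function is returned for use as an oracle.
#'
#' @param n number of points.
#' @param family `"sphere"`, `"ellipsoid"` or `"sinusoid"` (a sphere
#'   modulated by smooth sinusoidal terms in both angles).
#' @param radius sphere/sinusoid base radius (nm).
#' @param axes ellipsoid semi-axes `c(a, b, c)` (nm).
#' @param amplitude relative sinusoidal amplitude (must keep the surface
#'   star-shaped, i.e. `< 1`).
#' @param freq integer angular frequencies `c(f_theta, f_phi)`.
#' @param noise sd of radial Gaussian noise (nm).
#' @param seed RNG seed.
#' @param center surface center (nm).
#' @return list with `points` (a [surface_point_set()] centred at the
#'   true center), `radius_fn(theta, phi)` and the echoed `spec`.
#' @export
gen_surface_cloud <- function(n, family = c("sphere", "ellipsoid", "sinusoid"),
                              radius = 3, axes = c(4, 3, 3), amplitude = 0.1,
                              freq = c(3, 2), noise = 0, seed = 1L,
                              center = c(0, 0, 0)) {
  family <- match.arg(family)
  if (any(c(radius, axes) <= 0)) stop("radii must be positive")
  if (family == "sinusoid" && abs(amplitude) * 1.3 >= 1)
    stop("amplitude too large: surface would not stay star-shaped")
  fn <- .shape_radius_fn(family, radius, axes, amplitude, freq)
  set.seed(seed)
  theta <- stats::runif(n, 0, 2 * pi)
  phi <- acos(stats::runif(n, -1, 1))
  r <- fn(theta, phi)
  if (noise > 0) r <- pmax(r + stats::rnorm(n, 0, noise), 1e-6)
  ps <- surface_point_set(sph2cart(r, theta, phi, center), center = center)
  list(points = ps, radius_fn = fn,
       spec = list(family = family, radius = radius, axes = axes,
                   amplitude = amplitude, freq = freq, noise = noise,
                   seed = seed, n = n, center = center))
}

#' Exact spherical grid from an analytic radius function
#'
#' Evaluates `radius_fn` at every node direction of a `bin` grid; the
#' discretization-only counterpart of [fit_grid()] for oracle tests of
#' the morphometric estimators.
#'
#' @param radius_fn function(theta, phi) returning radii (nm).
#' @param bin grid resolution.
#' @param center grid center.
#' @return a `spherical_grid`.
#' @export
grid_from_function <- function(radius_fn, bin, center = c(0, 0, 0)) {
  ang <- grid_angles(bin)
  nth <- bin + 1L; nph <- bin / 2 + 1L
  th <- rep(ang$theta, times = nph)
  ph <- rep(ang$phi, each = nth)
  r <- matrix(radius_fn(th, ph), nth, nph)
  r[, 1] <- mean(r[seq_len(bin), 1])
  r[, nph] <- mean(r[seq_len(bin), nph])
  r[nth, ] <- r[1, ]
  new_spherical_grid(bin, r, center)
}

#' Synthetic two-leaflet vesicle trajectory
#'
#' Two concentric closed-surface clouds (outer leaflet `S_up`, inner
#' `S_down`) with optional smooth sinusoidal shape drift across frames.
#' Lipid directions are fixed per leaflet and move radially with the
#' drifting shape, emulating a fluctuating vesicle.  Analytic per-frame
#' ground truth (leaflet areas per lipid, thickness, volume per lipid of
#' the static spherical pair) accompanies the frames.
#'
#' @param r_outer,r_inner leaflet radii in nm (`r_inner < r_outer`).
#' @param n_up,n_down lipids per leaflet.
#' @param n_frames number of trajectory frames.
#' @param drift relative amplitude of the sinusoidal shape drift (0 for a
#'   static spherical vesicle).
#' @param seed RNG seed.
#' @return list with `frames` (list of `interface_frame`), `index`
#'   (list `up`, `down` of 1-based atom indices), and `truth` (data.frame
#'   of analytic values for the drift-free sphere pair).
#' @export
gen_vesicle <- function(r_outer = 7, r_inner = 5, n_up = 500, n_down = 500,
                        n_frames = 1, drift = 0, seed = 1L) {
  if (r_inner >= r_outer) stop("r_inner must be smaller than r_outer")
  set.seed(seed)
  dir_up <- list(theta = stats::runif(n_up, 0, 2 * pi),
                 phi = acos(stats::runif(n_up, -1, 1)))
  dir_dn <- list(theta = stats::runif(n_down, 0, 2 * pi),
                 phi = acos(stats::runif(n_down, -1, 1)))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    ph <- 2 * pi * (f - 1) / max(1, n_frames)
    mod <- function(theta, phi) {
      1 + drift * sin(ph) * sin(2 * theta) * sin(phi)^2 * cos(2 * phi)
    }
    r_up <- r_outer * mod(dir_up$theta, dir_up$phi)
    r_dn <- r_inner * mod(dir_dn$theta, dir_dn$phi)
    xyz <- rbind(sph2cart(r_up, dir_up$theta, dir_up$phi),
                 sph2cart(r_dn, dir_dn$theta, dir_dn$phi))
    n <- n_up + n_down
    frames[[f]] <- new_frame(
      atoms = data.frame(
        serial = seq_len(n), name = "P",
        resname = c(rep("LUP", n_up), rep("LDN", n_down)),
        resid = seq_len(n), element = "P"),
      xyz = xyz, box = NULL, frame = f, time = (f - 1) * 1.0)
  }
  truth <- data.frame(
    frame = seq_len(n_frames),
    A_L_up = 4 * pi * r_outer^2 / n_up,
    A_L_down = 4 * pi * r_inner^2 / n_down,
    D_HH = r_outer - r_inner,
    V_L = (4 / 3) * pi * (r_outer^3 - r_inner^3) / (n_up + n_down))
  list(frames = frames,
       index = list(up = seq_len(n_up), down = n_up + seq_len(n_down)),
       truth = truth)
}

#' Synthetic porous unit cell with analytic void fraction
#'
#' Atoms on a cubic lattice filling an orthorhombic box, with an optional
#' spherical cavity emptied around a center.  When the lattice spacing
#' exceeds twice the thresholded atom radius the excluded spheres do not
#' overlap, so the void fraction is exactly
#' `1 - n_atoms * (4/3) pi (t r_vdw)^3 / V_box`; `theta_fn(t)` returns
#' that value.
#'
#' @param box box lengths (nm).
#' @param spacing lattice constant (nm).
#' @param r_vdw atom van der Waals radius (nm).
#' @param cavity_radius radius of the emptied spherical cavity (nm, 0 for
#'   none).
#' @param cavity_center cavity center (default box middle).
#' @param element element label for the lattice atoms.
#' @return list with `cell` (a [unit_cell()]), `theta_fn(t)` and
#'   `n_atoms`.
#' @export
gen_porous_cell <- function(box = c(2, 2, 2), spacing = 0.5, r_vdw = 0.3,
                            cavity_radius = 0, cavity_center = NULL,
                            element = "C") {
  box <- as.numeric(box)
  if (is.null(cavity_center)) cavity_center <- box / 2
  if (cavity_radius > min(box) / 2) stop("cavity larger than the box")
  k <- pmax(1, floor(box / spacing))
  actual_spacing <- box / k
  g <- lapply(1:3, function(i) (seq_len(k[i]) - 0.5) * actual_spacing[i])
  xyz <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
  colnames(xyz) <- NULL
  if (cavity_radius > 0) {
    d <- sqrt(rowSums(sweep(xyz, 2, cavity_center)^2))
    xyz <- xyz[d > cavity_radius, , drop = FALSE]
  }
  cell <- unit_cell(xyz, box, radii = rep(r_vdw, nrow(xyz)))
  n_at <- nrow(xyz)
  theta_fn <- function(t = 0.5) {
    if (2 * t * r_vdw > min(actual_spacing))
      warning("excluded spheres overlap; analytic value is only a lower bound")
    1 - n_at * (4 / 3) * pi * (t * r_vdw)^3 / prod(box)
  }
  list(cell = cell, theta_fn = theta_fn, n_atoms = n_at)
}
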