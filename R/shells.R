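#' Membrane thickness between two fitted leaflet surfaces
#'
#' Per-node difference of the radial components of the outer and inner
#' grids, `D_HH(i,j) = r_up(i,j) - r_down(i,j)`, for grids sharing bin
#' and center convention.  The spatial mean over nodes gives one
#' thickness per frame; [temporal_thickness()] averages per-node maps
#' over trajectory frames.
#'
#' @param outer,inner congruent `spherical_grid`s (same `bin`).
#' @return object of class `thickness_map`: list with the per-node matrix
#'   `d` (nm), `mean` (spatial average over distinct nodes, nm) and `bin`.
#' @export
thickness <- function(outer, inner) {
  stopifnot(inherits(outer, "spherical_grid"), inherits(inner, "spherical_grid"))
  if (outer$bin != inner$bin) stop("grids have mismatched bins")
  d <- outer$r - inner$r
  uniq <- matrix(grid_nodes(outer)$unique_mask, nrow(d), ncol(d))
  structure(list(d = d, mean = mean(d[uniq]), bin = outer$bin),
            class = "thickness_map")
}

#' Temporal thickness map over trajectory frames
#'
#' Averages per-node thickness over `NF` frames, node by node.
#'
#' @param maps list of [thickness()] results with equal bins.
#' @return a `thickness_map` whose `d` is the per-node temporal mean and
#'   whose `n_frames` records NF.
#' @export
temporal_thickness <- function(maps) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, TRUE, "thickness_map")))
  bins <- vapply(maps, `[[`, 1L, "bin")
  if (length(unique(bins)) != 1) stop("grids have mismatched bins")
  d <- Reduce(`+`, lapply(maps, `[[`, "d")) / length(maps)
  uniq <- matrix(grid_nodes(new_spherical_grid(bins[1], d, c(0, 0, 0)))$unique_mask,
                 nrow(d), ncol(d))
  structure(list(d = d, mean = mean(d[uniq]), bin = bins[1],
                 n_frames = length(maps)), class = "thickness_map")
}

#' Mid-surface between two leaflet grids
#'
#' Per-node average of the two radii,
#' `r_ref(i,j) = (r_up(i,j) + r_down(i,j)) / 2`; the reference surface
#' for shell slicing and density profiles.
#'
#' @inheritParams thickness
#' @return a `spherical_grid`.
#' @export
reference_surface <- function(outer, inner) {
  stopifnot(inherits(outer, "spherical_grid"), inherits(inner, "spherical_grid"))
  if (outer$bin != inner$bin) stop("grids have mismatched bins")
  new_spherical_grid(outer$bin, (outer$r + inner$r) / 2, outer$center)
}

#' Shape-preserving scaled copy of a grid surface
#'
#' Multiplies every node radius by the scale factor `k`; shells with the
#' same shape as the reference surface but different average radii.
#'
#' @param ref a `spherical_grid`.
#' @param k positive scale factor.
#' @return a `spherical_grid`.
#' @export
scaled_surface <- function(ref, k) {
  stopifnot(inherits(ref, "spherical_grid"))
  if (k <= 0) stop("scale factor must be positive")
  new_spherical_grid(ref$bin, ref$r * k, ref$center)
}

#' Volume of the shell between two closed surfaces
#'
#' Absolute difference of the enclosed grid volumes; for vesicle leaflets
#' this is the membrane volume `V_g^up - V_g^down`.
#'
#' @param limit_a,limit_b `spherical_grid`s bounding the shell.
#' @return shell volume in nm^3.
#' @export
shell_volume <- function(limit_a, limit_b) {
  abs(grid_volume(limit_a) - grid_volume(limit_b))
}

#' Volume per lipid
#'
#' Membrane shell volume divided by the total lipid count of both
#' leaflets.
#'
#' @param dV_sh shell volume between outer and inner surfaces, nm^3.
#' @param n_lipids total lipids `n_up + n_down` (> 0).
#' @return nm^3 per lipid.
#' @export
volume_per_lipid <- function(dV_sh, n_lipids) {
  if (n_lipids <= 0) stop("n_lipids must be positive")
  dV_sh / n_lipids
}

#' Radial number-density profile in shape-conformal shells
#'
#' Slices space around the reference surface into closed shells bounded
#' by scaled copies of the reference, uniform in the scale factor
#' `k = r / r_ref(theta, phi)` (the reference radius interpolated at each
#' particle's direction, so `k = 1` marks the reference surface).  The
#' density of each shell is its particle count over its volume, with
#' per-shell volumes computed from the grid volumes of consecutive scaled
#' surfaces, preserving the reference shape.  Particles outside
#' `[k_inf, k_sup]` are counted and reported, never silently dropped.
#'
#' @param xyz particle coordinates (n x 3, nm), same frame and unit as
#'   the reference grid.
#' @param ref reference `spherical_grid`.
#' @param k_inf,k_sup shell range in scale-factor units (`k_inf < k_sup`).
#' @param n_bins number of shells.
#' @return object of class `shell_profile`: a list with `table`
#'   (data.frame: `k_lo`, `k_hi`, `k_mid`, `count`, `volume` nm^3,
#'   `density` nm^-3), `n_out_of_range` and `n_total`.
#' @export
density_profile <- function(xyz, ref, k_inf, k_sup, n_bins) {
  stopifnot(inherits(ref, "spherical_grid"))
  if (!(k_inf < k_sup)) stop("k_inf must be smaller than k_sup")
  if (n_bins < 1) stop("need at least one bin")
  xyz <- as.matrix(xyz)
  sph <- cart2sph(xyz, ref$center)
  r_ref <- grid_interpolate(ref, sph$theta, sph$phi)
  k <- sph$r / r_ref
  edges <- seq(k_inf, k_sup, length.out = n_bins + 1)
  inside <- k >= k_inf & k <= k_sup
  bin_id <- pmin(findInterval(k[inside], edges), n_bins)
  counts <- tabulate(bin_id, n_bins)
  # volumes of consecutive scaled surfaces; grid volume scales exactly as
  # k^3, so one reference grid volume gives every shell volume
  v_ref <- grid_volume(ref)
  vols <- (edges[-1]^3 - edges[-(n_bins + 1)]^3) * v_ref
  structure(list(
    table = data.frame(
      k_lo = edges[-(n_bins + 1)], k_hi = edges[-1],
      k_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
      count = counts, volume = vols, density = counts / vols),
    n_out_of_range = sum(!inside), n_total = nrow(xyz)
  ), class = "shell_profile")
}

#' Average shell profiles over trajectory frames
#'
#' Time-average of per-frame densities (not of counts), on a common
#' k-binning.
#'
#' @param profiles list of [density_profile()] results with identical
#'   binning.
#' @return a `shell_profile` with averaged densities and summed counts.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  t1 <- profiles[[1]]$table
  dens <- rowMeans(vapply(profiles, function(p) p$table$density,
                          numeric(nrow(t1))))
  counts <- rowSums(vapply(profiles, function(p) p$table$count,
                           numeric(nrow(t1))))
  out <- t1
  out$density <- dens
  out$count <- counts
  structure(list(table = out,
                 n_out_of_range = sum(vapply(profiles, `[[`, 0, "n_out_of_range")),
                 n_total = sum(vapply(profiles, `[[`, 0, "n_total"))),
            class = "shell_profile")
}
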