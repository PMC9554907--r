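sphere_grid <- function(R = 1, bin = 60) {
  grid_from_function(function(th, ph) rep(R, length(th)), bin)
}

ellipsoid_grid <- function(a, b, c, bin = 80) {
  grid_from_function(ellipsoid_radius_fn(a, b, c), bin)
}

test_that("triangulation covers the closed surface exactly once", {
  g <- sphere_grid(1, bin = 4)
  tp <- triangulate(g)
  expect_equal(tp$n_triangles, 16)   # 2 * bin * bin/2
  # every cell contributes exactly two triangles
  g2 <- sphere_grid(1, bin = 12)
  tp2 <- triangulate(g2)
  expect_equal(tp2$n_triangles, 2 * 12 * 6)
  # vertex triples of an interior cell match the two defining index triples
  nth <- 13L
  lin <- function(i, j) (j - 1L) * nth + i
  l <- which(tp2$v_idx[, 1] == lin(3L, 3L) & tp2$v_idx[, 2] == lin(4L, 3L))
  expect_equal(tp2$v_idx[l, ], c(lin(3L, 3L), lin(4L, 3L), lin(3L, 4L)))
  l2 <- which(tp2$v_idx[, 3] == lin(4L, 4L) & tp2$v_idx[, 2] == lin(4L, 3L))
  expect_setequal(tp2$v_idx[l2, ], c(lin(4L, 4L), lin(4L, 3L), lin(3L, 4L)))
})

test_that("surface area converges to analytic values", {
  expect_equal(total_area(sphere_grid(1, 60)), 4 * pi, tolerance = 0.01)
  expect_equal(total_area(sphere_grid(2, 60)) / total_area(sphere_grid(1, 60)),
               4, tolerance = 1e-10)
  e <- ellipsoid_grid(4, 3, 3, 80)
  expect_equal(total_area(e), ellipsoid_area_quad(4, 3, 3), tolerance = 0.01)
  expect_equal(ellipsoid_area_quad(4, 3, 3), prolate_area(4, 3), tolerance = 1e-4)
  # quadratic (or better) convergence in 1/bin
  err <- vapply(c(20, 40, 80), function(b)
    abs(total_area(sphere_grid(1, b)) - 4 * pi), numeric(1))
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("enclosed volume matches analytic values and the scale law", {
  expect_equal(grid_volume(sphere_grid(1, 60)), 4 * pi / 3, tolerance = 0.01)
  e <- ellipsoid_grid(4, 3, 3, 80)
  expect_equal(grid_volume(e), 4 / 3 * pi * 36, tolerance = 0.01)
  g <- grid_from_function(function(th, ph) 1.5 + 0.2 * cos(2 * ph), 40)
  g2 <- g; g2$r <- 2 * g$r
  expect_equal(grid_volume(g2), 8 * grid_volume(g), tolerance = 1e-12)
})

test_that("volume agrees with the divergence-theorem oracle", {
  for (g in list(sphere_grid(2, 60), ellipsoid_grid(4, 3, 3, 60),
                 grid_from_function(function(th, ph)
                   3 * (1 + 0.15 * sin(2 * th) * sin(ph)^2 * cos(2 * ph)), 60))) {
    tp <- triangulate(g)
    v_div <- sum(rowSums(tp$centroid * tp$normal) * tp$area) / 3
    expect_equal(grid_volume(g), v_div, tolerance = 0.005)
  }
})

test_that("sphericity is 1 for spheres, matches prolate closed form, scale-free", {
  expect_equal(sphericity(sphere_grid(1.7, 60)), 1, tolerance = 1e-3)
  e <- ellipsoid_grid(4, 3, 3, 80)
  psi_exact <- pi^(1 / 3) * (6 * 4 / 3 * pi * 36)^(2 / 3) / prolate_area(4, 3)
  expect_equal(sphericity(e), psi_exact, tolerance = 0.01)
  e2 <- e; e2$r <- 3.7 * e$r
  expect_equal(sphericity(e2), sphericity(e), tolerance = 1e-12)
  # isoperimetric bound with discretization slack
  for (amp in c(0.1, 0.25)) {
    g <- grid_from_function(function(th, ph)
      2 * (1 + amp * sin(3 * th) * sin(ph)^3 * cos(2 * ph)), 40)
    expect_lt(sphericity(g), 1.02)
  }
})

test_that("area per lipid divides leaflet area by leaflet count", {
  expect_equal(area_per_lipid(12.566, 100), 0.12566)
  expect_equal(area_per_lipid(10, 200), area_per_lipid(10, 100) / 2)
  expect_error(area_per_lipid(10, 0), "positive")
})

test_that("deflection angles vanish on spheres and stay bounded on ellipsoids", {
  da <- deflection_angles(sphere_grid(3, 40))
  expect_lt(max(da$angles), 1e-6)
  # oblate 0.5:1:1 - spread below 65 degrees
  o <- grid_from_function(ellipsoid_radius_fn(1, 1, 0.5), 60)
  dao <- deflection_angles(o)
  expect_gt(max(dao$angles), 0.1)
  expect_lt(max(dao$angles), 65 * pi / 180)
  # analytic maximum for an axis ratio-2 ellipse: atan((a^2-b^2)/(2ab))
  expect_equal(max(dao$angles), atan(0.75), tolerance = 0.02)
})

test_that("curvature order parameter: sphere limit, 90-degree limit, eccentricity ordering", {
  expect_equal(curvature_order_parameter(sphere_grid(3, 60)), 1, tolerance = 1e-6)
  # P2 at 90 degrees is -0.5: tilt every normal by construction is not
  # reachable on a closed radial graph, so check the functional directly
  # through an ellipsoid family ordered by eccentricity instead
  sc <- vapply(c(1, 0.9, 0.75, 0.6, 0.5), function(cax)
    curvature_order_parameter(grid_from_function(ellipsoid_radius_fn(1, 1, cax), 60)),
    numeric(1))
  expect_true(all(diff(sc) < 0))
  expect_true(all(sc >= -0.5 & sc <= 1))
})

test_that("principal inertia moments: symmetry, shell oracle, rotation invariance", {
  I_sph <- inertia_principal_moments(sphere_grid(2, 40))
  expect_lt(diff(range(I_sph)) / I_sph[3], 0.005)
  I_ell <- inertia_principal_moments(ellipsoid_grid(4, 3, 3, 60))
  expect_lt(I_ell[1], I_ell[2])
  expect_equal(I_ell[2], I_ell[3], tolerance = 0.01)
  oracle <- ellipsoid_shell_inertia_quad(4, 3, 3)
  expect_equal(I_ell[1] / I_ell[3], oracle[1] / oracle[3], tolerance = 0.02)
  # rotating the surface leaves the spectrum unchanged
  cl <- gen_surface_cloud(2000, "ellipsoid", axes = c(4, 3, 3), seed = 21)
  ps <- cl$points
  R <- rotation_matrix(c(0.3, 1, 2), 1.1)
  ps_rot <- surface_point_set(ps$xyz %*% t(R),
                              center = as.numeric(R %*% ps$center))
  I1 <- inertia_principal_moments(ps)
  I2 <- inertia_principal_moments(ps_rot)
  expect_equal(I1, I2, tolerance = 1e-9)
})

test_that("roundness indices are 1 for spheres and match ellipsoid oracles", {
  g <- sphere_grid(3, 60)
  for (m in 1:3) expect_equal(roundness(g, m), 1, tolerance = 1e-3)
  e <- ellipsoid_grid(4, 3, 3, 80)
  expect_equal(roundness(e, 2), 3 / 4, tolerance = 0.01 * 3 / 4)
  oracle <- ellipsoid_shell_inertia_quad(4, 3, 3)
  expect_equal(roundness(e, 3), oracle[1] / oracle[3], tolerance = 0.02)
  expect_error(roundness(g, 4), "unknown")
})

test_that("morphometry report collects consistent columns", {
  rep <- morphometry_report(sphere_grid(3, 40), n_lipids = 500)
  expect_equal(rep$A_L, rep$A_g / 500)
  expect_equal(rep$psi_g, sphericity(rep$A_g, rep$V_g))
  expect_true(rep$I1 <= rep$I2 && rep$I2 <= rep$I3)
})
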