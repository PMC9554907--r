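# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: brute-force loops, analytic closed forms
# and plain quadrature.

# ellipsoid radius along a direction (radial graph form)
ellipsoid_radius_fn <- function(a, b, c) {
  function(theta, phi) {
    sp <- sin(phi)
    1 / sqrt((sp * cos(theta) / a)^2 + (sp * sin(theta) / b)^2 + (cos(phi) / c)^2)
  }
}

# surface area of an ellipsoid by midpoint quadrature of |r_theta x r_phi|
ellipsoid_area_quad <- function(a, b, c, n = 600) {
  th <- (seq_len(n) - 0.5) * 2 * pi / n
  ph <- (seq_len(n) - 0.5) * pi / n
  # |r_theta x r_phi| = sin(phi) sqrt(b^2c^2 sin^2 cos^2th + a^2c^2 sin^2 sin^2th + a^2b^2 cos^2)
  g <- vapply(ph, function(p) {
    s <- sin(p); cc <- cos(p)
    sum(s * sqrt((b * c * s * cos(th))^2 + (a * c * s * sin(th))^2 + (a * b * cc)^2))
  }, numeric(1))
  sum(g) * (2 * pi / n) * (pi / n)
}

# principal moments of a uniform-surface-density ellipsoidal shell,
# by the same quadrature (unit total mass scale is irrelevant for ratios)
ellipsoid_shell_inertia_quad <- function(a, b, c, n = 400) {
  th <- (seq_len(n) - 0.5) * 2 * pi / n
  ph <- (seq_len(n) - 0.5) * pi / n
  Ixx <- Iyy <- Izz <- 0
  for (p in ph) {
    s <- sin(p); cc <- cos(p)
    x <- a * s * cos(th); y <- b * s * sin(th); z <- c * cc
    dA <- s * sqrt((b * c * s * cos(th))^2 + (a * c * s * sin(th))^2 + (a * b * cc)^2)
    Ixx <- Ixx + sum(dA * (y^2 + z^2))
    Iyy <- Iyy + sum(dA * (x^2 + z^2))
    Izz <- Izz + sum(dA * (x^2 + y^2))
  }
  sort(c(Ixx, Iyy, Izz))
}

# closed-form area of a prolate spheroid (a > b = c)
prolate_area <- function(a, b) {
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + a / (b * e) * asin(e))
}

# brute-force reimplementation of the grid fit: plain double loop over
# nodes and atoms with unshifted Gaussian weights and the same fallback,
# pole and seam rules
brute_fit <- function(ps, params) {
  bin <- params$bin
  d <- 2 * pi / bin
  nth <- bin + 1; nph <- bin / 2 + 1
  r <- matrix(NA_real_, nth, nph)
  for (i in seq_len(nth)) {
    for (j in seq_len(nph)) {
      tg <- d * (i - 1); pg <- d * (j - 1)
      ca <- acos(pmin(pmax(cos(pg) * cos(ps$phi) +
                             sin(pg) * sin(ps$phi) * cos(tg - ps$theta), -1), 1))
      dd <- ps$r * ca
      sel <- dd <= params$r_c
      if (!any(sel)) sel <- rep(TRUE, length(dd))
      w <- exp(-(dd[sel]^2 - min(dd[sel]^2)) / (2 * params$alpha^2))
      r[i, j] <- sum(w * ps$r[sel]) / sum(w)
    }
  }
  r[, 1] <- mean(r[seq_len(bin), 1])
  r[, nph] <- mean(r[seq_len(bin), nph])
  r[nth, ] <- r[1, ]
  r
}

# rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
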