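# Internal coordinate helpers.  All lengths in nm, angles in radians.
# Spherical convention: theta = azimuth in [0, 2*pi), phi = polar angle
# (colatitude) in [0, pi], so phi = 0 is the +z pole.

cart2sph <- function(xyz, center = c(0, 0, 0)) {
  d <- sweep(as.matrix(xyz), 2, center)
  r <- sqrt(rowSums(d^2))
  phi <- ifelse(r > 0, acos(pmin(1, pmax(-1, d[, 3] / r))), 0)
  theta <- atan2(d[, 2], d[, 1]) %% (2 * pi)
  list(r = r, theta = theta, phi = phi)
}

sph2cart <- function(r, theta, phi, center = c(0, 0, 0)) {
  cbind(
    center[1] + r * sin(phi) * cos(theta),
    center[2] + r * sin(phi) * sin(theta),
    center[3] + r * cos(phi)
  )
}

clamp1 <- function(x) pmin(pmax(x, -1), 1)   # keeps dim attributes

# cross product of rows of two n x 3 matrices
row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
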