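# shared fixtures, built in code

# smooth asymmetric blob volume: broad Gaussians keep interpolation error
# well below the tolerances of the resampling oracles
smooth_blob_volume <- function(n = 64, pixel_size = 4,
                               blobs = list(c(0, 0, 0, 5),
                                            c(6, -4, 3, 4),
                                            c(-5, 5, -4, 4.5))) {
  u <- seq_len(n) - 1 - n / 2
  g <- array(0, c(n, n, n))
  for (b in blobs) {
    gx <- exp(-(u - b[1])^2 / (2 * b[4]^2))
    gy <- exp(-(u - b[2])^2 / (2 * b[4]^2))
    gz <- exp(-(u - b[3])^2 / (2 * b[4]^2))
    g <- g + gx %o% gy %o% gz
  }
  density_volume(g, pixel_size)
}

# spherically symmetric Gaussian volume
spherical_volume <- function(n = 64, sigma = 5, pixel_size = 4) {
  u <- seq_len(n) - 1 - n / 2
  r2 <- outer(outer(u^2, u^2, "+"), u^2, "+")
  density_volume(array(exp(-r2 / (2 * sigma^2)), c(n, n, n)), pixel_size)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2) + 1e-300)

# random projection direction (uniform over the sphere)
random_direction <- function() {
  z <- runif(1, -1, 1)
  c(phi = runif(1, 0, 360), theta = 180 / pi * acos(z))
}

# direct textbook evaluation of the correlation coefficient over selected
# pixels (independent of the package's accumulation path)
ccc_oracle <- function(a, b, sel = TRUE) {
  x <- a[sel]; y <- b[sel]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# rotation-matrix parallel transport of the in-plane angle, written
# independently of the package internals
transport_oracle <- function(phi0, theta0, psi0, phi1, theta1) {
  e0 <- direction_to_vector(phi0, theta0)
  e1 <- direction_to_vector(phi1, theta1)
  a <- acos(max(min(sum(e0 * e1), 1), -1))
  ax <- c(e0[2] * e1[3] - e0[3] * e1[2],
          e0[3] * e1[1] - e0[1] * e1[3],
          e0[1] * e1[2] - e0[2] * e1[1])
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  Rm <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  eu <- matrix_to_euler(euler_matrix(phi0, theta0, psi0) %*% t(Rm))
  unname(eu["psi"])
}

angdiff_abs <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
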