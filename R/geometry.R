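# Coordinate conventions
# ----------------------
# A projection direction is the spherical angle pair (phi, theta) in degrees:
# phi azimuthal in [0, 360), theta polar in [0, 180].  The five alignment
# parameters of a particle or module are (phi, theta, psi, x, y): the
# direction, the in-plane rotation psi (degrees, angle between the camera
# frame and the local meridian) and the in-plane translation (x, y) in
# pixels (the projected object moves by +x, +y in the image).
#
# Orientations are stored as degrees externally; all trigonometry is done in
# double precision radians internally.  The Euler convention is ZYZ
# intrinsic (SPIDER-compatible): rotate by phi about z, theta about the new
# y, psi about the new z; the projection integrates along the final z axis.

#' Construct an orientation parameter set
#'
#' Bundles the five projection parameters of one particle (or of one module
#' within a particle) into a named numeric vector.
#'
#' @param phi,theta Projection direction in degrees (`phi` azimuthal,
#'   `theta` polar in `[0, 180]`).
#' @param psi In-plane rotation in degrees.
#' @param x,y In-plane translation in pixels; the projected object moves by
#'   `(+x, +y)` in the image.
#' @return A named numeric vector of class `orientation_params`.
#' @export
orientation_params <- function(phi = 0, theta = 0, psi = 0, x = 0, y = 0) {
  check_finite(c(phi, theta, psi, x, y), "orientation parameters")
  if (theta < -1e-9 || theta > 180 + 1e-9)
    stop_invalid("theta must lie in [0, 180] degrees")
  out <- c(phi = wrap360(unname(phi)), theta = min(max(unname(theta), 0), 180),
           psi = wrap360(unname(psi)), x = unname(x), y = unname(y))
  class(out) <- "orientation_params"
  out
}

as_params <- function(p) {
  if (inherits(p, "orientation_params")) return(p)
  if (is.data.frame(p)) p <- unlist(p[1, c("phi", "theta", "psi", "x", "y")])
  p <- as.numeric(p[c("phi", "theta", "psi", "x", "y")])
  names(p) <- c("phi", "theta", "psi", "x", "y")
  orientation_params(p["phi"], p["theta"], p["psi"], p["x"], p["y"])
}

#' Unit vector of a projection direction
#'
#' Maps spherical angles to the unit direction vector
#' `(sin(theta) cos(phi), sin(theta) sin(phi), cos(theta))`.
#'
#' @param phi,theta Direction angles in degrees; vectors are accepted and
#'   recycled element-wise.
#' @return An `n x 3` matrix of unit vectors (a plain length-3 vector for a
#'   single direction).
#' @export
direction_to_vector <- function(phi, theta) {
  check_finite(phi, "phi"); check_finite(theta, "theta")
  p <- deg2rad(phi); t <- deg2rad(theta)
  v <- cbind(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  if (nrow(v) == 1L) drop(v) else v
}

#' Spherical angles of unit vectors
#'
#' Inverse of [direction_to_vector()]. At the poles the azimuth is not
#' determined; `phi = 0` is returned there (the `phi = 0` meridian limit).
#'
#' @param v A length-3 vector or an `n x 3` matrix; need not be normalized.
#' @return A data frame with columns `phi`, `theta` (degrees).
#' @export
vector_to_direction <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  check_finite(v, "direction vector")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-300)) stop_invalid("zero-length direction vector")
  v <- v / nrm
  theta <- rad2deg(acos(pmin(pmax(v[, 3], -1), 1)))
  phi <- wrap360(rad2deg(atan2(v[, 2], v[, 1])))
  phi[abs(v[, 1]) < 1e-15 & abs(v[, 2]) < 1e-15] <- 0
  data.frame(phi = phi, theta = theta)
}

#' Span angle between two projection directions
#'
#' The great-circle angle `arccos(e_r0 . e_r1)` in degrees, with the dot
#' product clamped to `[-1, 1]`.
#'
#' @param phi0,theta0,phi1,theta1 Direction angles in degrees (vectorized).
#' @return Span angle(s) in `[0, 180]` degrees.
#' @export
span_angle <- function(phi0, theta0, phi1, theta1) {
  check_finite(c(phi0, theta0, phi1, theta1), "direction angles")
  t0 <- deg2rad(theta0); t1 <- deg2rad(theta1)
  d <- sin(t0) * sin(t1) * cos(deg2rad(phi0 - phi1)) + cos(t0) * cos(t1)
  rad2deg(acos(pmin(pmax(d, -1), 1)))
}

#' Passive ZYZ Euler matrix
#'
#' The 3x3 frame matrix `A` with `camera = A %*% object`: rows are the
#' camera axes expressed in object coordinates.  Its third row is the
#' projection direction unit vector; the projection integrates along it.
#'
#' @param phi,theta,psi Euler angles in degrees.
#' @return A 3x3 orthonormal matrix.
#' @export
euler_matrix <- function(phi, theta, psi) {
  check_finite(c(phi, theta, psi), "Euler angles")
  cp <- cos(deg2rad(phi)); sp <- sin(deg2rad(phi))
  ct <- cos(deg2rad(theta)); st <- sin(deg2rad(theta))
  cs <- cos(deg2rad(psi)); ss <- sin(deg2rad(psi))
  rz_phi <- matrix(c(cp, -sp, 0, sp, cp, 0, 0, 0, 1), 3, 3)
  ry_th  <- matrix(c(ct, 0, st, 0, 1, 0, -st, 0, ct), 3, 3)
  rz_psi <- matrix(c(cs, -ss, 0, ss, cs, 0, 0, 0, 1), 3, 3)
  rz_psi %*% ry_th %*% rz_phi
}

#' Euler angles of a frame matrix
#'
#' Inverse of [euler_matrix()]; at `theta` in `{0, 180}` the split between
#' `phi` and `psi` is degenerate and `phi = 0` is returned.
#'
#' @param A A 3x3 orthonormal frame matrix.
#' @return Named numeric vector `(phi, theta, psi)` in degrees.
#' @export
matrix_to_euler <- function(A) {
  check_finite(A, "frame matrix")
  theta <- rad2deg(acos(min(max(A[3, 3], -1), 1)))
  st <- sin(deg2rad(theta))
  if (st > 1e-9) {
    phi <- wrap360(rad2deg(atan2(A[3, 2], A[3, 1])))
    psi <- wrap360(rad2deg(atan2(A[2, 3], -A[1, 3])))
  } else {
    # pole: define the reference via the phi = 0 meridian limit; with
    # phi = 0, A = Rz(psi) Ry(theta) has A[1,2] = sin(psi), A[2,2] = cos(psi)
    phi <- 0
    psi <- wrap360(rad2deg(atan2(A[1, 2], A[2, 2])))
  }
  c(phi = phi, theta = theta, psi = psi)
}

#' Quasi-uniform direction set on the sphere
#'
#' Deterministic spiral-lattice covering (Saff-Kuijlaars) of the sphere (or
#' upper hemisphere) with approximately one direction per
#' `spacing_deg^2` square degrees.
#'
#' @param spacing_deg Target angular spacing between neighbours, degrees.
#' @param hemisphere If `TRUE`, cover only `theta <= 90`.
#' @param max_points Resource cap on the set size.
#' @return Data frame with columns `phi`, `theta` (degrees).
#' @export
generate_direction_set <- function(spacing_deg, hemisphere = FALSE,
                                   max_points = 2e6) {
  check_finite(spacing_deg, "spacing")
  if (spacing_deg <= 0) stop_invalid("spacing must be positive")
  sphere_deg2 <- 360^2 / pi            # 41252.96 square degrees
  n <- ceiling((if (hemisphere) sphere_deg2 / 2 else sphere_deg2) /
                 spacing_deg^2)
  n <- max(n, 8L)
  if (n > max_points)
    stop_resource(sprintf("direction set of %d points exceeds cap %d",
                          n, as.integer(max_points)))
  k <- seq_len(n)
  h <- if (hemisphere) (k - 1) / (n - 1) else -1 + 2 * (k - 1) / (n - 1)
  theta <- rad2deg(acos(pmin(pmax(h, -1), 1)))
  phi <- numeric(n)
  for (i in 2:n) {
    if (abs(h[i]) >= 1 - 1e-12) { phi[i] <- 0; next }
    phi[i] <- (phi[i - 1] + 3.6 / sqrt(n * (1 - h[i]^2))) %% (2 * pi)
  }
  data.frame(phi = wrap360(rad2deg(phi)), theta = theta)
}

#' Constrain a direction set to a cone
#'
#' Keeps the members of `directions` whose span angle from
#' `(phi0, theta0)` is at most `alpha0`; the centre direction itself is
#' appended when no retained member coincides with it, so the preliminary
#' direction is always part of the search.
#'
#' @param directions Data frame with columns `phi`, `theta`.
#' @param phi0,theta0 Cone centre, degrees.
#' @param alpha0 Cone semi-angle, degrees.
#' @return Data frame with columns `phi`, `theta`, `span` (degrees from the
#'   centre).
#' @export
constrain_directions <- function(directions, phi0, theta0, alpha0) {
  if (nrow(directions) == 0L) stop_invalid("empty direction set")
  check_finite(alpha0, "alpha0")
  sp <- span_angle(directions$phi, directions$theta, phi0, theta0)
  keep <- sp <= alpha0 + 1e-9
  out <- data.frame(phi = directions$phi[keep], theta = directions$theta[keep],
                    span = sp[keep])
  if (!any(out$span < 1e-7))
    out <- rbind(data.frame(phi = wrap360(phi0), theta = theta0, span = 0), out)
  out[order(out$span), , drop = FALSE]
}

#' Parallel-transported in-plane rotation
#'
#' When the projection direction moves from `(phi0, theta0)` to
#' `(phi_i, theta_i)` along the great-circle arc, the camera that keeps its
#' angle with the arc unchanged (parallel transport) changes its apparent
#' in-plane rotation.  This returns the transported `psi_i`: the camera
#' frame at the new direction is the minimal rotation (about the axis
#' `e_r0 x e_ri`) of the frame `(phi0, theta0, psi0)`.
#'
#' For directions on a common meridian plane (including paths over a pole)
#' this reduces to the closed form `psi_i = phi0 + psi0 - phi_i`.
#'
#' @param phi0,theta0 Starting direction, degrees.
#' @param psi0 Starting in-plane rotation, degrees.
#' @param phi_i,theta_i Target direction(s), degrees (vectorized).
#' @return Transported `psi_i` in `[0, 360)` degrees.
#' @export
transported_psi <- function(phi0, theta0, psi0, phi_i, theta_i) {
  check_finite(c(phi0, theta0, psi0, phi_i, theta_i), "angles")
  n <- max(length(phi_i), length(theta_i))
  phi_i <- rep_len(phi_i, n); theta_i <- rep_len(theta_i, n)
  e0 <- direction_to_vector(phi0, theta0)
  A0 <- euler_matrix(phi0, theta0, psi0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ei <- direction_to_vector(phi_i[i], theta_i[i])
    cosa <- min(max(sum(e0 * ei), -1), 1)
    if (cosa <= -1 + 1e-12)
      stop_invalid("antipodal directions: transport is ill-posed")
    if (cosa >= 1 - 1e-15) { out[i] <- wrap360(psi0); next }
    ax <- c(e0[2] * ei[3] - e0[3] * ei[2],
            e0[3] * ei[1] - e0[1] * ei[3],
            e0[1] * ei[2] - e0[2] * ei[1])
    ax <- ax / sqrt(sum(ax^2))
    a <- acos(cosa)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    Rmin <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
    Anew <- A0 %*% t(Rmin)
    B <- euler_matrix(phi_i[i], theta_i[i], 0)
    M <- Anew %*% t(B)
    out[i] <- wrap360(rad2deg(atan2(M[1, 2], M[1, 1])))
  }
  out
}

#' Local search specification
#'
#' The five-parameter local search range: a cone of semi-angle `alpha0`
#' around the preliminary direction (intersected with the direction set
#' `directions`), an in-plane rotation grid of step `d1` and half-extent
#' `t1` steps centred on the transported `psi`, and an in-plane shift grid
#' of step `d2` and half-extent `t2` steps centred on the preliminary shift.
#'
#' Defaults follow the reference benchmark: a 10 degree cone, 2 degree
#' angular step, 1 pixel shift step, shifts from -4 to 4 pixels; the psi
#' grid spans +/- 6 degrees, about 3.6 standard deviations of the module
#' rotation it has to absorb.
#'
#' @param alpha0 Cone semi-angle, degrees.
#' @param d1 Psi step, degrees; `t1` half-extent in steps.
#' @param t1,t2 Non-negative integer half-extents.
#' @param d2 Shift step, pixels.
#' @param directions Optional direction set (data frame `phi`, `theta`);
#'   defaults to [generate_direction_set()] at spacing `d1`.
#' @return An object of class `search_range`.
#' @export
search_range <- function(alpha0 = 10, d1 = 2, t1 = 3, d2 = 1, t2 = 4,
                         directions = NULL) {
  check_finite(c(alpha0, d1, t1, d2, t2), "search range")
  if (alpha0 < 0 || d1 <= 0 || d2 <= 0) stop_invalid("alpha0 >= 0, d1 > 0, d2 > 0 required")
  if (t1 < 0 || t2 < 0 || t1 != round(t1) || t2 != round(t2))
    stop_invalid("t1, t2 must be non-negative integers")
  if (is.null(directions)) directions <- generate_direction_set(d1)
  if (nrow(directions) == 0L) stop_invalid("direction set must be nonempty")
  structure(list(alpha0 = alpha0, d1 = d1, t1 = as.integer(t1),
                 d2 = d2, t2 = as.integer(t2), directions = directions),
            class = "search_range")
}

# structured local grid used by the optimizers: constrained directions,
# per-direction psi grids (transported centres) and shift offsets
local_grid <- function(params0, range) {
  p0 <- as_params(params0)
  dirs <- constrain_directions(range$directions, p0["phi"], p0["theta"],
                               range$alpha0)
  psic <- transported_psi(p0["phi"], p0["theta"], p0["psi"],
                          dirs$phi, dirs$theta)
  psi_off <- range$d1 * seq(-range$t1, range$t1)
  psis <- outer(psic, psi_off, "+")     # nd x np, absolute degrees
  off <- range$d2 * seq(-range$t2, range$t2)
  list(params0 = p0, dirs = dirs, psi_centers = psic, psis = psis,
       psi_off = psi_off, off = off)
}

#' Build the local five-parameter search grid
#'
#' Cartesian product of the cone-constrained directions, the in-plane
#' rotation grid centred on the parallel-transported `psi` of each
#' direction, and the shift grid centred on the preliminary translation.
#' The preliminary parameter point is always a grid member (exactly once),
#' so a local search can never score worse than its starting point.
#'
#' @param params0 Preliminary parameters ([orientation_params()] or a named
#'   vector).
#' @param range A [search_range()].
#' @param cap Resource cap on the number of grid points.
#' @return Data frame with columns `phi`, `theta`, `psi`, `x`, `y` plus
#'   bookkeeping columns `span` (degrees from the preliminary direction),
#'   `dpsi` (offset from the transported centre) and `dshift` (pixels).
#' @export
build_search_grid <- function(params0, range, cap = 1e6) {
  g <- local_grid(params0, range)
  nd <- nrow(g$dirs); np <- length(g$psi_off); ns <- length(g$off)
  total <- nd * np * ns^2
  if (total > cap)
    stop_resource(sprintf("search grid of %d points exceeds cap %d",
                          total, as.integer(cap)))
  # nested order must match the optimizer scoring order:
  # directions (outer), psi, y offset, x offset (inner)
  idx_d <- rep(seq_len(nd), each = np * ns * ns)
  idx_p <- rep(rep(seq_len(np), each = ns * ns), times = nd)
  idx_y <- rep(rep(seq_len(ns), each = ns), times = nd * np)
  idx_x <- rep(seq_len(ns), times = nd * np * ns)
  data.frame(
    phi = g$dirs$phi[idx_d],
    theta = g$dirs$theta[idx_d],
    psi = wrap360(g$psis[cbind(idx_d, idx_p)]),
    x = g$params0["x"] + g$off[idx_x],
    y = g$params0["y"] + g$off[idx_y],
    span = g$dirs$span[idx_d],
    dpsi = abs(g$psi_off[idx_p]),
    dshift = sqrt(g$off[idx_x]^2 + g$off[idx_y]^2)
  )
}
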