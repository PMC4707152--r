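# Synthetic two-module benchmark.
# The generator emulates the validation protocol: a two-module phantom
# whose modules are independently rotated about a random axis through their
# own centre (angle ~ N(0, 1.67 deg)) and shifted (each axis ~ N(0, 1 px))
# per particle, projected once in a random global orientation, then
# degraded with Gaussian noise at a fixed signal-to-noise ratio (variance
# ratio over the full frame) or with a simple analytic CTF across defocus
# groups.  All randomness flows from one master seed; per-particle streams
# are keyed by particle index.

#' Module perturbation model
#'
#' @param sigma_rot Standard deviation of the rotation angle, degrees.
#' @param sigma_shift Standard deviation of each shift component, pixels.
#' @return Object of class `perturbation_model`.
#' @export
perturbation_model <- function(sigma_rot = 1.67, sigma_shift = 1.0) {
  check_finite(c(sigma_rot, sigma_shift), "perturbation sigmas")
  if (sigma_rot < 0 || sigma_shift < 0) stop_invalid("sigmas must be >= 0")
  structure(list(sigma_rot = sigma_rot, sigma_shift = sigma_shift),
            class = "perturbation_model")
}

#' Draw one rigid module perturbation
#'
#' The rotation axis is uniform on the sphere (normalized Gaussian draw),
#' the rotation angle is `N(0, sigma_rot^2)` and the three shift
#' components are iid `N(0, sigma_shift^2)`.  Uses the current RNG state.
#'
#' @param model A [perturbation_model()].
#' @return List with `axis` (unit 3-vector), `angle` (degrees) and
#'   `shift` (3-vector, pixels).
#' @export
sample_module_perturbation <- function(model = perturbation_model()) {
  ax <- rnorm(3)
  while (sum(ax^2) < 1e-12) ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  list(axis = ax,
       angle = rnorm(1, 0, model$sigma_rot),
       shift = rnorm(3, 0, model$sigma_shift))
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues formula; active rotation by `angle` degrees about the unit
#' axis.
#'
#' @param axis Length-3 vector (normalized internally).
#' @param angle Rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle) {
  check_finite(c(axis, angle), "axis-angle")
  axis <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# deterministic low-discrepancy (Halton) points in [0,1)^3: the blob
# positions that give the phantom a dense, asymmetric internal texture
halton3 <- function(k) {
  vdc <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
    r
  }
  cbind(vapply(k, vdc, 0, base = 2), vapply(k, vdc, 0, base = 3),
        vapply(k, vdc, 0, base = 5))
}

# blob cluster filling an ellipsoid with quasi-random texture
ellipsoid_cluster <- function(center, axes, n_blobs, sigma_cycle, amp_cycle,
                              offset = 0, xmax = Inf, xmin = -Inf) {
  p <- 2 * halton3(seq_len(12 * n_blobs) + offset) - 1
  p <- p[rowSums(p^2) <= 1, , drop = FALSE]
  centers <- sweep(p %*% diag(axes), 2, center, "+")
  sigma <- rep_len(sigma_cycle, nrow(centers))
  # keep blobs whose 2.5-sigma extent stays on the module's side
  keep <- centers[, 1] + 2.5 * sigma <= xmax &
    centers[, 1] - 2.5 * sigma >= xmin
  sel <- which(keep)[seq_len(n_blobs)]
  list(centers = centers[sel, , drop = FALSE],
       sigma = sigma[sel],
       amp = rep_len(amp_cycle, nrow(centers))[sel])
}

# default layout: two adjoining, asymmetric, densely textured modules of
# unequal mass on either side of the x = 0.5 voxel plane (units of n/64)
phantom_geometry <- function() {
  list(
    module1 = ellipsoid_cluster(c(-10.5, 0.5, -0.5), c(11.5, 9.5, 8.5), 56,
                                c(1.3, 1.7, 2.2, 1.5, 2.8, 1.4),
                                c(1.0, 0.7, 0.5, 0.9, 0.4, 0.8),
                                xmax = 0.5),
    module2 = ellipsoid_cluster(c(10.0, 1.0, 0.5), c(8.5, 7.5, 7.0), 34,
                                c(1.3, 1.6, 2.1, 1.4, 2.5),
                                c(1.0, 0.8, 0.5, 0.9, 0.6), offset = 701,
                                xmin = 0.5),
    split_x = 0.5)
}

#' Two-module benchmark phantom
#'
#' A deterministic pair of compact, asymmetric, adjoining blob clusters of
#' unequal mass (default mass ratio 2:1, mimicking the large and small
#' subunits of a two-subunit complex), with complementary binary half-space
#' masks separating the modules.
#'
#' @param n Box side in voxels (>= 32).
#' @param pixel_size Angstrom per voxel.
#' @param mass_ratio Integrated density ratio module 1 : module 2.
#' @param geometry Blob layout; see the default for the expected structure.
#' @return List with `volume` (a [density_volume()]) and `masks` (list of
#'   two binary arrays, module 1 then module 2, which partition the box).
#' @export
two_module_phantom <- function(n = 64, pixel_size = 4, mass_ratio = 2,
                               geometry = phantom_geometry()) {
  if (n < 32) stop_invalid("phantom box must be at least 32 voxels")
  scale <- n / 64
  u <- seq_len(n) - 1 - n / 2
  blob_cluster <- function(spec) {
    g <- array(0, c(n, n, n))
    for (b in seq_len(nrow(spec$centers))) {
      ctr <- spec$centers[b, ] * scale
      s <- spec$sigma[b] * scale
      gx <- exp(-(u - ctr[1])^2 / (2 * s^2))
      gy <- exp(-(u - ctr[2])^2 / (2 * s^2))
      gz <- exp(-(u - ctr[3])^2 / (2 * s^2))
      g <- g + spec$amp[b] * (gx %o% gy %o% gz)
    }
    g
  }
  # centre the complex: an off-centre overall centroid would give global
  # alignment a lever arm trading orientation against sub-pixel shifts
  w1 <- geometry$module1$amp * geometry$module1$sigma^3
  w2 <- geometry$module2$amp * geometry$module2$sigma^3
  m2scale <- sum(w1) / sum(w2) / mass_ratio
  ctr <- (crossprod(geometry$module1$centers, w1) +
            crossprod(geometry$module2$centers, w2 * m2scale)) /
    (sum(w1) + sum(w2) * m2scale)
  geometry$module1$centers <- sweep(geometry$module1$centers, 2, drop(ctr))
  geometry$module2$centers <- sweep(geometry$module2$centers, 2, drop(ctr))
  geometry$split_x <- geometry$split_x - ctr[1]
  g1 <- blob_cluster(geometry$module1)
  g2 <- blob_cluster(geometry$module2)
  split <- geometry$split_x * scale
  m1 <- array(rep(u <= split, n * n), c(n, n, n))
  # modules must live on their own side of the split plane
  leak1 <- sum(g1[!m1]) / sum(g1)
  leak2 <- sum(g2[m1]) / sum(g2)
  if (leak1 > 0.01 || leak2 > 0.01)
    stop_invalid("phantom modules overlap the split plane")
  g2 <- g2 * (sum(g1) / sum(g2) / mass_ratio)
  list(volume = density_volume(g1 + g2, pixel_size),
       masks = list(m1 * 1, (!m1) * 1))
}

#' Generate one synthetic particle
#'
#' Each module (volume times its mask) is independently rotated about its
#' own centre of density and shifted in one resampling pass, the perturbed
#' modules are summed, projected with the global parameters, and optionally
#' degraded.
#'
#' @param volume The phantom [density_volume()].
#' @param masks List of binary module masks.
#' @param perturbations List (one per module) of perturbation records as
#'   from [sample_module_perturbation()].
#' @param global_params Global [orientation_params()] of the particle.
#' @param degradation `NULL`, or a list `list(type = "gaussian", snr = )`
#'   (noise added by the caller's RNG) or
#'   `list(type = "ctf", ctf = ctf_params, snr = )`.
#' @return List with `image`, `truth` (global params, per-module
#'   transforms and module centres).
#' @export
generate_particle <- function(volume, masks, perturbations, global_params,
                              degradation = NULL, precomputed = NULL) {
  g <- as_volume_grid(volume)
  n <- dim(g)[1]
  if (is.null(precomputed)) precomputed <- precompute_modules(g, masks)
  pert_sum <- array(0, c(n, n, n))
  centers <- vector("list", length(masks))
  for (m in seq_along(masks)) {
    pc <- precomputed[[m]]
    centers[[m]] <- pc$center
    pr <- perturbations[[m]]
    R <- axis_angle_matrix(pr$axis, pr$angle)
    vm <- rotate_shift_volume(density_volume(pc$grid, volume$pixel_size),
                              matrix = R, shift3d = pr$shift,
                              center = pc$center, support = pc$sr)
    pert_sum <- pert_sum + as_volume_grid(vm)
  }
  img <- project(density_volume(pert_sum, volume$pixel_size), global_params,
                 support = attr(precomputed, "whole_sr") + 4)
  if (!is.null(degradation) && degradation$type == "ctf")
    img <- apply_ctf(img, degradation$ctf)
  if (!is.null(degradation) && !is.null(degradation$snr))
    img <- add_gaussian_noise(img, degradation$snr)
  list(image = img,
       truth = list(global = as_params(global_params),
                    perturbations = perturbations,
                    centers = centers))
}

# per-module grids, centres and support radii shared across particles
precompute_modules <- function(g, masks) {
  out <- lapply(masks, function(m) {
    gm <- g * as_volume_grid(m)
    list(grid = gm, center = center_of_density(gm),
         sr = support_radius(gm))
  })
  attr(out, "whole_sr") <- support_radius(g)
  out
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' SNR is defined as the ratio of the signal variance to the noise
#' variance, both over the full image frame; the added noise is zero-mean
#' Gaussian with variance `var(img) / snr`.  Uses the current RNG state.
#'
#' @param img Image matrix (non-constant).
#' @param snr Positive signal-to-noise ratio.
#' @return Noisy image.
#' @export
add_gaussian_noise <- function(img, snr) {
  check_finite(snr, "snr")
  if (snr <= 0) stop_invalid("snr must be positive")
  v <- var(as.numeric(img))
  if (v <= 0) stop_invalid("constant image: SNR undefined")
  img + matrix(rnorm(length(img), 0, sqrt(v / snr)), nrow(img))
}

# deterministic per-particle RNG stream key (kept well below 2^31)
particle_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

# per-particle random conditions under the particle's own RNG stream:
# global orientation uniform over the sphere, psi uniform, zero global
# shift, one perturbation per module
draw_particle_conditions <- function(seed, index,
                                     perturbation = perturbation_model(),
                                     n_modules = 2) {
  set.seed(particle_seed(seed, index))
  z <- runif(1, -1, 1)
  gp <- orientation_params(phi = runif(1, 0, 360),
                           theta = rad2deg(acos(z)),
                           psi = runif(1, 0, 360))
  list(global = gp,
       perturbations = replicate(n_modules,
                                 sample_module_perturbation(perturbation),
                                 simplify = FALSE))
}

#' Generate a synthetic two-module dataset
#'
#' Global orientations are uniform over the sphere, `psi` uniform in
#' `[0, 360)` and global shifts zero; each particle gets independent module
#' perturbations; degradation is Gaussian noise at a fixed SNR or a simple
#' CTF (defocus groups assigned round-robin) followed by noise.  Fully
#' reproducible from the seed: particle `i` is generated under its own RNG
#' stream keyed by `(seed, i)`.
#'
#' @param n_particles Number of particles.
#' @param phantom Output of [two_module_phantom()] (built at defaults when
#'   `NULL`).
#' @param perturbation A [perturbation_model()].
#' @param degradation As in [generate_particle()]; for CTF mode, a list
#'   `list(type = "ctf", defocus = c(...), snr = , voltage = , cs = ,
#'   amplitude_contrast = )` where `defocus` is in micrometres.
#' @param seed Master seed.
#' @return A [particle_stack()] whose `params` table holds the global
#'   (preliminary) parameters and whose `truth` holds per-particle module
#'   transforms.
#' @export
generate_dataset <- function(n_particles, phantom = NULL,
                             perturbation = perturbation_model(),
                             degradation = list(type = "gaussian", snr = 0.25),
                             seed = 1) {
  if (n_particles < 1) stop_invalid("need at least one particle")
  if (is.null(phantom)) phantom <- two_module_phantom()
  n <- vol_side(phantom$volume)
  imgs <- array(0, c(n, n, n_particles))
  truth <- vector("list", n_particles)
  defgrp <- rep(NA_integer_, n_particles)
  ctf_list <- NULL
  if (!is.null(degradation) && degradation$type == "ctf") {
    ndef <- length(degradation$defocus)
    defgrp <- ((seq_len(n_particles) - 1L) %% ndef) + 1L
    ctf_list <- lapply(degradation$defocus, function(df)
      ctf_params(voltage = degradation$voltage %||% 200,
                 cs = degradation$cs %||% 2.7, defocus = df,
                 amplitude_contrast = degradation$amplitude_contrast %||% 0.07,
                 pixel_size = phantom$volume$pixel_size))
  }
  params <- data.frame(index = seq_len(n_particles), phi = 0, theta = 0,
                       psi = 0, x = 0, y = 0)
  pre <- precompute_modules(as_volume_grid(phantom$volume), phantom$masks)
  for (i in seq_len(n_particles)) {
    cond <- draw_particle_conditions(seed, i, perturbation)
    gp <- cond$global
    perts <- cond$perturbations
    deg <- degradation
    if (!is.null(deg) && deg$type == "ctf") deg$ctf <- ctf_list[[defgrp[i]]]
    pt <- generate_particle(phantom$volume, phantom$masks, perts, gp, deg,
                            precomputed = pre)
    imgs[, , i] <- pt$image
    truth[[i]] <- pt$truth
    params[i, c("phi", "theta", "psi")] <- gp[c("phi", "theta", "psi")]
  }
  if (!all(is.na(defgrp))) params$defocus_group <- defgrp
  st <- particle_stack(imgs, phantom$volume$pixel_size, params, truth)
  st$phantom <- phantom
  st$seed <- seed
  st$ctf <- ctf_list
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth module parameters in the recentred frame
#'
#' The perturbed target module of a particle, viewed in the frame where the
#' unperturbed module centre sits at the box centre, projects exactly like
#' the recentred module volume with frame `B = A_g R_m` and in-plane shift
#' `(A_g (c + s) - B (c + t))_xy` added to the global translation, where
#' `A_g` is the global frame, `R_m`/`s` the module rotation/shift, `c` the
#' module centre and `t` the model recentring translation.  Used to measure
#' parameter recovery on synthetic data.
#'
#' @param truth One per-particle truth record from [generate_dataset()].
#' @param module Module index (1 or 2).
#' @param recenter_shift The `shift3d` returned by [recenter_model()].
#' @return [orientation_params()] of the module in the recentred frame.
#' @export
module_truth_params <- function(truth, module, recenter_shift) {
  gp <- truth$global
  A <- euler_matrix(gp["phi"], gp["theta"], gp["psi"])
  pr <- truth$perturbations[[module]]
  Rm <- axis_angle_matrix(pr$axis, pr$angle)
  B <- A %*% Rm
  cc <- truth$centers[[module]]
  d <- A %*% (cc + pr$shift) - B %*% (cc + recenter_shift)
  eu <- matrix_to_euler(B)
  orientation_params(eu["phi"], eu["theta"], eu["psi"],
                     gp["x"] + d[1], gp["y"] + d[2])
}
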