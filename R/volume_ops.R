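# Volume transformation, projection, module splitting and recentring,
# composite simulated projections, CTF application and non-target signal
# subtraction.

#' Split a model into target module and remainder
#'
#' Voxel-wise `vol * mask` and `vol * (1 - mask)`; the two parts sum back
#' to the input exactly.
#'
#' @param vol A [density_volume()].
#' @param mask 3D array of weights in `[0, 1]`, same shape as the volume
#'   (binary or soft).
#' @return List with elements `target` and `remainder`.
#' @export
split_volume <- function(vol, mask) {
  g <- as_volume_grid(vol)
  m <- as_volume_grid(mask)
  if (!identical(dim(g), dim(m))) stop_invalid("mask shape must match volume")
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9)
    stop_invalid("mask weights must lie in [0, 1]")
  ps <- if (inherits(vol, "density_volume")) vol$pixel_size else 1
  list(target = density_volume(g * m, ps),
       remainder = density_volume(g * (1 - m), ps))
}

#' Intensity-weighted centre of density
#'
#' Centroid (in voxel coordinates relative to the box centre) of the voxels
#' at or above `threshold` times the maximum.
#'
#' @param vol A [density_volume()] or 3D array.
#' @param threshold Fraction of the maximum value; voxels below it are
#'   ignored.
#' @return Length-3 numeric vector (voxels).
#' @export
center_of_density <- function(vol, threshold = 0) {
  g <- as_volume_grid(vol)
  n <- dim(g)[1]
  mx <- max(g)
  if (mx <= 0) stop_invalid("volume has no positive density")
  sel <- which(g >= threshold * mx & g > 0)
  if (length(sel) == 0L) stop_invalid("no voxels above threshold")
  w <- g[sel]
  idx <- arrayInd(sel, dim(g)) - 1
  drop(crossprod(idx, w)) / sum(w) - n / 2
}

#' Recentre a model on its target module
#'
#' Shifts the entire model (and every supplied mask) so that the centre of
#' density of the target module lands on the box centre.  Integer shifts
#' are applied as exact voxel rolls; fractional shifts use a single
#' trilinear resampling pass.
#'
#' @param vol A [density_volume()].
#' @param target_mask 3D mask selecting the target module.
#' @param other_masks Optional list of additional masks to shift along.
#' @return List with `volume`, `target_mask`, `other_masks` and `shift3d`
#'   (the translation applied, voxels).
#' @export
recenter_model <- function(vol, target_mask, other_masks = list()) {
  g <- as_volume_grid(vol)
  m <- as_volume_grid(target_mask)
  shift3d <- -center_of_density(g * m)
  # sub-millivoxel centring residue is numerical noise: snap to the exact
  # voxel roll when the shift is this close to an integer
  nearint <- abs(shift3d - round(shift3d)) < 1e-3
  shift3d[nearint] <- round(shift3d[nearint])
  list(volume = density_volume(translate_grid(g, shift3d), vol$pixel_size),
       target_mask = translate_grid(m, shift3d),
       other_masks = lapply(other_masks,
                            function(mm) translate_grid(as_volume_grid(mm),
                                                        shift3d)),
       shift3d = shift3d)
}

# translate a grid by a 3-vector (voxels): exact roll for integer shifts;
# fractional shifts use trilinear resampling (zero fill, keeps compact
# support) or an exact-for-band-limited Fourier phase ramp
translate_grid <- function(g, shift3d, method = c("trilinear", "fourier")) {
  method <- match.arg(method)
  n <- dim(g)[1]
  if (all(abs(shift3d - round(shift3d)) < 1e-9)) {
    s <- as.integer(round(shift3d))
    out <- array(0, dim(g))
    src <- lapply(1:3, function(a) {
      i <- seq_len(n) - s[a]
      i
    })
    ok <- lapply(src, function(i) i >= 1 & i <= n)
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      g[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    return(out)
  }
  if (method == "fourier") {
    f <- fft_freqs(n)
    ph <- exp(-2i * pi * (outer(outer(f * shift3d[1], f * shift3d[2], "+"),
                                f * shift3d[3], "+")))
    return(Re(fft(fft(g) * ph, inverse = TRUE)) / n^3)
  }
  array(cpp_affine_sample(as.numeric(g), n, diag(3), as.numeric(shift3d),
                          c(0, 0, 0), -1), dim(g))
}

#' Transform particle parameters for a model shift
#'
#' After the model is translated by `shift3d` (voxels), the particle
#' parameters that reproduce the same experimental image against the
#' shifted model keep their angles and change their in-plane translation by
#' minus the in-plane components of `A %*% shift3d`, where `A` is the
#' particle's ZYZ frame.
#'
#' @param params A parameter data frame (columns `phi`, `theta`, `psi`,
#'   `x`, `y`) or a single [orientation_params()].
#' @param shift3d The model translation, voxels.
#' @return Same shape as `params`, with updated `x`, `y`.
#' @export
transform_particle_params <- function(params, shift3d) {
  check_finite(shift3d, "shift3d")
  single <- !is.data.frame(params)
  df <- if (single) as.data.frame(t(unclass(as_params(params)))) else params
  for (i in seq_len(nrow(df))) {
    A <- euler_matrix(df$phi[i], df$theta[i], df$psi[i])
    d <- A %*% as.numeric(shift3d)
    df$x[i] <- df$x[i] - d[1]
    df$y[i] <- df$y[i] - d[2]
  }
  if (single) orientation_params(df$phi, df$theta, df$psi, df$x, df$y) else df
}

#' Rotate and shift a volume in one resampling pass
#'
#' Applies the rotation `R` about `center` followed by the translation
#' `shift3d`, as a single composed affine resample (one trilinear
#' interpolation).  With Euler angles, the operator is the passive frame
#' matrix used actively, so that rotating a volume by `(phi, theta, psi)`
#' and projecting it along z equals projecting the original volume with
#' parameters `(phi, theta, psi)`.  Identity parameters return the input
#' unchanged, bit for bit.
#'
#' @param vol A [density_volume()].
#' @param phi,theta,psi Euler angles, degrees (ignored when `matrix` given).
#' @param shift3d Translation in voxels.
#' @param center Rotation centre offset from the box centre, voxels.
#' @param matrix Optional explicit 3x3 rotation matrix (active).
#' @return A [density_volume()].
#' @export
rotate_shift_volume <- function(vol, phi = 0, theta = 0, psi = 0,
                                shift3d = c(0, 0, 0), center = c(0, 0, 0),
                                matrix = NULL, support = NULL) {
  g <- as_volume_grid(vol)
  n <- dim(g)[1]
  R <- if (is.null(matrix)) euler_matrix(phi, theta, psi) else matrix
  check_finite(R, "rotation matrix"); check_finite(shift3d, "shift3d")
  if (max(abs(R - diag(3))) < 1e-15 && all(abs(shift3d) < 1e-15))
    return(vol)
  # output support: the rotated density stays within |input support| +
  # |rotation centre| of the shifted centre
  out_r <- -1
  sr <- if (is.null(support)) support_radius(g) else support
  if (sr > 0) out_r <- sr + sqrt(sum(center^2)) + 2
  out <- cpp_affine_sample(as.numeric(g), n, t(R), as.numeric(shift3d),
                           as.numeric(center), out_r)
  density_volume(array(out, dim(g)),
                 if (inherits(vol, "density_volume")) vol$pixel_size else 1)
}

#' Project a volume
#'
#' Line integral of the volume along the viewing axis defined by the ZYZ
#' frame of `params`, then shifted in-plane by `(x, y)` (the projected
#' object moves by `+x, +y`); all in a single trilinear sampling pass.
#' Linear in the volume.
#'
#' @param vol A [density_volume()].
#' @param params [orientation_params()] (or named vector with `phi`,
#'   `theta`, `psi`, `x`, `y`).
#' @param matrix Optional explicit frame matrix overriding the angles (the
#'   shift still comes from `params`).
#' @return An `n x n` image matrix.
#' @export
project <- function(vol, params = orientation_params(), matrix = NULL,
                    support = NULL) {
  g <- as_volume_grid(vol)
  n <- dim(g)[1]
  p <- as_params(params)
  A <- if (is.null(matrix)) euler_matrix(p["phi"], p["theta"], p["psi"]) else matrix
  sr <- if (is.null(support)) support_radius(g) else support
  cpp_project(as.numeric(g), n, A, p["x"], p["y"], if (sr > 0) sr else -1)
}

#' Composite simulated projection
#'
#' Projection of the target module with its candidate parameters plus the
#' projection of the remainder with the preliminary parameters: the
#' simulated image compared against the experimental particle.
#'
#' @param target,remainder [density_volume()]s of the same shape.
#' @param target_params,base_params Orientation parameter sets.
#' @return An `n x n` image matrix.
#' @export
compose_simulated_projection <- function(target, target_params,
                                         remainder, base_params) {
  if (!identical(dim(as_volume_grid(target)), dim(as_volume_grid(remainder))))
    stop_invalid("target and remainder must have the same shape")
  project(target, target_params) + project(remainder, base_params)
}

#' Contrast transfer function parameters
#'
#' @param voltage Acceleration voltage, kV.
#' @param cs Spherical aberration, mm.
#' @param defocus Defocus, micrometres (underfocus positive).
#' @param amplitude_contrast Amplitude contrast fraction in `[0, 1]`.
#' @param pixel_size Angstrom per pixel.
#' @return Object of class `ctf_params`.
#' @export
ctf_params <- function(voltage = 200, cs = 2.7, defocus = 2.0,
                       amplitude_contrast = 0.07, pixel_size = 1) {
  check_finite(c(voltage, cs, defocus, amplitude_contrast, pixel_size), "ctf")
  if (voltage <= 0 || cs < 0 || defocus <= 0 || pixel_size <= 0)
    stop_invalid("voltage, defocus, pixel_size must be positive; cs >= 0")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop_invalid("amplitude_contrast must lie in [0, 1]")
  structure(list(voltage = voltage, cs = cs, defocus = defocus,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size), class = "ctf_params")
}

# relativistic electron wavelength in Angstrom, voltage in kV
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Evaluate the CTF on an image frequency grid
#'
#' Weak-phase contrast transfer function
#' `CTF(s) = -(sqrt(1 - A^2) sin(chi) + A cos(chi))` with aberration phase
#' `chi(s) = pi lambda defocus s^2 - (pi/2) Cs lambda^3 s^4` (underfocus
#' positive, giving negative contrast at low frequency).  `CTF(0) = -A`.
#'
#' @param ctf A [ctf_params()].
#' @param n Image side, pixels.
#' @return `n x n` matrix of transfer values in unshifted FFT layout.
#' @export
ctf_evaluate <- function(ctf, n) {
  lam <- electron_wavelength(ctf$voltage)
  df <- ctf$defocus * 1e4          # um -> A
  cs <- ctf$cs * 1e7               # mm -> A
  f <- fft_freqs(n) / ctf$pixel_size   # cycles/A
  s2 <- outer(f^2, f^2, "+")
  chi <- pi * lam * df * s2 - 0.5 * pi * cs * lam^3 * s2^2
  a <- ctf$amplitude_contrast
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

# unshifted FFT frequency coordinates in cycles/pixel
fft_freqs <- function(n) {
  k <- c(seq(0, n / 2 - 1), seq(-n / 2, -1))
  k / n
}

#' Apply a CTF to an image
#'
#' Multiplication by the transfer function in Fourier space; the output is
#' real and the operator is linear.
#'
#' @param img `n x n` image matrix.
#' @param ctf A [ctf_params()] or a precomputed transfer matrix from
#'   [ctf_evaluate()].
#' @param phase_flip If `TRUE`, apply `sign(CTF)` instead (CTF correction
#'   dialect used for the simulated experimental data).
#' @return Filtered image.
#' @export
apply_ctf <- function(img, ctf, phase_flip = FALSE) {
  n <- nrow(img)
  tf <- if (inherits(ctf, "ctf_params")) ctf_evaluate(ctf, n) else ctf
  if (phase_flip) tf <- sign(tf)
  Re(fft(fft(img) * tf, inverse = TRUE)) / (n * n)
}

#' Subtract the non-target signal from an experimental image
#'
#' Returns `exp_img - k * nontarget_sim`.  In `least_squares` mode the
#' scaling factor is the closed form `<exp, sim> / <sim, sim>` over a
#' support restricted to the non-target footprint (to avoid bias from the
#' target signal); in `fixed` mode the supplied `k` is used.
#'
#' @param exp_img Experimental image.
#' @param nontarget_sim Simulated non-target projection (already
#'   CTF-modulated when the experimental image is).
#' @param k_mode `"least_squares"` or `"fixed"`.
#' @param k Scaling factor for `fixed` mode.
#' @param support Optional logical/numeric support mask; defaults to the
#'   non-target footprint (`|sim| > 1e-6 max|sim|`).
#' @return List with `image` (the residual) and `k`.
#' @export
subtract_nontarget <- function(exp_img, nontarget_sim,
                               k_mode = c("least_squares", "fixed"),
                               k = 1, support = NULL) {
  k_mode <- match.arg(k_mode)
  if (!identical(dim(exp_img), dim(nontarget_sim)))
    stop_invalid("image shapes must match")
  if (k_mode == "least_squares") {
    if (is.null(support))
      support <- abs(nontarget_sim) > 1e-6 * max(abs(nontarget_sim), 1e-300)
    s <- nontarget_sim[support > 0]
    e <- exp_img[support > 0]
    den <- sum(s * s)
    if (den <= 0) stop_invalid("non-target projection has zero norm on support")
    k <- sum(e * s) / den
  }
  list(image = exp_img - k * nontarget_sim, k = k)
}
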