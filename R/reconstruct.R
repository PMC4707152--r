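# Weighted back projection, Fourier shell correlation and resolution
# assessment.  WBP uses the general 2D ramp weighting |s| (Nyquist-capped)
# per image; the centring shift (-x, -y) is applied as an exact Fourier
# phase ramp during filtering, so each image costs one FFT pair plus one
# backprojection pass.

# ramp-filter an image and undo its in-plane shift
ramp_filter_image <- function(img, x = 0, y = 0) {
  n <- nrow(img)
  f <- fft_freqs(n)
  r <- sqrt(outer(f^2, f^2, "+"))
  w <- pmin(r, 0.5)
  # image holds the object at +(x, y); sampling the filtered image at the
  # projection of each voxel assumes a centred object, so shift it back
  ph <- exp(2i * pi * (outer(f * x, f * y, "+")))
  Re(fft(fft(img) * w * ph, inverse = TRUE)) / (n * n)
}

#' Weighted back projection reconstruction
#'
#' Ramp-filters every particle image (|s| weighting in 2D Fourier space,
#' capped at Nyquist), removes its in-plane shift, and smears it back along
#' its viewing axis with the adjoint of the projection operator.  Linear in
#' the stack; the result is scaled by the number of images.
#'
#' @param stack A [particle_stack()] or an `n x n x m` array.
#' @param params Data frame of per-particle parameters (`phi`, `theta`,
#'   `psi`, `x`, `y`); defaults to the stack's own table.
#' @param pixel_size Angstrom per pixel (taken from the stack if given).
#' @return A [density_volume()].
#' @export
wbp_reconstruct <- function(stack, params = NULL, pixel_size = NULL) {
  if (inherits(stack, "particle_stack")) {
    imgs <- stack$images
    if (is.null(params)) params <- stack$params
    if (is.null(pixel_size)) pixel_size <- stack$pixel_size
  } else {
    imgs <- stack
    if (is.null(pixel_size)) pixel_size <- 1
  }
  m <- dim(imgs)[3]
  if (is.null(m) || m < 1L) stop_invalid("empty stack")
  if (is.null(params) || nrow(params) != m)
    stop_invalid("need one parameter row per particle")
  n <- dim(imgs)[1]
  acc <- numeric(n^3)
  for (i in seq_len(m)) {
    fi <- ramp_filter_image(imgs[, , i], params$x[i], params$y[i])
    A <- euler_matrix(params$phi[i], params$theta[i], params$psi[i])
    cpp_backproject(fi, n, A, acc)
  }
  density_volume(array(acc / m, c(n, n, n)), pixel_size)
}

#' Fourier shell correlation of two volumes
#'
#' Per-shell normalized correlation of the Fourier coefficients,
#' `Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)`, with shells one
#' Fourier voxel wide indexed by integer radius.
#'
#' @param vol1,vol2 [density_volume()]s of identical shape and pixel size.
#' @param shell_width Shell width in Fourier voxels.
#' @return Object of class `fsc_curve`: data frame with `shell`, `freq`
#'   (cycles/Angstrom) and `correlation`.
#' @export
fsc <- function(vol1, vol2, shell_width = 1) {
  g1 <- as_volume_grid(vol1); g2 <- as_volume_grid(vol2)
  if (!identical(dim(g1), dim(g2))) stop_invalid("volume shapes must match")
  ps1 <- if (inherits(vol1, "density_volume")) vol1$pixel_size else 1
  ps2 <- if (inherits(vol2, "density_volume")) vol2$pixel_size else ps1
  if (abs(ps1 - ps2) > 1e-9) stop_invalid("pixel sizes must match")
  n <- dim(g1)[1]
  F1 <- fft(g1); F2 <- fft(g2)
  f <- fft_freqs(n) * n                  # integer frequency index
  r2 <- outer(outer(f^2, f^2, "+"), f^2, "+")
  shell <- as.integer(round(sqrt(r2) / shell_width))
  nmax <- as.integer(floor((n / 2) / shell_width))
  keep <- shell <= nmax
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2; p2 <- Mod(F2)^2
  sn <- tapply(num[keep], shell[keep], sum)
  s1 <- tapply(p1[keep], shell[keep], sum)
  s2 <- tapply(p2[keep], shell[keep], sum)
  corr <- as.numeric(sn / sqrt(pmax(s1 * s2, 1e-300)))
  sh <- as.integer(names(sn))
  out <- data.frame(shell = sh,
                    freq = sh * shell_width / (n * ps1),
                    correlation = corr)
  structure(out, class = c("fsc_curve", "data.frame"), pixel_size = ps1)
}

#' Resolution at an FSC threshold
#'
#' First crossing of the curve below the threshold, linearly interpolated
#' in frequency between adjacent shells; returns `1/frequency` in
#' Angstrom.  Without a crossing, the Nyquist resolution
#' (`2 * pixel_size`) is returned with attribute `no_crossing = TRUE`.
#'
#' @param curve An [fsc()] curve.
#' @param threshold FSC threshold (0.5 by default, map-versus-model
#'   convention).
#' @param pixel_size Angstrom per pixel; defaults to the curve's.
#' @return Resolution in Angstrom.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.5,
                                    pixel_size = NULL) {
  if (nrow(curve) == 0L) stop_invalid("empty FSC curve")
  if (is.null(pixel_size)) pixel_size <- attr(curve, "pixel_size")
  co <- curve$correlation; fr <- curve$freq
  idx <- which(co < threshold & curve$shell > 0)
  if (length(idx) == 0L)
    return(structure(2 * pixel_size, no_crossing = TRUE))
  i <- idx[1]
  if (i == 1L) return(structure(1 / max(fr[1], 1e-12), no_crossing = FALSE))
  f0 <- fr[i - 1]; f1 <- fr[i]
  c0 <- co[i - 1]; c1 <- co[i]
  fx <- f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
  fx <- min(max(fx, f0), f1)     # keep within the crossing interval
  structure(1 / fx, no_crossing = FALSE)
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.5, ...) {
  graphics::plot(x$freq, x$correlation, type = "l", xlab = "frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$correlation)), 1), ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(x)
}

#' Low-pass filter a volume
#'
#' Radial Fourier mask at the cutoff frequency with a cosine soft edge; the
#' DC component is preserved exactly.  The radial frequency is capped at
#' Nyquist, so a Nyquist cutoff with a hard edge passes the volume through
#' unchanged.
#'
#' @param vol A [density_volume()].
#' @param resolution Cutoff resolution in Angstrom (`>= 2 * pixel_size`).
#' @param edge_width Cosine edge width in Fourier voxels (0 = hard edge).
#' @return Filtered [density_volume()].
#' @export
lowpass_filter <- function(vol, resolution, edge_width = 2) {
  g <- as_volume_grid(vol)
  ps <- vol$pixel_size
  n <- dim(g)[1]
  if (resolution < 2 * ps - 1e-9)
    stop_invalid("cutoff resolution finer than Nyquist")
  f <- fft_freqs(n) / ps
  r <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+"))
  nyq <- 0.5 / ps
  r <- pmin(r, nyq)
  fc <- 1 / resolution
  ew <- edge_width / (n * ps)
  w <- array(0, dim(g))
  w[r <= fc] <- 1
  if (ew > 0) {
    band <- r > fc & r < fc + ew
    w[band] <- 0.5 * (1 + cos(pi * (r[band] - fc) / ew))
  }
  w[1, 1, 1] <- 1
  density_volume(Re(fft(fft(g) * w, inverse = TRUE)) / n^3, ps)
}

#' Cosine-tapered soft mask from a binary module mask
#'
#' Values are 1 inside the binary mask and fall off as a raised cosine of
#' the Euclidean distance to the mask over `edge_width` voxels (the usual
#' soft segmentation mask applied before module-wise FSC).
#'
#' @param mask Binary 3D array (or [density_volume()]).
#' @param edge_width Taper width in voxels.
#' @return 3D array of weights in `[0, 1]`.
#' @export
soft_shape_mask <- function(mask, edge_width) {
  g <- as_volume_grid(mask)
  if (any(g < 0 | g > 1)) stop_invalid("mask must be binary")
  if (edge_width <= 0) return(g * 1)
  n <- dim(g)[1]
  d <- sqrt(array(cpp_edt3(as.numeric(g), n), dim(g)))
  w <- array(0, dim(g))
  w[d == 0] <- 1
  band <- d > 0 & d < edge_width
  w[band] <- 0.5 * (1 + cos(pi * d[band] / edge_width))
  w
}
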