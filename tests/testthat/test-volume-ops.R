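test_that("volume splitting conserves density", {
  set.seed(10)
  n <- 32
  vol <- density_volume(array(rnorm(n^3), c(n, n, n)), 2)
  mask <- array(runif(n^3), c(n, n, n))
  sv <- split_volume(vol, mask)
  expect_lt(max(abs(sv$target$grid + sv$remainder$grid - vol$grid)), 1e-12)
  all1 <- split_volume(vol, array(1, c(n, n, n)))
  expect_equal(all1$target$grid, vol$grid)
  expect_true(all(all1$remainder$grid == 0))
  half <- array(rep(seq_len(n) <= n / 2, n * n), c(n, n, n)) * 1
  sv2 <- split_volume(vol, half)
  expect_equal(sum(abs(sv2$target$grid) * abs(sv2$remainder$grid)), 0)
  expect_error(split_volume(vol, array(1, c(n, n, 2 * n))),
               class = "lorefine_invalid_argument")
})

test_that("centre of density finds point masses and symmetric pairs", {
  n <- 32
  g <- array(0, c(n, n, n))
  g[n / 2 + 1, n / 2 + 1, n / 2 + 1] <- 1
  expect_equal(center_of_density(g), c(0, 0, 0))
  g2 <- array(0, c(n, n, n))
  g2[n / 2 + 1 + 3, n / 2 + 1 - 2, n / 2 + 1 + 5] <- 2
  expect_equal(center_of_density(g2), c(3, -2, 5))
  g3 <- array(0, c(n, n, n))
  g3[n / 2 + 1 + 4, n / 2 + 1, n / 2 + 1] <- 1
  g3[n / 2 + 1 - 4, n / 2 + 1, n / 2 + 1] <- 1
  expect_equal(center_of_density(g3), c(0, 0, 0))
  expect_error(center_of_density(array(0, c(n, n, n))),
               class = "lorefine_invalid_argument")
})

test_that("recentring puts the target centre on the box centre", {
  n <- 48
  mask <- array(1, c(n, n, n))
  centred <- smooth_blob_volume(n, blobs = list(c(0, 0, 0, 3)))
  # integer offset: exact voxel roll, no interpolation loss
  off <- lorefine:::translate_grid(centred$grid, c(3, -2, 4))
  rec <- recenter_model(density_volume(off, 4), mask)
  expect_equal(rec$shift3d, c(-3, 2, -4), tolerance = 1e-9)
  expect_lt(max(abs(rec$volume$grid - centred$grid)), 1e-9)
  expect_lt(sqrt(sum(center_of_density(rec$volume$grid *
                                         rec$target_mask)^2)), 0.5)
  # fractional offset: recomputed centre lands within half a voxel
  off2 <- lorefine:::translate_grid(centred$grid, c(2.4, -1.3, 0.8),
                                    method = "fourier")
  rec2 <- recenter_model(density_volume(off2, 4), mask)
  expect_lt(sqrt(sum(center_of_density(rec2$volume$grid *
                                         rec2$target_mask)^2)), 0.5)
})

test_that("parameter transformation compensates a model shift exactly", {
  vol <- smooth_blob_volume(64)
  p0 <- orientation_params(100, 55, 210, 1, -0.5)
  expect_equal(unclass(transform_particle_params(p0, c(0, 0, 0))),
               unclass(p0))
  s3 <- c(2.4, -1.2, 3.1)
  shifted <- lorefine:::translate_grid(vol$grid, s3, method = "fourier")
  pt <- transform_particle_params(p0, s3)
  i0 <- project(vol, p0)
  i1 <- project(density_volume(shifted, vol$pixel_size), pt)
  expect_lt(rel_l2(i1, i0), 1e-3)
  # identity orientation: the in-plane change is minus the shift itself
  pid <- transform_particle_params(orientation_params(0, 0, 0, 0, 0),
                                   c(2, 3, 0))
  expect_equal(unname(pid["x"]), -2)
  expect_equal(unname(pid["y"]), -3)
})

test_that("rotate_shift_volume composes into one resampling pass", {
  vol <- smooth_blob_volume(48)
  same <- rotate_shift_volume(vol, 0, 0, 0, c(0, 0, 0))
  expect_identical(same$grid, vol$grid)
  # a full turn about z composed as one operation is exact
  full <- rotate_shift_volume(vol, 0, 0, 360)
  expect_lt(rel_l2(full$grid, vol$grid), 1e-12)
  # rotate-then-project consistency: project(rot(v, Rm), A) = project(v, A Rm)
  set.seed(11)
  Rm <- axis_angle_matrix(c(1, 2, -1), 14)
  A <- euler_matrix(70, 40, 120)
  lhs <- project(rotate_shift_volume(vol, matrix = Rm),
                 orientation_params(70, 40, 120))
  rhs <- project(vol, orientation_params(), matrix = A %*% Rm)
  expect_lt(rel_l2(lhs, rhs), 5e-3)
})

test_that("projection conserves mass, is linear, and centres deltas", {
  vol <- smooth_blob_volume(48)
  p <- project(vol, orientation_params(), support = 100)
  expect_lt(abs(sum(p) / sum(vol$grid) - 1), 1e-6)
  pr <- project(vol, orientation_params(30, 60, 10))
  expect_lt(abs(sum(pr) / sum(vol$grid) - 1), 1e-4)
  # linearity
  set.seed(12)
  n <- 32
  a <- density_volume(array(rnorm(n^3), c(n, n, n)), 1)
  b <- density_volume(array(rnorm(n^3), c(n, n, n)), 1)
  ab <- density_volume(a$grid + b$grid, 1)
  pp <- orientation_params(77, 33, 121, 0.5, -1)
  expect_lt(max(abs(project(ab, pp) -
                      project(a, pp, support = n) -
                      project(b, pp, support = n))), 1e-9)
  # delta at the box centre projects to the image centre for any angles
  d <- array(0, c(n, n, n)); d[n / 2 + 1, n / 2 + 1, n / 2 + 1] <- 1
  img <- project(density_volume(d, 1), orientation_params(123, 71, 45))
  pk <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(n / 2 + 1, n / 2 + 1))
  # spherically symmetric volume: projection invariant under rotation
  # (a broad Gaussian keeps trilinear sampling error below the bound)
  sv <- spherical_volume(96, sigma = 11)
  expect_lt(rel_l2(project(sv, orientation_params(77, 33, 121)),
                   project(sv, orientation_params())), 1e-3)
})

test_that("composite projections realize the additivity of the model", {
  vol <- smooth_blob_volume(48)
  n <- 48
  mask <- array(rep(seq_len(n) <= n / 2, n * n), c(n, n, n)) * 1
  sv <- split_volume(vol, mask)
  pp <- orientation_params(50, 70, 10, 1, 2)
  whole <- project(vol, pp)
  comp <- compose_simulated_projection(sv$target, pp, sv$remainder, pp)
  expect_lt(rel_l2(comp, whole), 1e-6)
  zero <- density_volume(array(0, c(n, n, n)), vol$pixel_size)
  expect_equal(compose_simulated_projection(sv$target, pp, zero, pp),
               project(sv$target, pp))
  p2 <- orientation_params(55, 75, 12)
  expect_equal(compose_simulated_projection(zero, pp, sv$remainder, p2),
               compose_simulated_projection(zero, p2, sv$remainder, p2))
})

test_that("the weak-phase CTF has the right closed-form anchors", {
  ctf <- ctf_params(voltage = 200, cs = 2.7, defocus = 2.0,
                    amplitude_contrast = 0.07, pixel_size = 2)
  tf <- ctf_evaluate(ctf, 64)
  expect_equal(tf[1, 1], -0.07, tolerance = 1e-12)
  tf1 <- ctf_evaluate(ctf_params(amplitude_contrast = 1, defocus = 2,
                                 pixel_size = 2), 64)
  expect_equal(abs(tf1[1, 1]), 1, tolerance = 1e-12)
  # first zero along the frequency axis vs a brute-force root find of chi
  lam <- lorefine:::electron_wavelength(200)
  chi <- function(s) pi * lam * 2e4 * s^2 - 0.5 * pi * 2.7e7 * lam^3 * s^4
  a <- 0.07
  f <- function(s) -(sqrt(1 - a^2) * sin(chi(s)) + a * cos(chi(s)))
  sgrid <- seq(1e-4, 0.25, by = 1e-5)
  root <- sgrid[which(diff(sign(f(sgrid))) != 0)[1]]
  row <- tf[1:32, 1]
  freqs <- (0:31) / 64 / 2
  cross <- freqs[which(diff(sign(row)) != 0)[1]]
  expect_lt(abs(cross - root), 1 / 64 / 2 + 1e-9)
})

test_that("CTF application is a linear real Fourier filter", {
  set.seed(13)
  img <- matrix(rnorm(64^2), 64)
  one <- matrix(1, 64, 64)
  expect_lt(max(abs(apply_ctf(img, one) - img)), 1e-10)
  ctf <- ctf_params(defocus = 2.5, pixel_size = 4)
  a <- matrix(rnorm(64^2), 64); b <- matrix(rnorm(64^2), 64)
  expect_lt(max(abs(apply_ctf(a + b, ctf) - apply_ctf(a, ctf) -
                      apply_ctf(b, ctf))), 1e-10)
  # Parseval: output power equals the filtered spectral power
  tf <- ctf_evaluate(ctf, 64)
  out <- apply_ctf(a, ctf)
  expect_lt(abs(sum(out^2) - sum(Mod(tf * fft(a))^2) / 64^2) /
              sum(out^2), 1e-6)
})

test_that("non-target subtraction recovers the scaling factor", {
  set.seed(14)
  sim <- matrix(rnorm(48^2), 48)
  sub <- subtract_nontarget(2.5 * sim, sim)
  expect_equal(sub$k, 2.5, tolerance = 1e-12)
  expect_lt(max(abs(sub$image)), 1e-10)
  # orthogonal experimental image: k vanishes
  ex <- matrix(rnorm(48^2), 48)
  ex <- ex - sim * sum(ex * sim) / sum(sim^2)
  sub2 <- subtract_nontarget(ex, sim, support = matrix(1, 48, 48))
  expect_lt(abs(sub2$k), 1e-12)
  expect_equal(sub2$image, ex, tolerance = 1e-9)
  # Monte-Carlo recovery of k = 1.3 under noise
  target <- matrix(rnorm(48^2), 48)
  ks <- replicate(100, {
    noisy <- target + 1.3 * sim + matrix(rnorm(48^2, 0, 0.5), 48)
    subtract_nontarget(noisy, sim, support = matrix(1, 48, 48))$k
  })
  se <- 0.5 / sqrt(sum(sim^2))        # sd of the LS estimate per draw
  expect_lt(abs(mean(ks) - 1.3), 3 * se / sqrt(100) + 3 * se)
  expect_error(subtract_nontarget(ex, matrix(0, 48, 48)),
               class = "lorefine_invalid_argument")
})
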