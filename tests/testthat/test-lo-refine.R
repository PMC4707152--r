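# shared small benchmark stack for the driver tests
lo_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- two_module_phantom()
      cache <<- list(ph = ph,
                     stack = generate_dataset(4, ph, degradation = NULL,
                                              seed = 21))
    }
    cache
  }
})

test_that("zero search extents return the preliminary parameters", {
  fx <- lo_fixture()
  cfg <- refinement_config(
    search = search_range(alpha0 = 0, t1 = 0, t2 = 0,
                          directions = data.frame(phi = 0, theta = 90)),
    mask = list(diameter = 30), seed = 1)
  fit <- refine_module(fx$stack, fx$ph$volume, fx$ph$masks[[2]], cfg)
  expect_equal(fit$params$phi, fit$preliminary$phi, tolerance = 1e-9)
  expect_equal(fit$params$x, fit$preliminary$x, tolerance = 1e-9)
  # and the reconstruction equals a plain WBP from those parameters
  direct <- wbp_reconstruct(fx$stack$images, fit$preliminary, 4)
  expect_lt(rel_l2(fit$reconstruction$grid, direct$grid), 1e-6)
})

test_that("the optimizer matches a naive reference on a toy grid", {
  fx <- lo_fixture()
  rec <- recenter_model(fx$ph$volume, fx$ph$masks[[2]])
  sv <- split_volume(rec$volume, rec$target_mask)
  prelim <- transform_particle_params(fx$stack$params, rec$shift3d)
  dirs <- generate_direction_set(6)
  cfg <- refinement_config(
    search = search_range(alpha0 = 7, d1 = 6, t1 = 1, d2 = 1, t2 = 1,
                          directions = dirs),
    mask = list(diameter = 24), seed = 1)
  i <- 2
  p0 <- orientation_params(prelim$phi[i], prelim$theta[i], prelim$psi[i],
                           prelim$x[i], prelim$y[i])
  record <- list(index = i, params = p0, params_preliminary = p0)
  got <- optimize_particle_simultaneous(fx$stack$images[, , i], sv$target,
                                        sv$remainder, record, cfg)
  # naive two-nested-loop reference over the same grid
  grid <- build_search_grid(p0, cfg$search)
  mask <- circular_mask(64, 24, center = c(p0["x"], p0["y"]))
  rem <- project(sv$remainder, p0)
  best <- c(-2, 0)
  for (r in seq_len(nrow(grid))) {
    sim <- project(sv$target, orientation_params(grid$phi[r], grid$theta[r],
                                                 grid$psi[r], grid$x[r],
                                                 grid$y[r])) + rem
    v <- ccc(fx$stack$images[, , i], sim, mask)
    if (v > best[1] + 1e-12) best <- c(v, r)
  }
  expect_equal(unname(got$best_ccc), best[1], tolerance = 1e-10)
  expect_equal(unname(got$params["phi"]), grid$phi[best[2]], tolerance = 1e-9)
  expect_equal(unname(got$params["theta"]), grid$theta[best[2]],
               tolerance = 1e-9)
  expect_equal(unname(got$params["x"]), grid$x[best[2]], tolerance = 1e-9)
  expect_equal(got$n_evals, nrow(grid))
  # the slow reference path agrees with itself
  cfg_exact <- cfg; cfg_exact$exact <- TRUE
  got2 <- optimize_particle_simultaneous(fx$stack$images[, , i], sv$target,
                                         sv$remainder, record, cfg_exact)
  expect_equal(unname(got2$best_ccc), unname(got$best_ccc), tolerance = 1e-10)
})

test_that("the refined score never falls below the preliminary score", {
  fx <- lo_fixture()
  stack <- generate_dataset(4, fx$ph, seed = 22)   # noisy variant
  cfg <- refinement_config(mask = list(diameter = 24), seed = 2)
  fit <- refine_module(stack, fx$ph$volume, fx$ph$masks[[2]], cfg)
  rec <- recenter_model(fx$ph$volume, fx$ph$masks[[2]])
  sv <- split_volume(rec$volume, rec$target_mask)
  for (i in 1:4) {
    p0 <- orientation_params(fit$preliminary$phi[i], fit$preliminary$theta[i],
                             fit$preliminary$psi[i], fit$preliminary$x[i],
                             fit$preliminary$y[i])
    mask <- circular_mask(64, 24, center = c(p0["x"], p0["y"]))
    s0 <- ccc(stack$images[, , i],
              compose_simulated_projection(sv$target, p0, sv$remainder, p0),
              mask)
    expect_gte(fit$params$ccc[i], s0 - 1e-10)
  }
  # refined parameters stay inside the declared search range
  span <- span_angle(fit$params$phi, fit$params$theta,
                     fit$preliminary$phi, fit$preliminary$theta)
  expect_true(all(span <= cfg$search$alpha0 + 1e-6))
  expect_true(all(abs(fit$params$x - fit$preliminary$x) <=
                    cfg$search$d2 * cfg$search$t2 + 1e-9))
  expect_true(all(abs(fit$params$y - fit$preliminary$y) <=
                    cfg$search$d2 * cfg$search$t2 + 1e-9))
})

test_that("the separate strategy honours its stage structure", {
  fx <- lo_fixture()
  rec <- recenter_model(fx$ph$volume, fx$ph$masks[[2]])
  sv <- split_volume(rec$volume, rec$target_mask)
  prelim <- transform_particle_params(fx$stack$params, rec$shift3d)
  i <- 1
  p0 <- orientation_params(prelim$phi[i], prelim$theta[i], prelim$psi[i],
                           prelim$x[i], prelim$y[i])
  record <- list(index = i, params = p0, params_preliminary = p0)
  # with zero perturbation particles the optimal shift offset is zero for
  # every trial angle, so the averaged shift equals the common argmax
  zero_stack <- local({
    none <- list(list(axis = c(0, 0, 1), angle = 0, shift = c(0, 0, 0)),
                 list(axis = c(0, 0, 1), angle = 0, shift = c(0, 0, 0)))
    gp <- orientation_params(fx$stack$params$phi[i], fx$stack$params$theta[i],
                             fx$stack$params$psi[i])
    generate_particle(fx$ph$volume, fx$ph$masks, none, gp)$image
  })
  cfg <- refinement_config(strategy = "separate", n_trial_angles = 4,
                           mask = list(diameter = 24), seed = 5)
  set.seed(5)
  got <- optimize_particle_separate(zero_stack, sv$target, sv$remainder,
                                    record, cfg)
  expect_lt(abs(got$params["x"] - p0["x"]), 0.5)
  expect_lt(abs(got$params["y"] - p0["y"]), 0.5)
  # evaluation count follows the two-stage formula
  g <- lorefine:::local_grid(p0, cfg$search)
  n_ang <- nrow(g$dirs) * length(g$psi_off)
  expect_equal(got$n_evals, 4 * (2 * cfg$search$t2 + 1)^2 + n_ang)
})

test_that("module refinement is deterministic and order-independent", {
  fx <- lo_fixture()
  stack <- generate_dataset(3, fx$ph, seed = 23)
  cfg <- refinement_config(strategy = "separate",
                           mask = list(diameter = 24), seed = 31)
  f1 <- refine_module(stack, fx$ph$volume, fx$ph$masks[[2]], cfg)
  f2 <- refine_module(stack, fx$ph$volume, fx$ph$masks[[2]], cfg)
  expect_identical(f1$params, f2$params)
  # a reordered stack gives each particle the same answer
  ord <- c(3, 1, 2)
  stack_r <- particle_stack(stack$images[, , ord], 4,
                            within(stack$params[ord, ],
                                   index <- stack$params$index[ord]),
                            stack$truth[ord])
  stack_r$params$index <- stack$params$index[ord]
  f3 <- refine_module(stack_r, fx$ph$volume, fx$ph$masks[[2]], cfg)
  expect_equal(f3$params$phi, f1$params$phi[ord], tolerance = 1e-12)
  expect_equal(f3$params$x, f1$params$x[ord], tolerance = 1e-12)
})

test_that("multi-module refinement keeps independent bookkeeping", {
  fx <- lo_fixture()
  cfg <- refinement_config(mask = list(diameter = 24), seed = 3,
                           search = search_range(alpha0 = 4, d1 = 2, t1 = 1,
                                                 d2 = 1, t2 = 1))
  out <- refine_all_modules(fx$stack, fx$ph$volume, fx$ph$masks, cfg)
  expect_length(out$modules, 2)
  expect_equal(nrow(out$modules[[1]]$params), 4)
  expect_equal(nrow(out$modules[[2]]$params), 4)
  # both start from the same input parameters but end independently
  expect_false(identical(out$modules[[1]]$params$phi,
                         out$modules[[2]]$params$phi))
  expect_s3_class(out$model, "density_volume")
  # overlapping masks are rejected
  expect_error(refine_all_modules(fx$stack, fx$ph$volume,
                                  list(fx$ph$masks[[1]],
                                       fx$ph$masks[[1]]), cfg),
               class = "lorefine_invalid_argument")
})

test_that("lo_refine returns a well-formed model object", {
  fx <- lo_fixture()
  cfg <- refinement_config(mask = list(diameter = 24), seed = 4,
                           search = search_range(alpha0 = 4, d1 = 2, t1 = 1,
                                                 d2 = 1, t2 = 1))
  fit <- lo_refine(fx$stack, fx$ph$volume, fx$ph$masks[[2]], cfg)
  expect_s3_class(fit, "lo_refine")
  expect_equal(dim(coef(fit)), c(4L, 5L))
  expect_output(print(fit), "LO-refinement")
  expect_output(print(summary(fit)), "direction change")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("conventional matching recovers on-grid rigid particles", {
  ph <- two_module_phantom()
  D <- generate_direction_set(2)
  picks <- D[c(400, 2500, 5200, 8000), ]
  psis <- c(0, 30, 112, 240)
  n <- 64
  imgs <- array(0, c(n, n, 4))
  sr <- lorefine:::support_radius(ph$volume$grid)
  for (i in 1:4)
    imgs[, , i] <- project(ph$volume,
                           orientation_params(picks$phi[i], picks$theta[i],
                                              psis[i]), support = sr)
  stack <- particle_stack(imgs, 4, data.frame(index = 1:4, phi = 0,
                                              theta = 0, psi = 0, x = 0,
                                              y = 0))
  conv <- conventional_global_refine(stack, ph$volume)
  derr <- span_angle(conv$phi, conv$theta, picks$phi, picks$theta)
  # rigid, noise-free, on-grid views: most views recover exactly; the
  # transported in-plane grid occasionally trades one direction step
  # against a psi step
  expect_true(all(derr <= 4 + 1e-6))
  expect_gte(sum(derr < 1e-6), 3)
  expect_true(all(angdiff_abs(conv$psi, psis) <= 5 + 1e-6))
  expect_true(all(abs(conv$x) <= 1e-9) && all(abs(conv$y) <= 1e-9))
  # deterministic: a second run is identical
  expect_identical(conv, conventional_global_refine(stack, ph$volume))
})

test_that("refinement runs on phase-flipped CTF data", {
  ph <- two_module_phantom()
  stack <- generate_dataset(3, ph, seed = 24,
                            degradation = list(type = "ctf",
                                               defocus = c(2.0, 3.0),
                                               snr = 2))
  # phase flip the experimental images per defocus group
  for (i in 1:3) {
    tf <- ctf_evaluate(stack$ctf[[stack$params$defocus_group[i]]], 64)
    stack$images[, , i] <- apply_ctf(stack$images[, , i], tf,
                                     phase_flip = TRUE)
  }
  cfg <- refinement_config(mask = list(diameter = 24), seed = 6,
                           ctf_mode = "phase_flipped",
                           search = search_range(alpha0 = 4, d1 = 2, t1 = 1,
                                                 d2 = 1, t2 = 2))
  fit <- refine_module(stack, ph$volume, ph$masks[[2]], cfg)
  expect_true(all(is.finite(fit$params$ccc)))
  expect_false(any(fit$flags))
})
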