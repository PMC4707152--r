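# LO-refinement driver: per-particle local optimization of the target
# module's five projection parameters, scored by masked CCC between the
# experimental image and composite simulated projections (moving target
# plus fixed remainder), followed by module-wise reconstruction.

#' Refinement configuration
#'
#' @param search A [search_range()]; defaults to the benchmark settings
#'   (10 degree cone, 2 degree step, shifts -4..4 px in 1 px steps).
#' @param strategy `"simultaneous"` (exhaustive over the full grid) or
#'   `"separate"` (randomly chosen trial angles for the shift stage, then
#'   exhaustive angles at the averaged shift).
#' @param n_trial_angles Number of random angle triples in the separate
#'   strategy's shift stage.
#' @param mask 2D scoring mask: a matrix, or a list
#'   `list(diameter =, center =, soft_edge =)` for [circular_mask()], or
#'   `NULL` for all pixels.
#' @param subtract If `TRUE`, subtract the scaled non-target projection
#'   from the experimental image and score the residual against the target
#'   alone (the CTF-aware objective); default scores the composite.
#' @param k_mode Scaling mode for the subtraction, see
#'   [subtract_nontarget()].
#' @param ctf_mode `"none"`, `"phase_flipped"` (simulations modulated by
#'   |CTF|, for phase-flipped experimental data) or `"modulated"`.
#' @param seed Seed keying the per-particle RNG streams (separate
#'   strategy).
#' @param exact If `TRUE`, score every candidate with
#'   [compose_simulated_projection()] in a single resampling pass (the
#'   reference path; slow). The default path projects each direction once
#'   at `psi = 0` and applies `psi`/shift as in-plane resampling.
#' @return Object of class `refinement_config`.
#' @export
refinement_config <- function(search = search_range(),
                              strategy = c("simultaneous", "separate"),
                              n_trial_angles = 10,
                              mask = list(diameter = 30),
                              subtract = FALSE,
                              k_mode = "least_squares",
                              ctf_mode = c("none", "phase_flipped",
                                           "modulated"),
                              seed = 1, exact = FALSE) {
  strategy <- match.arg(strategy)
  ctf_mode <- match.arg(ctf_mode)
  if (n_trial_angles < 1) stop_invalid("n_trial_angles must be >= 1")
  structure(list(search = search, strategy = strategy,
                 n_trial_angles = as.integer(n_trial_angles), mask = mask,
                 subtract = subtract, k_mode = k_mode, ctf_mode = ctf_mode,
                 seed = seed, exact = exact),
            class = "refinement_config")
}

resolve_mask2d <- function(mask, n, center = c(0, 0)) {
  if (is.null(mask)) return(matrix(1, n, n))
  if (is.matrix(mask)) {
    if (!all(dim(mask) == n)) stop_invalid("mask shape must match images")
    return(mask)
  }
  circular_mask(n, mask$diameter, (mask$center %||% c(0, 0)) + unname(center),
                mask$soft_edge %||% 0)
}

mask_index <- function(maskmat) {
  sel <- which(maskmat > 0)
  if (length(sel) < 2) stop_invalid("mask must select at least 2 pixels")
  list(idx = as.integer(sel - 1L), w = as.numeric(maskmat[sel]))
}

# per-particle scoring context shared by both strategies
particle_context <- function(exp_img, target, remainder, record, cfg,
                             tf = NULL) {
  n <- nrow(exp_img)
  rem_img <- project(remainder, record$params_preliminary)
  tf_sim <- NULL
  if (!is.null(tf) && cfg$ctf_mode != "none") {
    tf_sim <- if (cfg$ctf_mode == "phase_flipped") abs(tf) else tf
    rem_img <- apply_ctf(rem_img, tf_sim)
  }
  exp_use <- exp_img
  rem_use <- rem_img
  if (cfg$subtract) {
    sub <- subtract_nontarget(exp_img, rem_img, k_mode = cfg$k_mode)
    exp_use <- sub$image
    rem_use <- matrix(0, n, n)
  }
  # the recentred target module projects at the preliminary in-plane shift;
  # a circular mask spec follows it there
  p0 <- record$params_preliminary
  mm <- resolve_mask2d(cfg$mask, n, center = c(p0["x"], p0["y"]))
  mi <- mask_index(mm)
  tg <- as_volume_grid(target)
  sr <- support_radius(tg)
  list(n = n, exp_use = exp_use, rem_use = rem_use, tf_sim = tf_sim,
       widx = mi$idx, wval = mi$w, tgrid = as.numeric(tg),
       sr = if (sr > 0) sr else -1)
}

# target projection at one orientation (single trilinear pass, base shift
# included; CTF-modulated if configured)
ctx_projection <- function(ctx, phi, theta, psi = 0, x = 0, y = 0) {
  pr <- cpp_project(ctx$tgrid, ctx$n, euler_matrix(phi, theta, psi),
                    unname(x), unname(y), ctx$sr)
  if (!is.null(ctx$tf_sim)) pr <- apply_ctf(pr, ctx$tf_sim)
  pr
}

# scores over the integer shift-offset grid for one fully specified
# candidate orientation: exact (index-displacement) shifts on top of a
# single-pass projection
score_offsets <- function(ctx, phi, theta, psi, x0, y0, off) {
  proj <- ctx_projection(ctx, phi, theta, psi, x0, y0)
  cpp_score_psi_shift(ctx$exp_use, ctx$rem_use, proj, 0, 0, 0,
                      as.integer(round(off)), as.integer(round(off)),
                      ctx$widx, ctx$wval)
}

# scores for one direction over psi values and the shift grid centred at
# (x0, y0); returns vector ordered (psi, y offset, x offset)
score_direction <- function(ctx, proj, psis, x0, y0, off) {
  if (all(abs(off - round(off)) < 1e-9)) {
    cpp_score_psi_shift(ctx$exp_use, ctx$rem_use, proj, psis, x0, y0,
                        as.integer(round(off)), as.integer(round(off)),
                        ctx$widx, ctx$wval)
  } else {
    ns <- length(off)
    out <- numeric(length(psis) * ns * ns)
    k <- 1L
    for (p in seq_along(psis)) for (iy in seq_len(ns)) for (ix in seq_len(ns)) {
      out[k] <- cpp_score_psi_shift(ctx$exp_use, ctx$rem_use, proj, psis[p],
                                    x0 + off[ix], y0 + off[iy],
                                    0L, 0L, ctx$widx, ctx$wval)
      k <- k + 1L
    }
    out
  }
}

# vertex of the parabola through three equidistant samples, clamped to
# half a step; NA-safe
peak_offset <- function(sm, s0, sp) {
  if (is.na(sm) || is.na(sp) || is.na(s0)) return(0)
  den <- sm - 2 * s0 + sp
  if (den >= -1e-300) return(0)
  min(max(0.5 * (sm - sp) / den, -0.5), 0.5)
}

range_step <- function(off) if (length(off) > 1) off[2] - off[1] else 1

# argmax with the local-optimization tie-break: among near-equal scores
# prefer the candidate closest to the preliminary parameters
# (span angle, then |dpsi|, then shift magnitude)
pick_best <- function(scores, grid) {
  ok <- !is.na(scores)
  if (!any(ok)) return(NULL)
  mx <- max(scores[ok])
  cand <- which(ok & scores >= mx - 1e-12)
  o <- order(grid$span[cand], grid$dpsi[cand], grid$dshift[cand])
  list(i = cand[o[1]], score = mx)
}

#' Optimize one particle: simultaneous strategy
#'
#' Exhaustive masked-CCC search over the full Cartesian grid of
#' cone-constrained directions, transported in-plane rotations and shifts;
#' the remainder is always projected at the preliminary parameters.  The
#' grid contains the preliminary point, so the refined score can never be
#' worse than the starting score.
#'
#' @param exp_img Experimental image (n x n).
#' @param target,remainder Recentred module volumes.
#' @param record List with `index`, `params` (current, recentred frame) and
#'   `params_preliminary`.
#' @param cfg A [refinement_config()].
#' @param tf Optional CTF transfer matrix for this particle.
#' @return The record with refined `params`, `best_ccc`, `n_evals` and
#'   `failed` flag.
#' @export
optimize_particle_simultaneous <- function(exp_img, target, remainder,
                                           record, cfg, tf = NULL) {
  if (isTRUE(cfg$exact))
    return(optimize_particle_exact(exp_img, target, remainder, record, cfg,
                                   tf))
  ctx <- particle_context(exp_img, target, remainder, record, cfg, tf)
  g <- local_grid(record$params, cfg$search)
  grid <- build_search_grid(record$params, cfg$search)
  x0 <- g$params0["x"]; y0 <- g$params0["y"]
  integer_off <- all(abs(g$off - round(g$off)) < 1e-9)
  np <- length(g$psi_off)
  scores <- numeric(0)
  for (d in seq_len(nrow(g$dirs))) for (p in seq_len(np)) {
    sc <- if (integer_off) {
      score_offsets(ctx, g$dirs$phi[d], g$dirs$theta[d], g$psis[d, p],
                    x0, y0, g$off)
    } else {
      ns <- length(g$off)
      v <- numeric(ns * ns); k <- 1L
      for (iy in seq_len(ns)) for (ix in seq_len(ns)) {
        v[k] <- score_offsets(ctx, g$dirs$phi[d], g$dirs$theta[d],
                              g$psis[d, p], x0 + g$off[ix], y0 + g$off[iy],
                              0)
        k <- k + 1L
      }
      v
    }
    scores <- c(scores, sc)
  }
  best <- pick_best(scores, grid)
  finish_record(record, best, grid, length(scores))
}

#' Optimize one particle: separate strategy
#'
#' Stage 1 draws `n_trial_angles` angle triples uniformly (without
#' replacement) from the constrained angle grid and exhausts the shift grid
#' for each; the per-trial best shifts are averaged (fractional result
#' allowed).  Stage 2 exhausts the full angle grid at the averaged shift.
#' Uses the current RNG state; the driver keys it by particle index.
#'
#' @inheritParams optimize_particle_simultaneous
#' @return As [optimize_particle_simultaneous()].
#' @export
optimize_particle_separate <- function(exp_img, target, remainder, record,
                                       cfg, tf = NULL) {
  ctx <- particle_context(exp_img, target, remainder, record, cfg, tf)
  g <- local_grid(record$params, cfg$search)
  nd <- nrow(g$dirs); np <- length(g$psi_off); ns <- length(g$off)
  n_ang <- nd * np
  ntrial <- min(cfg$n_trial_angles, n_ang)
  trials <- sample.int(n_ang, ntrial)
  x0 <- g$params0["x"]; y0 <- g$params0["y"]
  shifts <- matrix(NA_real_, ntrial, 2)
  n_evals <- 0L
  for (k in seq_len(ntrial)) {
    d <- ((trials[k] - 1L) %/% np) + 1L
    p <- ((trials[k] - 1L) %% np) + 1L
    sc <- score_offsets(ctx, g$dirs$phi[d], g$dirs$theta[d], g$psis[d, p],
                        x0, y0, g$off)
    n_evals <- n_evals + length(sc)
    if (all(is.na(sc))) next
    sgrid <- data.frame(span = 0, dpsi = 0,
                        dshift = sqrt(rep(g$off^2, each = ns) +
                                        rep(g$off^2, times = ns)))
    # order within one (dir, psi): (y offset, x offset)
    iy <- rep(seq_len(ns), each = ns); ix <- rep(seq_len(ns), times = ns)
    b <- pick_best(sc, sgrid)
    bx <- ix[b$i]; by <- iy[b$i]
    # sub-pixel refinement of the per-trial peak (1D quadratic fit along
    # each axis); per-trial shifts are averaged afterwards, so fractional
    # precision here is what lets the average beat the sampling step
    M <- matrix(sc, ns, ns)            # [ix, iy]
    dx <- if (bx > 1 && bx < ns) peak_offset(M[bx - 1, by], M[bx, by],
                                             M[bx + 1, by]) else 0
    dy <- if (by > 1 && by < ns) peak_offset(M[bx, by - 1], M[bx, by],
                                             M[bx, by + 1]) else 0
    shifts[k, ] <- c(x0 + g$off[bx] + dx * range_step(g$off),
                     y0 + g$off[by] + dy * range_step(g$off))
  }
  if (all(is.na(shifts[, 1]))) {
    record$failed <- TRUE
    record$best_ccc <- NA_real_
    record$n_evals <- n_evals
    return(record)
  }
  avg <- colMeans(shifts, na.rm = TRUE)
  # stage 2: exhaust all angle triples at the averaged (fractional) shift,
  # the sub-pixel shift entering the single projection pass directly
  scores <- numeric(n_ang)
  k <- 1L
  for (d in seq_len(nd)) for (p in seq_len(np)) {
    scores[k] <- score_offsets(ctx, g$dirs$phi[d], g$dirs$theta[d],
                               g$psis[d, p], avg[1], avg[2], 0)
    k <- k + 1L
  }
  n_evals <- n_evals + length(scores)
  agrid <- data.frame(
    span = rep(g$dirs$span, each = np),
    dpsi = rep(abs(g$psi_off), times = nd),
    dshift = 0)
  best <- pick_best(scores, agrid)
  if (is.null(best)) {
    record$failed <- TRUE
    record$best_ccc <- NA_real_
    record$n_evals <- n_evals
    return(record)
  }
  d <- ((best$i - 1L) %/% np) + 1L
  p <- ((best$i - 1L) %% np) + 1L
  record$params <- orientation_params(g$dirs$phi[d], g$dirs$theta[d],
                                      g$psis[d, p], avg[1], avg[2])
  record$best_ccc <- best$score
  record$failed <- FALSE
  record$n_evals <- n_evals
  record
}

# reference path: every candidate scored with a single-pass composite
# simulated projection (slow; used by tests and tiny grids)
optimize_particle_exact <- function(exp_img, target, remainder, record, cfg,
                                    tf = NULL) {
  n <- nrow(exp_img)
  grid <- build_search_grid(record$params, cfg$search)
  p0 <- record$params_preliminary
  mm <- resolve_mask2d(cfg$mask, n, center = c(p0["x"], p0["y"]))
  tf_sim <- NULL
  if (!is.null(tf) && cfg$ctf_mode != "none")
    tf_sim <- if (cfg$ctf_mode == "phase_flipped") abs(tf) else tf
  rem_img <- project(remainder, record$params_preliminary)
  if (!is.null(tf_sim)) rem_img <- apply_ctf(rem_img, tf_sim)
  exp_use <- exp_img; rem_use <- rem_img
  if (cfg$subtract) {
    sub <- subtract_nontarget(exp_img, rem_img, k_mode = cfg$k_mode)
    exp_use <- sub$image
    rem_use <- matrix(0, n, n)
  }
  scores <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sim <- project(target, orientation_params(grid$phi[i], grid$theta[i],
                                              grid$psi[i], grid$x[i],
                                              grid$y[i]))
    if (!is.null(tf_sim)) sim <- apply_ctf(sim, tf_sim)
    sim <- sim + rem_use
    scores[i] <- tryCatch(ccc(exp_use, sim, mm),
                          lorefine_degenerate_score = function(e) NA_real_)
  }
  best <- pick_best(scores, grid)
  finish_record(record, best, grid, length(scores))
}

finish_record <- function(record, best, grid, n_evals) {
  if (is.null(best)) {
    record$failed <- TRUE
    record$best_ccc <- NA_real_
  } else {
    record$params <- orientation_params(grid$phi[best$i], grid$theta[best$i],
                                        grid$psi[best$i], grid$x[best$i],
                                        grid$y[best$i])
    record$best_ccc <- best$score
    record$failed <- FALSE
  }
  record$n_evals <- n_evals
  record
}

#' Refine one module over a particle stack
#'
#' Recentres the model on the target module, transforms all particle
#' parameters accordingly, optimizes every particle with the configured
#' strategy and reconstructs the module from the refined parameters.
#' Deterministic given `cfg$seed`: each particle runs under its own RNG
#' stream keyed by `(seed, index)`, so results are independent of
#' execution order.
#'
#' @param stack A [particle_stack()] with a parameter table.
#' @param model The current full model ([density_volume()]).
#' @param target_mask Binary/soft 3D mask of the target module.
#' @param cfg A [refinement_config()].
#' @return List with the refined parameter table (`params`), the
#'   transformed preliminary table (`preliminary`), `reconstruction` (in
#'   the recentred frame), `shift3d`, `flags`, `n_evals`, and the recentred
#'   `target`/`remainder` volumes.
#' @export
refine_module <- function(stack, model, target_mask, cfg = refinement_config()) {
  m <- n_particles(stack)
  if (is.null(stack$params) || nrow(stack$params) != m)
    stop_invalid("stack must carry one parameter row per particle")
  rec <- recenter_model(model, target_mask)
  sv <- split_volume(rec$volume, rec$target_mask)
  prelim <- transform_particle_params(stack$params, rec$shift3d)
  refined <- prelim
  refined$ccc <- NA_real_
  flags <- logical(m)
  n_evals <- 0L
  tf_by_group <- NULL
  if (cfg$ctf_mode != "none" && !is.null(stack$ctf))
    tf_by_group <- lapply(stack$ctf, ctf_evaluate, n = dim(stack$images)[1])
  for (i in seq_len(m)) {
    p0 <- orientation_params(prelim$phi[i], prelim$theta[i], prelim$psi[i],
                             prelim$x[i], prelim$y[i])
    idx <- (prelim$index[i] %||% i)
    recd <- list(index = idx, params = p0, params_preliminary = p0)
    tf <- NULL
    if (!is.null(tf_by_group) && !is.null(prelim$defocus_group))
      tf <- tf_by_group[[prelim$defocus_group[i]]]
    # RNG stream keyed by the particle's own index: results do not depend
    # on the order particles are processed in
    set.seed(particle_seed(cfg$seed, idx))
    out <- tryCatch({
      if (cfg$strategy == "separate")
        optimize_particle_separate(stack$images[, , i], sv$target,
                                   sv$remainder, recd, cfg, tf)
      else
        optimize_particle_simultaneous(stack$images[, , i], sv$target,
                                       sv$remainder, recd, cfg, tf)
    }, lorefine_error = function(e) { recd$failed <- TRUE; recd })
    if (isTRUE(out$failed)) {
      flags[i] <- TRUE
    } else {
      refined[i, c("phi", "theta", "psi", "x", "y")] <-
        out$params[c("phi", "theta", "psi", "x", "y")]
      refined$ccc[i] <- out$best_ccc
    }
    n_evals <- n_evals + (out$n_evals %||% 0L)
  }
  if (mean(flags) > 0.5)
    lo_stop("refinement failed for more than half of the particles",
            "lorefine_refinement_failed")
  recon <- wbp_reconstruct(stack$images, refined, stack$pixel_size)
  list(params = refined, preliminary = prelim, reconstruction = recon,
       shift3d = rec$shift3d, flags = flags, n_evals = n_evals,
       target = sv$target, remainder = sv$remainder,
       target_mask = rec$target_mask)
}

#' Local-optimization refinement of a target module
#'
#' The main entry point: runs [refine_module()] and wraps the result in a
#' classed object with `print`, `summary`, `coef` and `plot` methods.
#'
#' @inheritParams refine_module
#' @return Object of class `lo_refine`.
#' @export
lo_refine <- function(stack, model, target_mask, cfg = refinement_config()) {
  out <- refine_module(stack, model, target_mask, cfg)
  out$cfg <- cfg
  out$n_particles <- n_particles(stack)
  out$pixel_size <- stack$pixel_size
  class(out) <- "lo_refine"
  out
}

#' @export
print.lo_refine <- function(x, ...) {
  cat(sprintf("LO-refinement (%s strategy): %d particles, %d failed\n",
              x$cfg$strategy, x$n_particles, sum(x$flags)))
  cat(sprintf("  grid evaluations: %d; median best CCC: %.4f\n",
              x$n_evals, stats::median(x$params$ccc, na.rm = TRUE)))
  dspan <- span_angle(x$params$phi, x$params$theta,
                      x$preliminary$phi, x$preliminary$theta)
  cat(sprintf("  median direction change: %.2f deg; median shift change: %.2f px\n",
              stats::median(dspan),
              stats::median(sqrt((x$params$x - x$preliminary$x)^2 +
                                   (x$params$y - x$preliminary$y)^2))))
  invisible(x)
}

#' @export
summary.lo_refine <- function(object, ...) {
  dspan <- span_angle(object$params$phi, object$params$theta,
                      object$preliminary$phi, object$preliminary$theta)
  dpsi <- abs(angdiff(object$params$psi, object$preliminary$psi))
  dshift <- sqrt((object$params$x - object$preliminary$x)^2 +
                   (object$params$y - object$preliminary$y)^2)
  out <- list(n_particles = object$n_particles, n_failed = sum(object$flags),
              strategy = object$cfg$strategy, n_evals = object$n_evals,
              ccc = summary(object$params$ccc),
              direction_change_deg = summary(dspan),
              psi_change_deg = summary(dpsi),
              shift_change_px = summary(dshift))
  class(out) <- "summary.lo_refine"
  out
}

#' @export
print.summary.lo_refine <- function(x, ...) {
  cat(sprintf("LO-refinement summary (%s strategy)\n", x$strategy))
  cat(sprintf("  particles: %d (%d failed), grid evaluations: %d\n",
              x$n_particles, x$n_failed, x$n_evals))
  cat("  best CCC:\n"); print(x$ccc)
  cat("  direction change (deg):\n"); print(x$direction_change_deg)
  cat("  in-plane rotation change (deg):\n"); print(x$psi_change_deg)
  cat("  shift change (px):\n"); print(x$shift_change_px)
  invisible(x)
}

#' @export
coef.lo_refine <- function(object, ...) {
  as.matrix(object$params[, c("phi", "theta", "psi", "x", "y")])
}

#' @export
plot.lo_refine <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  dspan <- span_angle(x$params$phi, x$params$theta,
                      x$preliminary$phi, x$preliminary$theta)
  graphics::hist(dspan, breaks = 20, main = "direction change",
                 xlab = "degrees", ...)
  graphics::hist(x$params$ccc, breaks = 20, main = "best masked CCC",
                 xlab = "CCC", ...)
  invisible(x)
}

#' Refine every module of a multi-module model
#'
#' Runs [refine_module()] once per module (each from the same input
#' parameters, treating all other modules as one fixed integral part) and
#' combines the module reconstructions, each mapped back to the original
#' frame and masked by its own module mask, into an updated model;
#' optionally iterates.
#'
#' @param stack A [particle_stack()].
#' @param model Full model ([density_volume()]).
#' @param masks List of module masks whose voxel-wise sum must not exceed 1.
#' @param cfg A [refinement_config()].
#' @param iterations Number of outer iterations (>= 1).
#' @return List with `modules` (per-module [refine_module()] results of the
#'   last iteration) and `model` (the updated combined model).
#' @export
refine_all_modules <- function(stack, model, masks, cfg = refinement_config(),
                               iterations = 1) {
  g <- as_volume_grid(model)
  msum <- Reduce(`+`, lapply(masks, as_volume_grid))
  if (max(msum) > 1 + 1e-6)
    stop_invalid("module masks overlap: voxel-wise sum exceeds 1")
  current <- model
  results <- NULL
  for (it in seq_len(iterations)) {
    results <- lapply(masks, function(mk)
      refine_module(stack, current, mk, cfg))
    combined <- as_volume_grid(current) * (1 - msum)
    for (m in seq_along(masks)) {
      back <- translate_grid(as_volume_grid(results[[m]]$reconstruction),
                             -results[[m]]$shift3d)
      combined <- combined + back * as_volume_grid(masks[[m]])
    }
    current <- density_volume(combined, model$pixel_size)
  }
  list(modules = results, model = current)
}
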