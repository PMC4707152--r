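# Conventional whole-model projection matching: the baseline whose
# converged parameters are the starting point ("before" state) of
# LO-refinement.  Two stages per particle: a coarse exhaustive match of
# reference projections on a global direction set (in-plane rotation
# handled by rotating the particle image, zero shift), then a local pass at
# the final sampling that alternates an exhaustive angle sweep at the
# current shift with an exhaustive shift sweep at the best angles.
# Deterministic: no randomness anywhere.

#' Conventional global projection matching
#'
#' Assigns per-particle `(phi, theta, psi, x, y)` by maximizing the masked
#' CCC between the particle and whole-model reference projections.
#'
#' @param stack A [particle_stack()].
#' @param model Reference model ([density_volume()]), e.g. a low-pass
#'   filtered ground-truth map or the previous reconstruction.
#' @param angular_spacing Final direction/psi sampling step, degrees.
#' @param shift_range Shift half-extent, pixels.
#' @param shift_step Shift step, pixels.
#' @param coarse_spacing Direction/psi step of the global stage, degrees.
#' @param mask 2D scoring mask spec as in [refinement_config()]; the
#'   default is a circular mask of diameter `n - 8` (it must be circular
#'   for the coarse stage's rotation trick to be exact).
#' @param max_iter Local-pass iterations; the pass is repeated until the
#'   assignment stops changing or `max_iter` is reached.
#' @return Data frame of assigned parameters (plus `ccc`), one row per
#'   particle.
#' @export
conventional_global_refine <- function(stack, model, angular_spacing = 2,
                                       shift_range = 4, shift_step = 1,
                                       coarse_spacing = 10, mask = NULL,
                                       max_iter = 1) {
  n <- dim(stack$images)[1]
  m <- n_particles(stack)
  mm <- if (is.null(mask)) circular_mask(n, n - 8) else resolve_mask2d(mask, n)
  mi <- mask_index(mm)
  g <- as_volume_grid(model)
  sr <- support_radius(g); if (sr <= 0) sr <- -1
  gvec <- as.numeric(g)

  # --- coarse stage: shared reference projections, zero shift ---
  D <- generate_direction_set(coarse_spacing)
  nd <- nrow(D)
  sel <- mi$idx + 1L
  refs <- matrix(0, length(sel), nd)
  for (d in seq_len(nd)) {
    pr <- cpp_project(gvec, n, euler_matrix(D$phi[d], D$theta[d], 0), 0, 0, sr)
    refs[, d] <- pr[sel]
  }
  w <- mi$w
  wnorm <- function(M) {
    mu <- colSums(M * w) / sum(w)
    Mc <- sweep(M, 2, mu) * sqrt(w)
    sweep(Mc, 2, pmax(sqrt(colSums(Mc^2)), 1e-300), "/")
  }
  refs_n <- wnorm(refs)
  psis_c <- seq(0, 360 - coarse_spacing, by = coarse_spacing)

  out <- data.frame(index = stack$params$index %||% seq_len(m),
                    phi = 0, theta = 0, psi = 0, x = 0, y = 0, ccc = NA_real_)
  fine_dirs <- generate_direction_set(angular_spacing)
  # the coarse lock can err by the covering radius plus the psi-coupling
  # wander, so the local cone is generously wider than the coarse spacing;
  # a second local pass re-centres the cone and walks the assignment in
  srch <- search_range(alpha0 = 1.2 * coarse_spacing, d1 = angular_spacing,
                       t1 = ceiling(coarse_spacing / angular_spacing),
                       d2 = shift_step,
                       t2 = round(shift_range / shift_step),
                       directions = fine_dirs)

  for (i in seq_len(m)) {
    img <- stack$images[, , i]
    # rotate the particle instead of every reference: for a circular mask
    # CCC(img, rotate(ref, psi)) = CCC(rotate(img, -psi), ref)
    E <- matrix(0, length(sel), length(psis_c))
    for (p in seq_along(psis_c))
      E[, p] <- cpp_rotate_image(img, -psis_c[p])[sel]
    sc <- crossprod(refs_n, wnorm(E))     # nd x npsi
    b <- arrayInd(which.max(sc), dim(sc))
    cur <- orientation_params(D$phi[b[1]], D$theta[b[1]], psis_c[b[2]], 0, 0)
    # --- local pass(es) at final sampling: alternate angles and shifts ---
    ctx <- list(n = n, exp_use = img, rem_use = matrix(0, n, n),
                tf_sim = NULL, widx = mi$idx, wval = mi$w, tgrid = gvec,
                sr = sr)
    best_score <- -Inf
    for (it in seq_len(max_iter)) {
      lg <- local_grid(cur, srch)
      # angle sweep at current shift
      ascores <- numeric(0)
      for (d in seq_len(nrow(lg$dirs))) {
        proj <- ctx_projection(ctx, lg$dirs$phi[d], lg$dirs$theta[d])
        ascores <- c(ascores,
                     cpp_score_psi_shift(img, ctx$rem_use, proj,
                                         lg$psis[d, ], cur["x"], cur["y"],
                                         0L, 0L, mi$idx, mi$w))
      }
      np <- length(lg$psi_off)
      agrid <- data.frame(span = rep(lg$dirs$span, each = np),
                          dpsi = rep(abs(lg$psi_off), times = nrow(lg$dirs)),
                          dshift = 0)
      ab <- pick_best(ascores, agrid)
      if (is.null(ab)) break
      d <- ((ab$i - 1L) %/% np) + 1L
      p <- ((ab$i - 1L) %% np) + 1L
      ang <- c(lg$dirs$phi[d], lg$dirs$theta[d], lg$psis[d, p])
      # shift sweep at the best angles
      proj <- ctx_projection(ctx, ang[1], ang[2])
      ss <- score_direction(ctx, proj, ang[3], cur["x"], cur["y"], lg$off)
      ns <- length(lg$off)
      sgrid <- data.frame(span = 0, dpsi = 0,
                          dshift = sqrt(rep(lg$off^2, each = ns) +
                                          rep(lg$off^2, times = ns)))
      sb <- pick_best(ss, sgrid)
      iy <- ((sb$i - 1L) %/% ns) + 1L
      ix <- ((sb$i - 1L) %% ns) + 1L
      newp <- orientation_params(ang[1], ang[2], ang[3],
                                 cur["x"] + lg$off[ix], cur["y"] + lg$off[iy])
      moved <- span_angle(newp["phi"], newp["theta"], cur["phi"],
                          cur["theta"]) > 1e-9 ||
        abs(angdiff(newp["psi"], cur["psi"])) > 1e-9 ||
        abs(newp["x"] - cur["x"]) + abs(newp["y"] - cur["y"]) > 1e-9
      cur <- newp
      best_score <- sb$score
      if (!moved) break
    }
    out[i, c("phi", "theta", "psi", "x", "y")] <-
      cur[c("phi", "theta", "psi", "x", "y")]
    out$ccc[i] <- best_score
  }
  out
}
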