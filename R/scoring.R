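# Cross-correlation objective.
# The CCC of two images is the normalized covariance over the pixels
# selected (or weighted) by a 2D mask; soft mask weights enter as frequency
# weights in the weighted means and sums, so the score stays invariant to
# positive affine rescaling of either image.  Degenerate (zero-variance)
# inputs raise a classed error rather than returning a silent value: a
# quiet zero could corrupt an argmax search.

#' Cross-correlation coefficient of two images
#'
#' @param img1,img2 Equal-shaped numeric matrices.
#' @param mask Optional weight matrix in `[0, 1]`; `NULL` means all pixels.
#' @return The CCC in `[-1, 1]`.
#' @export
ccc <- function(img1, img2, mask = NULL) {
  if (!identical(dim(img1), dim(img2))) stop_invalid("image shapes must match")
  if (is.null(mask)) {
    w <- rep(1, length(img1))
    a <- as.numeric(img1); b <- as.numeric(img2)
  } else {
    if (!identical(dim(mask), dim(img1)))
      stop_invalid("mask shape must match images")
    sel <- mask > 0
    if (sum(sel) < 2) stop_invalid("mask must select at least 2 pixels")
    w <- mask[sel]; a <- img1[sel]; b <- img2[sel]
  }
  out <- cpp_wccc(a, b, w)
  if (is.na(out))
    stop_degenerate("zero variance under mask: CCC undefined")
  # rounding can push the normalized covariance past its mathematical range
  min(max(out, -1), 1)
}

#' Numerator decomposition of the composite CCC
#'
#' For experimental and simulated images that are each the sum of a target
#' (A) and a non-target (B) module projection, the numerator of the
#' composite CCC splits into four cross terms, each computed with its own
#' component's mean.  Diagnostic only: the first term is the one the local
#' optimization effectively maximizes, the fourth is the cross-talk term
#' whose variance an appropriate target mask suppresses.
#'
#' @param f1A,f1B Experimental target/non-target component images.
#' @param f2A,f2B Simulated target/non-target component images.
#' @return Named numeric vector `(AA, AB, BB, BA)`: covariance sums of
#'   (exp A, sim A), (exp A, sim B), (exp B, sim B), (exp B, sim A).
#' @export
ccc_numerator_terms <- function(f1A, f1B, f2A, f2B) {
  dims <- list(dim(f1A), dim(f1B), dim(f2A), dim(f2B))
  if (length(unique(dims)) != 1L) stop_invalid("image shapes must match")
  ctr <- function(x) x - mean(x)
  c(AA = sum(ctr(f1A) * ctr(f2A)),
    AB = sum(ctr(f1A) * ctr(f2B)),
    BB = sum(ctr(f1B) * ctr(f2B)),
    BA = sum(ctr(f1B) * ctr(f2A)))
}

#' Target CCC after non-target subtraction
#'
#' Realizes the CTF-aware objective: subtract the (scaled) simulated
#' non-target projection from the experimental image, then score the
#' residual against the simulated target projection under the mask.
#'
#' @param exp_img Experimental image.
#' @param nontarget_sim Simulated non-target projection.
#' @param target_sim Simulated target projection.
#' @param mask Optional 2D weight mask.
#' @inheritParams subtract_nontarget
#' @return List with `score` and the scaling factor `k` used.
#' @export
ccc_target <- function(exp_img, nontarget_sim, target_sim, mask = NULL,
                       k_mode = c("least_squares", "fixed"), k = 1,
                       support = NULL) {
  if (all(nontarget_sim == 0)) {
    return(list(score = ccc(exp_img, target_sim, mask), k = 0))
  }
  sub <- subtract_nontarget(exp_img, nontarget_sim, k_mode = k_mode, k = k,
                            support = support)
  list(score = ccc(sub$image, target_sim, mask), k = sub$k)
}
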