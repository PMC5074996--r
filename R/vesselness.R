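#' Parameters for multi-scale Hessian vesselness
#'
#' The Frangi vesselness of a voxel at Gaussian kernel scale S is
#' \deqn{V_S = (1 - e^{-R_A^2/2\alpha^2}) \; e^{-R_B^2/2\beta^2} \;
#'       (1 - e^{-\|\lambda\|^2/2c^2})}
#' with eigenvalues of the scale-normalized Hessian ordered
#' \eqn{|\lambda_1| \le |\lambda_2| \le |\lambda_3|},
#' \eqn{R_A = |\lambda_2|/|\lambda_3|} (plate vs tube),
#' \eqn{R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}} (blob), and
#' \eqn{\|\lambda\|^2 = \sum_i \lambda_i^2} (structureness). For bright
#' tubes V_S = 0 wherever \eqn{\lambda_2 > 0} or \eqn{\lambda_3 > 0}, and
#' at degenerate denominators (\eqn{\lambda_2\lambda_3 = 0}).
#'
#' @param scales strictly increasing Gaussian kernel scales S in voxels;
#'   integer scales 1..30 by default.
#' @param alpha plate/tube discriminant sensitivity (> 0).
#' @param beta blob discriminant sensitivity (> 0).
#' @param c structureness sensitivity: a positive number, or `"auto"` to use
#'   half of the maximum Hessian Frobenius norm over the volume across all
#'   scales of the run. The global (cross-scale) maximum keeps the
#'   structureness term comparable between scales, which is what makes the
#'   per-voxel argmax scale a usable caliber surrogate.
#' @param gamma scale-normalization exponent: second derivatives are
#'   multiplied by S^gamma. gamma = 2 makes responses comparable across
#'   scales for second-order structure.
#' @param polarity `"bright-tubes"` (vessels denser than surroundings, the
#'   micro-CT lung case) or `"dark-tubes"`.
#' @return A `vesselness_params` object.
#' @export
vesselness_params <- function(scales = 1:30, alpha = 0.5, beta = 0.5,
                              c = "auto", gamma = 2,
                              polarity = c("bright-tubes", "dark-tubes")) {
  polarity <- match.arg(polarity)
  scales <- as.numeric(scales)
  if (length(scales) < 1L) stop("`scales` must be non-empty")
  if (any(scales <= 0) || any(diff(scales) <= 0))
    stop("`scales` must be strictly increasing and positive")
  if (!identical(c, "auto") && (!is.numeric(c) || c <= 0))
    stop("`c` must be \"auto\" or a positive number")
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive")
  structure(list(scales = scales, alpha = alpha, beta = beta, c = c,
                 gamma = gamma, polarity = polarity),
            class = "vesselness_params")
}

#' Scale-normalized Hessian field at one Gaussian scale
#'
#' Smooths the volume with an isotropic Gaussian of standard deviation S
#' (separable FIR convolution, symmetric/reflective boundaries) and forms
#' the six unique second derivatives by central differences, each multiplied
#' by S^gamma.
#'
#' @param vol an [intensity_volume()] or 3D array.
#' @param S Gaussian kernel scale in voxels (> 0, at most half the smallest
#'   volume dimension).
#' @param gamma scale-normalization exponent.
#' @return list of six 3D arrays: `xx`, `xy`, `xz`, `yy`, `yz`, `zz`.
#' @export
hessian_at_scale <- function(vol, S, gamma = 2) {
  vol <- as_volume(vol)
  d <- dim(vol$voxels)
  if (S <= 0) stop("`S` must be positive")
  if (S > min(d) / 2)
    stop("scale S exceeds half the smallest volume dimension")
  h <- cpp_hessian_at_scale(as.numeric(vol$voxels), d, S, S^gamma)
  lapply(h, array, dim = d)
}

#' Eigenvalues of a Hessian field, sorted by absolute value
#'
#' @param hess list of six arrays as returned by [hessian_at_scale()].
#' @return list of arrays `lam1`, `lam2`, `lam3` with
#'   `|lam1| <= |lam2| <= |lam3|` at every voxel.
#' @export
sorted_eigenvalues <- function(hess) {
  d <- dim(hess$xx)
  e <- cpp_eigvals_sym3(as.numeric(hess$xx), as.numeric(hess$xy),
                        as.numeric(hess$xz), as.numeric(hess$yy),
                        as.numeric(hess$yz), as.numeric(hess$zz))
  lapply(e, array, dim = d)
}

#' Frangi vesselness from Hessian eigenvalues at one scale
#'
#' @param eig list of arrays `lam1`, `lam2`, `lam3` from
#'   [sorted_eigenvalues()].
#' @param params a [vesselness_params()]; if `params$c` is `"auto"`, c is
#'   resolved as half the maximum Frobenius norm (eigenvalue 2-norm) over
#'   this field.
#' @return 3D array of vesselness values in `[0, 1]`.
#' @export
vesselness_at_scale <- function(eig, params = vesselness_params()) {
  d <- dim(eig$lam1)
  cval <- params$c
  if (identical(cval, "auto")) {
    cval <- sqrt(max(eig$lam1^2 + eig$lam2^2 + eig$lam3^2)) / 2
    if (cval <= 0) cval <- 1
  }
  v <- cpp_vesselness_from_eigs(as.numeric(eig$lam1), as.numeric(eig$lam2),
                                as.numeric(eig$lam3), params$alpha,
                                params$beta, cval,
                                params$polarity == "bright-tubes")
  array(v, dim = d)
}

#' Multi-scale vesselness: probability and S_MAX volumes
#'
#' Runs the Frangi filter over all scales, streaming one scale at a time so
#' the peak working set stays at a fixed number of volume-sized grids.
#' Returns the pointwise maximum of vesselness over scales (the
#' "probability volume") and the scale at which the maximum is attained
#' (S_MAX, the caliber surrogate). Ties take the smallest scale; voxels with
#' zero probability carry `NA` in the S_MAX volume.
#'
#' @param vol an [intensity_volume()] or 3D array.
#' @param params a [vesselness_params()].
#' @return A `vesselness_result`: list with `probability` (array in
#'   `[0, 1]`), `s_max` (array of scales or `NA`), `valid` (logical array,
#'   `FALSE` where the voxel is within 3 S_MAX of the volume border so the
#'   filter support was truncated), `params`, resolved `c`, and `voxel_size`.
#' @export
multiscale_vesselness <- function(vol, params = vesselness_params()) {
  vol <- as_volume(vol)
  d <- dim(vol$voxels)
  if (max(params$scales) > min(d) / 2)
    stop("largest scale exceeds half the smallest volume dimension")
  cval <- if (identical(params$c, "auto")) -1 else params$c
  res <- cpp_multiscale_vesselness(as.numeric(vol$voxels), d, params$scales,
                                   params$alpha, params$beta, cval,
                                   params$gamma,
                                   params$polarity == "bright-tubes")
  prob <- array(res$probability, dim = d)
  smax <- array(res$s_max, dim = d)
  bdist <- border_distance(d)
  valid <- is.na(smax) | (bdist >= 3 * smax)
  structure(list(probability = prob, s_max = smax, valid = valid,
                 params = params, c = res$c,
                 scale_max_norm = res$scale_max_norm,
                 voxel_size = vol$voxel_size),
            class = "vesselness_result")
}

border_distance <- function(d) {
  ix <- pmin(seq_len(d[1]) - 1, d[1] - seq_len(d[1]))
  iy <- pmin(seq_len(d[2]) - 1, d[2] - seq_len(d[2]))
  iz <- pmin(seq_len(d[3]) - 1, d[3] - seq_len(d[3]))
  outer(outer(ix, iy, pmin), iz, pmin)
}

#' @export
print.vesselness_result <- function(x, ...) {
  d <- dim(x$probability)
  cat(sprintf("<vesselness_result> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  scales %s..%s (n=%d), alpha=%.3g beta=%.3g c=%.4g gamma=%.3g\n",
              min(x$params$scales), max(x$params$scales),
              length(x$params$scales), x$params$alpha, x$params$beta,
              x$c, x$params$gamma))
  cat(sprintf("  probability range [%.3g, %.3g]; %.1f%% voxels with V > 0\n",
              min(x$probability), max(x$probability),
              100 * mean(x$probability > 0)))
  invisible(x)
}
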