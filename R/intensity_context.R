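# Region-specific multi-modal intensity-context priors.
#
# MR intensities are not quantitative, so each tissue's plausible intensity
# range is pinned to quantiles of the image histogram rather than absolute
# values.  A voxel supports a tissue only if, for EVERY modality, its
# (bias-corrected) intensity falls strictly inside that tissue's quantile
# interval; the spatial prior is multiplied by this indicator and
# renormalized.  Bounds are conservative by construction: they are meant to
# never exclude true members of a tissue.

#' Empirical quantile of a masked volume
#'
#' Linear-interpolation (type-7) quantile of the intensities under the
#' mask; `q = 0` gives the minimum, `q = 1` the maximum.
#'
#' @param vol an [mri_volume()].
#' @param mask logical array (same grid), must select at least one voxel.
#' @param q quantile fraction in `[0, 1]` (vectorized).
#' @export
quantile_threshold <- function(vol, mask, q) {
  stopifnot(all(q >= 0 & q <= 1))
  x <- vol$data[mask]
  if (length(x) == 0L) stop("empty quantile mask")
  unname(stats::quantile(x, q, type = 7, names = FALSE))
}

#' Quantile-histogram mask from the warped atlas
#'
#' Voxels where the summed warped prior over all non-Air classes exceeds
#' `threshold`; restricting the histogram to the atlas-supported head
#' region keeps background air from dominating the quantiles.  The default
#' of 0.5 ("more likely head than air") keeps the mask approximately equal
#' to the head region regardless of how soft the atlas boundaries are; a
#' permissive cutoff would let the air tail of a blurred atlas dominate
#' the histogram and push every configured quantile into the wrong
#' intensity regime.
#'
#' @param atlas a warped [prior_atlas()].
#' @param threshold prior-sum cutoff in `[0, 1]` (default 0.5).
#' @return logical array.
#' @export
quantile_mask <- function(atlas, threshold = 0.5) {
  keep <- atlas$config$name != "Air"
  tot <- Reduce(`+`, lapply(atlas$priors[keep], function(v) v$data))
  tot > threshold
}

#' Per-tissue, per-modality intensity bounds from quantile fractions
#'
#' For every tissue row and modality, converts the configured quantile
#' fractions into intensity thresholds on the current (bias-corrected)
#' fused images.  Bounds must be recomputed whenever the images change.
#'
#' Configured fractions of 0 and 1 are *unbounded* sentinels (`-Inf` /
#' `+Inf` thresholds): an interval that is meant to include a tissue
#' completely must not exclude voxels merely for lying outside the masked
#' histogram's range (the background/Air classes live below the head
#' minimum by construction, and the maximal voxel of a `q_upper = 1`
#' tissue would otherwise fail its own strict bound).
#'
#' @param session fused [image_session()] (current corrected images).
#' @param config a `tissue_config` with bounds for every session modality.
#' @param mask logical array defining the histogram domain.
#' @return object of class `context_bounds`: list of `lower` and `upper`
#'   K x M matrices (tissue x modality, intensity units).
#' @export
compute_bounds <- function(session, config, mask) {
  mods <- session_modalities(session)
  fused <- session_fused(session)
  K <- nrow(config)
  lower <- upper <- matrix(NA_real_, K, length(mods),
                           dimnames = list(config$name, mods))
  for (m in mods) {
    qlo <- config[[paste0("q_lower.", m)]]
    qhi <- config[[paste0("q_upper.", m)]]
    if (is.null(qlo) || is.null(qhi))
      stop("tissue config has no quantile bounds for modality ", m)
    lower[, m] <- ifelse(qlo == 0, -Inf,
                         quantile_threshold(fused[[m]], mask, qlo))
    upper[, m] <- ifelse(qhi == 1, Inf,
                         quantile_threshold(fused[[m]], mask, qhi))
  }
  structure(list(lower = lower, upper = upper, modalities = mods),
            class = "context_bounds")
}

#' @export
print.context_bounds <- function(x, ...) {
  cat("<context_bounds> tissue x modality intensity intervals\n")
  for (m in x$modalities)
    cat(sprintf("  %s: [%s]\n", m,
                paste(sprintf("%s (%.4g, %.4g)", rownames(x$lower),
                              x$lower[, m], x$upper[, m]), collapse = "; ")))
  invisible(x)
}

#' Intensity-context indicator for one tissue
#'
#' 1 where the voxel's intensity vector lies strictly inside the tissue's
#' interval on ALL modalities (a conjunction), else 0.
#'
#' @param session fused [image_session()].
#' @param bounds a `context_bounds` computed from the same images.
#' @param tissue tissue name (row of the bounds).
#' @return binary [mri_volume()].
#' @export
indicator <- function(session, bounds, tissue) {
  st <- indicator_stack(session, bounds, tissues = tissue)
  mri_volume(array(st[, 1L], session$dim), session$spacing, session$origin)
}

#' Indicator stack for all tissues
#'
#' @inheritParams indicator
#' @param tissues tissue names (default: all rows of `bounds`).
#' @return binary N x K matrix (voxels x tissues).
#' @export
indicator_stack <- function(session, bounds, tissues = rownames(bounds$lower)) {
  Y <- session_matrix(session)
  out <- matrix(0, nrow(Y), length(tissues),
                dimnames = list(NULL, tissues))
  for (l in tissues) {
    ok <- rep(TRUE, nrow(Y))
    for (m in bounds$modalities)
      ok <- ok & (Y[, m] > bounds$lower[l, m]) & (Y[, m] < bounds$upper[l, m])
    out[, l] <- as.numeric(ok)
  }
  out
}

#' Constrain spatial priors by the intensity-context indicators
#'
#' Per-voxel renormalized product of the (warped, weighted) spatial prior
#' and the tissue indicators.  Voxels where every product vanishes (the
#' constraint would leave no admissible tissue) fall back to the
#' unconstrained prior; their count is recorded in attribute `n_fallback`
#' and reported by the pipeline log — a conservative constraint should
#' trim, never kill, the prior support.
#'
#' @param stack normalized spatial [prob_stack()].
#' @param indicators binary N x K matrix from [indicator_stack()] with
#'   columns matching `stack$classes`.
#' @return constrained [prob_stack()].
#' @export
constrain_priors <- function(stack, indicators) {
  stopifnot(nrow(indicators) == nrow(stack$p),
            ncol(indicators) == length(stack$classes))
  p <- stack$p * indicators
  tot <- rowSums(p)
  fallback <- tot <= 0
  if (any(fallback)) {
    p[fallback, ] <- stack$p[fallback, , drop = FALSE]
    tot[fallback] <- rowSums(p[fallback, , drop = FALSE])
  }
  out <- prob_stack(p / tot, stack$classes, stack$dim, stack$spacing,
                    stack$origin)
  attr(out, "n_fallback") <- sum(fallback)
  out
}
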