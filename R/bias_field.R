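# Smooth intensity-inhomogeneity (bias) field estimation.
#
# Scanner bias is physically multiplicative, while the mixture model wants
# an additive correction; working in log-intensity space reconciles the two
# (the classic adaptive-segmentation convention).  The field is modelled as
# a low-order 3-D polynomial per modality, fitted by precision-weighted
# least squares to the residual between the observed (working-space)
# intensity and its posterior-expected class mean, with weights restricted
# to the bias-eligible tissues of the configuration.  The mask-mean of the
# field is removed for identifiability (a constant offset is absorbed by
# the class means instead).

#' 3-D polynomial basis over a grid
#'
#' All monomials `x^i y^j z^k` with total degree `i+j+k <= order` in
#' per-axis coordinates scaled to `[-1, 1]`; column 1 is the constant.
#'
#' @param dim grid dimensions (length 3).
#' @param order maximum total degree (>= 0).
#' @return N x P matrix (column-major voxel order).
#' @export
poly_basis <- function(dim, order) {
  stopifnot(order >= 0L)
  co <- unit_coords(dim)
  x <- 2 * as.numeric(co$x) - 1
  y <- 2 * as.numeric(co$y) - 1
  z <- 2 * as.numeric(co$z) - 1
  cols <- list()
  nm <- character(0)
  for (deg in 0:order) for (i in deg:0) for (j in (deg - i):0) {
    k <- deg - i - j
    cols[[length(cols) + 1L]] <- x^i * y^j * z^k
    nm <- c(nm, sprintf("x%dy%dz%d", i, j, k))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Bias field estimate
#'
#' @param coef named list (per modality) of basis coefficients.
#' @param fields named list (per modality) of voxelized fields (numeric
#'   vectors, working-space units, zero mean over the mask).
#' @param order polynomial order used.
#' @param mask logical array the fit was restricted to.
#' @param dim,spacing,origin grid metadata.
#' @param space working-space tag (`"log"` or `"linear"`).
#' @export
bias_field <- function(coef, fields, order, mask, dim, spacing, origin,
                       space = "log") {
  structure(list(coef = coef, fields = fields, order = order, mask = mask,
                 dim = dim, spacing = spacing, origin = origin,
                 space = space),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  rng <- vapply(x$fields, function(f) max(abs(f)), 0)
  cat(sprintf("<bias_field> order %d, %s space; max |field|: %s\n",
              x$order, x$space,
              paste(sprintf("%s %.4g", names(rng), rng), collapse = ", ")))
  invisible(x)
}

#' Field of one modality as a volume
#' @param field a [bias_field()].
#' @param modality modality name.
#' @export
bias_volume <- function(field, modality) {
  mri_volume(array(field$fields[[modality]], field$dim), field$spacing,
             field$origin)
}

#' Estimate the per-modality bias field from current posteriors
#'
#' Per modality: the residual `r_i = y_i - sum_l p_il mu_l` is regressed
#' onto the polynomial basis by weighted least squares with
#' precision weights `w_i = sum_{l bias-eligible} p_il / sigma_l^2`
#' (marginal class variance of that modality), restricted to the mask.
#' The fitted field is evaluated on the whole grid (smooth basis
#' extrapolation outside the mask) and its mask-mean subtracted.
#'
#' @param session working-space fused [image_session()].
#' @param state current [mixture_state()].
#' @param posteriors current [prob_stack()].
#' @param config `tissue_config` supplying the `use_in_bias` flags.
#' @param order polynomial order (default 4).
#' @param mask logical array; the fit domain.
#' @param basis optional precomputed [poly_basis()] (reused across
#'   iterations).
#' @return a [bias_field()].
#' @export
estimate_bias <- function(session, state, posteriors, config, order = 4L,
                          mask = NULL, basis = NULL) {
  Y <- session_matrix(session)
  P <- posteriors$p
  stopifnot(identical(posteriors$classes, config$name))
  if (!any(config$use_in_bias))
    stop("no tissue has use_in_bias = TRUE")
  if (is.null(mask)) mask <- array(TRUE, session$dim)
  mv <- as.logical(mask)
  if (is.null(basis)) basis <- poly_basis(session$dim, order)
  elig <- which(config$use_in_bias)
  coefs <- fields <- list()
  for (m in session_modalities(session)) {
    mi <- match(m, session_modalities(session))
    mu_m <- state$mu[, mi]
    sig2_m <- vapply(state$sigma, function(s) s[mi, mi], 0)
    w <- rowSums(sweep(P[, elig, drop = FALSE], 2L, sig2_m[elig], "/"))
    w_mask <- w[mv]
    if (sum(w_mask) <= 0)
      stop("no bias-eligible posterior mass for modality ", m)
    resid <- Y[, m] - as.numeric(P %*% mu_m)
    fit <- stats::lm.wfit(basis[mv, , drop = FALSE], resid[mv], w_mask)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    field <- as.numeric(basis %*% beta)
    field <- field - mean(field[mv])
    # the polynomial is only constrained on the mask; clamp the
    # extrapolation outside it to the range observed inside so far-corner
    # voxels cannot receive an explosive "correction"
    rng <- range(field[mv])
    field <- pmin(pmax(field, rng[1L]), rng[2L])
    coefs[[m]] <- beta
    fields[[m]] <- field
  }
  bias_field(coefs, fields, order, mask, session$dim, session$spacing,
             session$origin)
}

#' Subtract an estimated bias field from a session
#'
#' Works in whatever space the session is in (the pipeline passes
#' working/log-space images); outside the mask the smooth basis
#' extrapolation is subtracted too, so there are no seams.
#'
#' @param session fused [image_session()].
#' @param field a [bias_field()] on the same grid.
#' @export
correct_bias <- function(session, field) {
  mods <- session_modalities(session)
  Y <- session_matrix(session)
  for (m in mods) Y[, m] <- Y[, m] - field$fields[[m]]
  session_from_matrix(session, Y)
}

#' Log-intensity working space and its inverse
#'
#' `to_working_space` maps `v -> log(max(v, 0) + eps)` with
#' `eps = 1e-3 x median of the masked intensities` by default; a
#' multiplicative field in linear space becomes additive in log space.
#' Non-positive intensities (possible after additive noise) are clamped to
#' zero before the log.  `from_working_space` is the exact inverse
#' (`exp(w) - eps`) for positive inputs.
#'
#' @param vol an [mri_volume()].
#' @param eps positive offset; default derived from `mask`.
#' @param mask logical array used to derive the default `eps`.
#' @return an [mri_volume()]; the `eps` used is attached as attribute
#'   `eps`.
#' @export
to_working_space <- function(vol, eps = NULL, mask = NULL) {
  if (is.null(eps)) {
    ref <- if (is.null(mask)) vol$data else vol$data[mask]
    eps <- 1e-3 * stats::median(ref[ref > 0])
    if (!is.finite(eps) || eps <= 0) eps <- 1e-3
  }
  out <- mri_volume(log(pmax(vol$data, 0) + eps), vol$spacing, vol$origin)
  attr(out, "eps") <- eps
  out
}

#' @rdname to_working_space
#' @export
from_working_space <- function(vol, eps) {
  mri_volume(exp(vol$data) - eps, vol$spacing, vol$origin)
}
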