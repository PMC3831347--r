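#' Synthetic phantom specification
#'
#' Describes a BrainWeb-style synthetic session: nested-ellipsoid tissue
#' geometry (air background, CSF shell, GM shell, WM core, optional
#' subcortical blobs), piecewise-constant per-tissue intensities per
#' modality, a multiplicative smooth bias field of peak amplitude `rf`
#' percent, and additive Gaussian noise with standard deviation `pn`
#' percent of the WM mean (the BrainWeb noise convention).
#'
#' @param n grid size per axis (scalar or length-3), default 64.
#' @param spacing voxel size in mm.
#' @param means per-tissue per-modality mean intensity table: a data.frame
#'   with rownames = class names and one column per modality.  Row order
#'   fixes the class codes (0-based).
#' @param geometry named list of ellipsoid semi-axis fractions (of the half
#'   grid) for `csf_outer`, `gm_outer`, `wm`; each length 3.
#' @param blobs optional list of subcortical blobs, each
#'   `list(class, center, radii)` with `center`/`radii` as fractions of the
#'   half grid; `class` must name a row of `means`.
#' @param pn noise level, percent of the WM mean (>= 0).
#' @param rf bias-field amplitude, percent peak deviation of the
#'   multiplicative field (>= 0); 20 and 40 are the conventional levels.
#' @param prior_blur Gaussian blur (voxels) applied to the one-hot
#'   ground-truth priors to emulate an imperfect atlas.
#' @param prior_offset integer voxel translation of the priors, emulating
#'   residual misregistration.
#' @param repeats number of repeats per modality (independent noise).
#' @param seed base random seed for bias coefficients and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n = 64, spacing = c(1, 1, 1),
                         means = default_phantom_means(),
                         geometry = list(csf_outer = c(0.88, 0.82, 0.78),
                                         gm_outer = c(0.74, 0.70, 0.66),
                                         wm = c(0.52, 0.48, 0.44)),
                         blobs = list(),
                         pn = 3, rf = 20,
                         prior_blur = 1.5, prior_offset = c(0, 0, 0),
                         repeats = 1L, seed = 1L) {
  n <- rep_len(as.integer(n), 3L)
  stopifnot(all(n >= 4L), pn >= 0, rf >= 0, prior_blur >= 0, repeats >= 1L)
  if (any(as.matrix(means) <= 0)) stop("tissue mean intensities must be > 0")
  stopifnot(all(c("csf_outer", "gm_outer", "wm") %in% names(geometry)))
  structure(list(n = n, spacing = rep_len(spacing, 3L), means = means,
                 geometry = geometry, blobs = blobs, pn = pn, rf = rf,
                 prior_blur = prior_blur,
                 prior_offset = rep_len(as.integer(prior_offset), 3L),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom intensity table (T1w / T2w)
#'
#' Typical relative tissue contrasts: on T1w, WM > GM > CSF; on T2w,
#' CSF > GM > WM.  Arbitrary units on a scanner-like scale.
#' @export
default_phantom_means <- function() {
  data.frame(T1 = c(Air = 10, Csf = 40, Gm = 100, Wm = 140),
             T2 = c(Air = 10, Csf = 180, Gm = 110, Wm = 70))
}

phantom_classes <- function(spec) rownames(spec$means)

# seeded sub-stream, kept below 2^31
sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)

#' Rasterize the phantom's ground-truth label volume
#'
#' Deterministic (no randomness): voxel centers are tested against the
#' nested ellipsoids in order air -> CSF -> GM -> WM, then blobs override.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()] with 0-based codes in `means` row order.
#' @export
generate_labels <- function(spec) {
  d <- spec$n
  cls <- phantom_classes(spec)
  # centered coordinates in [-1, 1] per axis
  cc <- lapply(1:3, function(ax) {
    h <- (d[ax] - 1) / 2
    (seq_len(d[ax]) - 1 - h) / h
  })
  t1 <- array(rep(cc[[1L]], times = d[2L] * d[3L]), d)
  t2 <- array(rep(rep(cc[[2L]], each = d[1L]), times = d[3L]), d)
  t3 <- array(rep(cc[[3L]], each = d[1L] * d[2L]), d)
  inside <- function(center, radii) {
    if (any(radii <= 0)) return(array(FALSE, d))
    ((t1 - center[1L]) / radii[1L])^2 + ((t2 - center[2L]) / radii[2L])^2 +
      ((t3 - center[3L]) / radii[3L])^2 <= 1
  }
  lab <- array(0L, d)
  lab[inside(c(0, 0, 0), spec$geometry$csf_outer)] <- match("Csf", cls) - 1L
  lab[inside(c(0, 0, 0), spec$geometry$gm_outer)] <- match("Gm", cls) - 1L
  lab[inside(c(0, 0, 0), spec$geometry$wm)] <- match("Wm", cls) - 1L
  for (b in spec$blobs) {
    j <- match(b$class, cls)
    if (is.na(j)) stop("blob class not in intensity table: ", b$class)
    lab[inside(b$center, b$radii)] <- j - 1L
  }
  counts <- tabulate(lab + 1L, nbins = length(cls))
  empty <- cls[counts == 0L]
  if (length(empty) > 0L)
    stop("class ", paste(empty, collapse = ", "), " empty")
  label_volume(lab, stats::setNames(seq_along(cls) - 1L, cls),
               spec$spacing, c(0, 0, 0))
}

#' Render noise-free, bias-free modality images from labels
#'
#' Each voxel takes exactly its class mean for each modality.
#'
#' @param labels ground-truth [label_volume()].
#' @param spec the [phantom_spec()] providing the intensity table.
#' @return an [image_session()] with one repeat per modality.
#' @export
render_modalities <- function(labels, spec) {
  cls <- phantom_classes(spec)
  scans <- lapply(names(spec$means), function(m) {
    lut <- spec$means[[m]]
    mri_volume(array(lut[labels$data + 1L], dim(labels$data)),
               labels$spacing, labels$origin)
  })
  names(scans) <- names(spec$means)
  image_session(scans)
}

#' Apply a seeded smooth multiplicative bias field
#'
#' The field is `1 + s * g` where `g` is a sum of a few seeded low-order
#' cosine-product components, centred to zero mean over the foreground, and
#' `s` rescales it so that `max |field - 1|` over the foreground equals
#' exactly `rf/100`.  Zero mean keeps the simulated inhomogeneity from
#' smuggling in a global intensity scale (which would be unidentifiable for
#' any bias estimator).  The true field is returned for recovery tests.
#'
#' @param vol input [mri_volume()].
#' @param rf percent peak deviation (>= 0); `rf = 0` returns the input
#'   unchanged with a unit field.
#' @param seed RNG seed for the component coefficients.
#' @param foreground optional logical array over which the peak/mean are
#'   taken; defaults to the whole grid.
#' @return `list(volume, field)`, both [mri_volume()]s.
#' @export
apply_bias <- function(vol, rf, seed = 1L, foreground = NULL) {
  stopifnot(rf >= 0)
  d <- dim(vol$data)
  if (is.null(foreground)) foreground <- array(TRUE, d)
  if (rf == 0) {
    field <- mri_volume(array(1, d), vol$spacing, vol$origin)
    return(list(volume = vol, field = field))
  }
  g <- with_seed(seed, {
    co <- unit_coords(d)
    acc <- array(0, d)
    for (k in 1:5) {
      f <- sample(c(0, 0.5, 1, 1.5), 3L, replace = TRUE)
      if (all(f == 0)) f[sample.int(3L, 1L)] <- 0.5
      ph <- stats::runif(3L, 0, 2 * pi)
      comp <- cos(pi * f[1L] * co$x + ph[1L]) *
        cos(pi * f[2L] * co$y + ph[2L]) *
        cos(pi * f[3L] * co$z + ph[3L])
      acc <- acc + stats::rnorm(1L) * comp
    }
    acc
  })
  g <- g - mean(g[foreground])
  peak <- max(abs(g[foreground]))
  if (peak == 0) stop("degenerate bias components (flat field)")
  field_arr <- 1 + (rf / 100) * g / peak
  field <- mri_volume(field_arr, vol$spacing, vol$origin)
  out <- mri_volume(vol$data * field_arr, vol$spacing, vol$origin)
  list(volume = out, field = field)
}

#' Add seeded Gaussian noise at a BrainWeb-style percent level
#'
#' Zero-mean Gaussian noise with standard deviation
#' `pn/100 * reference_mean` (reference = WM mean by convention).
#'
#' @param vol input [mri_volume()].
#' @param pn percent noise level (>= 0).
#' @param reference_mean reference tissue mean intensity.
#' @param seed RNG seed.
#' @export
add_noise <- function(vol, pn, reference_mean, seed = 1L) {
  stopifnot(pn >= 0, reference_mean > 0)
  if (pn == 0) return(vol)
  noise <- with_seed(seed, stats::rnorm(length(vol$data),
                                        sd = pn / 100 * reference_mean))
  mri_volume(vol$data + array(noise, dim(vol$data)), vol$spacing, vol$origin)
}

#' Degrade ground-truth labels into an imperfect prior atlas
#'
#' One-hot class maps are translated by `offset` voxels (simulating
#' residual misregistration) and Gaussian-blurred by `blur` voxels
#' (simulating atlas population averaging), then renormalized to sum to 1
#' per voxel.  `blur = 0`, `offset = 0` returns exact one-hot priors.
#'
#' @param labels ground-truth [label_volume()].
#' @param blur Gaussian sigma in voxels (>= 0).
#' @param offset integer voxel translation (length 3).
#' @param config `tissue_config` whose rows match the label classes.
#' @return a warped [prior_atlas()].
#' @export
make_prior_atlas <- function(labels, blur = 0, offset = c(0, 0, 0),
                             config = phantom_tissue_config()) {
  stopifnot(blur >= 0)
  offset <- rep_len(as.integer(round(offset)), 3L)
  if (!setequal(names(labels$labels), config$name))
    stop("label classes do not match tissue config rows")
  priors <- lapply(config$name, function(cl) {
    oh <- (labels$data == labels$labels[[cl]]) * 1
    oh <- shift_array(oh, offset)
    if (blur > 0) oh <- gaussian_blur3d(oh, blur)
    oh
  })
  tot <- Reduce(`+`, priors)
  bg <- background_class_index(config)
  zero <- tot <= 0
  if (any(zero)) {
    priors[[bg]][zero] <- 1
    tot[zero] <- 1
  }
  priors <- lapply(priors, function(p) {
    v <- p / tot
    mri_volume(array(v, dim(labels$data)), labels$spacing, labels$origin)
  })
  names(priors) <- config$name
  prior_atlas(config, priors, warped = TRUE)
}

#' Generate a complete synthetic session
#'
#' Composes the phantom stages in the BrainWeb order: rasterize labels,
#' render clean modalities, apply multiplicative bias (independent field
#' per modality), then add noise (independent per modality and repeat).
#'
#' @param spec a [phantom_spec()].
#' @param config tissue configuration for the prior atlas.
#' @return list with `session` ([image_session()]), `labels`
#'   ([label_volume()]), `clean` (noise/bias-free session), `fields` (true
#'   bias field per modality), `atlas` (degraded [prior_atlas()]), and
#'   `config`.
#' @export
generate_phantom_session <- function(spec, config = phantom_tissue_config()) {
  labels <- generate_labels(spec)
  clean <- render_modalities(labels, spec)
  fg <- labels$data > 0
  mods <- names(spec$means)
  fields <- list()
  scans <- list()
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    b <- apply_bias(clean$scans[[m]][[1L]], spec$rf,
                    seed = sub_seed(spec$seed, 100 + mi), foreground = fg)
    fields[[m]] <- b$field
    wm_mean <- spec$means["Wm", m]
    scans[[m]] <- lapply(seq_len(spec$repeats), function(r) {
      add_noise(b$volume, spec$pn, wm_mean,
                seed = sub_seed(spec$seed, 1000 * mi + r))
    })
  }
  atlas <- make_prior_atlas(labels, spec$prior_blur, spec$prior_offset,
                            config)
  list(session = image_session(scans), labels = labels, clean = clean,
       fields = fields, atlas = atlas, config = config)
}
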