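# Registration: rigid / affine transforms in physical (mm) coordinates,
# pull-back resampling, multi-resolution mutual-information optimization,
# and the plug-in contract for an external deformable engine.
#
# Convention: a transform maps FIXED (target) physical points to MOVING
# physical points, so resampling is a pull-back — for every target voxel we
# look up where it came from in the moving image.

#' Construct a spatial transform
#'
#' @param kind `"rigid"`, `"affine"` or `"displacement"`.
#' @param A 3 x 3 matrix part (rigid: orthonormal).
#' @param t length-3 translation (mm).
#' @param disp for `kind = "displacement"`: list of three arrays
#'   (`dx`, `dy`, `dz`, mm) sampled on the fixed grid.
#' @param grid grid metadata (`dim`, `spacing`, `origin`) of the fixed grid
#'   for displacement fields.
#' @export
spatial_transform <- function(kind = c("rigid", "affine", "displacement"),
                              A = diag(3), t = c(0, 0, 0), disp = NULL,
                              grid = NULL) {
  kind <- match.arg(kind)
  A <- as.matrix(A); t <- as.numeric(t)
  stopifnot(all(dim(A) == c(3L, 3L)), length(t) == 3L)
  if (kind == "rigid" &&
      max(abs(crossprod(A) - diag(3))) > 1e-6)
    stop("rigid matrix is not orthonormal")
  if (kind == "affine" && abs(det(A)) < 1e-12)
    stop("affine matrix is not invertible")
  if (kind == "displacement") {
    stopifnot(!is.null(disp), length(disp) == 3L, !is.null(grid))
    if (any(!vapply(disp, function(d) all(is.finite(d)), TRUE)))
      stop("displacement field contains non-finite values")
  }
  structure(list(kind = kind, A = A, t = t, disp = disp, grid = grid),
            class = "spatial_transform")
}

#' Identity transform
#' @export
transform_identity <- function() spatial_transform("rigid")

#' Rigid transform from 6 parameters about a rotation center
#'
#' `par = (tx, ty, tz, rx, ry, rz)`: translation in mm, Euler rotations in
#' radians applied as `Rz Ry Rx` about `center`.
#' @param par numeric length 6.
#' @param center rotation center (mm).
#' @export
rigid_from_params <- function(par, center = c(0, 0, 0)) {
  cx <- cos(par[4L]); sx <- sin(par[4L])
  cy <- cos(par[5L]); sy <- sin(par[5L])
  cz <- cos(par[6L]); sz <- sin(par[6L])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  R <- Rz %*% Ry %*% Rx
  spatial_transform("rigid", R,
                    as.numeric(center - R %*% center) + par[1:3])
}

#' Affine transform from 12 parameters about a center
#'
#' `par = (vec(P), u)`: matrix part `I + P` (column-major 9 values) and
#' translation `u`, applied about `center`.
#' @inheritParams rigid_from_params
#' @export
affine_from_params <- function(par, center = c(0, 0, 0)) {
  A <- diag(3) + matrix(par[1:9], 3L, 3L)
  spatial_transform("affine", A,
                    as.numeric(center - A %*% center) + par[10:12])
}

#' Apply a transform to physical points
#' @param tf a [spatial_transform()].
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(pts, ncol = 3L)
  out <- pts %*% t(tf$A) + matrix(tf$t, nrow(pts), 3L, byrow = TRUE)
  if (tf$kind == "displacement") {
    # displacement is sampled per fixed-grid voxel; pts must enumerate that
    # grid in column-major order
    stopifnot(nrow(pts) == prod(tf$grid$dim))
    out <- out + cbind(as.numeric(tf$disp[[1L]]), as.numeric(tf$disp[[2L]]),
                       as.numeric(tf$disp[[3L]]))
  }
  out
}

#' Compose two matrix transforms
#'
#' Returns the transform `p -> outer(inner(p))`; rigid composed with rigid
#' stays rigid.
#' @param outer,inner matrix-kind [spatial_transform()]s.
#' @export
compose_transforms <- function(outer, inner) {
  if (outer$kind == "displacement" || inner$kind == "displacement")
    stop("cannot compose displacement-field transforms")
  kind <- if (outer$kind == "rigid" && inner$kind == "rigid") "rigid"
          else "affine"
  spatial_transform(kind, outer$A %*% inner$A,
                    as.numeric(outer$A %*% inner$t) + outer$t)
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform:%s>\n", x$kind))
  m <- rbind(cbind(x$A, x$t), c(0, 0, 0, 1))
  print(round(m, 5))
  invisible(x)
}

#' Serialize / read a matrix transform as a plain-text 4 x 4 matrix
#' @param tf a matrix-kind [spatial_transform()].
#' @param path output path.
#' @export
write_transform <- function(tf, path) {
  stopifnot(tf$kind != "displacement")
  m <- rbind(cbind(tf$A, tf$t), c(0, 0, 0, 1))
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @param kind transform kind to tag the matrix with.
#' @export
read_transform <- function(path, kind = "affine") {
  m <- unname(as.matrix(utils::read.table(path)))
  spatial_transform(kind, m[1:3, 1:3], m[1:3, 4L])
}

grid_of <- function(vol) list(dim = dim(vol$data), spacing = vol$spacing,
                              origin = vol$origin)

# physical coordinates of every voxel center of a grid, column-major
grid_points <- function(grid) {
  d <- grid$dim
  idx <- cbind(
    rep(seq_len(d[1L]) - 1, times = d[2L] * d[3L]),
    rep(rep(seq_len(d[2L]) - 1, each = d[1L]), times = d[3L]),
    rep(seq_len(d[3L]) - 1, each = d[1L] * d[2L]))
  sweep(idx %*% diag(grid$spacing), 2L, grid$origin, "+")
}

#' Resample a volume through a transform (pull-back)
#'
#' For every voxel of the target grid, the transform gives the
#' corresponding moving-image position; the value there is interpolated
#' (`"linear"` for intensities and priors, `"nearest"` for labels).
#' Out-of-domain voxels get 0.  The in-domain mask is attached as
#' attribute `"valid"`.
#'
#' @param vol moving [mri_volume()].
#' @param tf [spatial_transform()] mapping target physical points to
#'   moving physical points.
#' @param target target grid: an `mri_volume`, `image_session` or a list
#'   with `dim`, `spacing`, `origin` (default: the moving grid).
#' @param interpolation `"linear"` or `"nearest"`.
#' @export
resample <- function(vol, tf, target = NULL,
                     interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  grid <- if (is.null(target)) grid_of(vol)
          else if (inherits(target, "mri_volume")) grid_of(target)
          else target
  pts <- grid_points(grid)
  q <- transform_points(tf, pts)
  cont <- sweep(q, 2L, vol$origin, "-") %*% diag(1 / vol$spacing)
  d <- dim(vol$data)
  vals <- interp3(vol$data, cont, interpolation)
  arr <- array(vals$v, grid$dim)
  is_lab <- inherits(vol, "label_volume")
  out <- if (is_lab) {
    labs <- vol$labels
    if (!0L %in% labs) labs <- c(labs, outside = 0L)
    label_volume(array(as.integer(round(arr)), grid$dim), labs,
                 grid$spacing, grid$origin)
  } else {
    mri_volume(arr, grid$spacing, grid$origin)
  }
  attr(out, "valid") <- array(vals$valid, grid$dim)
  out
}

# trilinear / nearest interpolation at continuous 0-based voxel coords
interp3 <- function(arr, cont, interpolation) {
  d <- dim(arr)
  eps <- 1e-9
  valid <- cont[, 1L] >= -eps & cont[, 1L] <= d[1L] - 1 + eps &
    cont[, 2L] >= -eps & cont[, 2L] <= d[2L] - 1 + eps &
    cont[, 3L] >= -eps & cont[, 3L] <= d[3L] - 1 + eps
  v <- numeric(nrow(cont))
  if (any(valid)) {
    cx <- pmin(pmax(cont[valid, 1L], 0), d[1L] - 1)
    cy <- pmin(pmax(cont[valid, 2L], 0), d[2L] - 1)
    cz <- pmin(pmax(cont[valid, 3L], 0), d[3L] - 1)
    if (interpolation == "nearest") {
      lin <- round(cx) + d[1L] * round(cy) + d[1L] * d[2L] * round(cz) + 1
      v[valid] <- arr[lin]
    } else {
      i0 <- pmin(floor(cx), d[1L] - 2); i0 <- pmax(i0, 0)
      j0 <- pmin(floor(cy), d[2L] - 2); j0 <- pmax(j0, 0)
      k0 <- pmin(floor(cz), d[3L] - 2); k0 <- pmax(k0, 0)
      if (d[1L] == 1L) i0 <- rep(0, length(cx))
      if (d[2L] == 1L) j0 <- rep(0, length(cy))
      if (d[3L] == 1L) k0 <- rep(0, length(cz))
      fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
      n1 <- d[1L]; n12 <- d[1L] * d[2L]
      base <- i0 + n1 * j0 + n12 * k0 + 1
      sx <- if (d[1L] > 1L) 1L else 0L
      sy <- if (d[2L] > 1L) n1 else 0L
      sz <- if (d[3L] > 1L) n12 else 0L
      acc <-
        arr[base] * (1 - fx) * (1 - fy) * (1 - fz) +
        arr[base + sx] * fx * (1 - fy) * (1 - fz) +
        arr[base + sy] * (1 - fx) * fy * (1 - fz) +
        arr[base + sx + sy] * fx * fy * (1 - fz) +
        arr[base + sz] * (1 - fx) * (1 - fy) * fz +
        arr[base + sx + sz] * fx * (1 - fy) * fz +
        arr[base + sy + sz] * (1 - fx) * fy * fz +
        arr[base + sx + sy + sz] * fx * fy * fz
      v[valid] <- acc
    }
  }
  list(v = v, valid = valid)
}

#' Resample a prior atlas onto a subject grid
#'
#' Linear interpolation per class, negatives clipped to 0, then per-voxel
#' renormalization wherever the class sum is positive.
#'
#' @param atlas a [prior_atlas()].
#' @param tf transform mapping subject physical points to atlas points.
#' @param target target grid (see [resample()]).
#' @return a warped [prior_atlas()].
#' @export
resample_atlas <- function(atlas, tf, target) {
  priors <- lapply(atlas$priors, function(v) {
    r <- resample(v, tf, target, "linear")
    r$data[r$data < 0] <- 0
    r
  })
  tot <- Reduce(`+`, lapply(priors, function(v) v$data))
  pos <- tot > 0
  priors <- lapply(priors, function(v) {
    v$data[pos] <- v$data[pos] / tot[pos]
    v
  })
  names(priors) <- atlas$config$name
  prior_atlas(atlas$config, priors, warped = TRUE)
}

# Gaussian-blur + decimate pyramid level
downsample_volume <- function(vol, factor) {
  if (factor <= 1L) return(vol)
  arr <- gaussian_blur3d(vol$data, factor / 2)
  d <- dim(arr)
  ix <- lapply(d, function(n) seq(1L, n, by = factor))
  mri_volume(arr[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE],
             vol$spacing * factor, vol$origin)
}

# negative mutual information between fixed values and resampled moving
neg_mutual_information <- function(fv, mv, valid, bins = 32L) {
  fv <- fv[valid]; mv <- mv[valid]
  if (length(fv) < 10L) return(0)
  rf <- range(fv); rm_ <- range(mv)
  if (diff(rf) == 0 || diff(rm_) == 0) return(0)
  bi <- pmin(bins, 1L + floor((fv - rf[1L]) / diff(rf) * bins))
  bj <- pmin(bins, 1L + floor((mv - rm_[1L]) / diff(rm_) * bins))
  joint <- tabulate(bi + bins * (bj - 1L), nbins = bins * bins)
  pj <- joint / sum(joint)
  pi_ <- rowSums(matrix(pj, bins))
  pk <- colSums(matrix(pj, bins))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  -(ent(pi_) + ent(pk) - ent(pj))
}

# The similarity is evaluated on a sub-voxel-jittered copy of the fixed
# grid: sampling both images off-grid removes the interpolation artifact
# that makes grid-aligned (e.g. identity) transforms spuriously sharp in a
# histogram metric and traps the optimizer there.
metric_value <- function(fixed_vals, moving, tf, grid, metric, bins) {
  r <- resample(moving, tf, grid, "linear")
  valid <- as.logical(attr(r, "valid"))
  if (metric == "mi") {
    neg_mutual_information(fixed_vals, as.numeric(r$data), valid, bins)
  } else {
    if (!any(valid)) return(Inf)
    mean((fixed_vals[valid] - r$data[valid])^2)
  }
}

jittered_grid <- function(vol, frac = 0.37) {
  g <- grid_of(vol)
  g$origin <- g$origin + frac * g$spacing
  g$dim <- pmax(g$dim - 1L, 1L)
  g
}

register_matrix <- function(fixed, moving, kind, init_par = NULL,
                            metric = "mi", bins = 32L,
                            levels = c(4L, 2L, 1L), maxit = 400L) {
  center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
  npar <- if (kind == "rigid") 6L else 12L
  par <- if (is.null(init_par)) numeric(npar) else init_par
  make_tf <- function(p) if (kind == "rigid") rigid_from_params(p, center)
                         else affine_from_params(p, center)
  # optimize in scaled units so Nelder-Mead's default 0.1 initial step is
  # ~0.4 voxel of translation / ~0.9 degree of rotation / 2% of scale
  sc <- if (kind == "rigid") c(rep(mean(fixed$spacing) * 4, 3L), rep(0.15, 3L))
        else c(rep(0.2, 9L), rep(mean(fixed$spacing) * 4, 3L))
  tr_idx <- if (kind == "rigid") 1:3 else 10:12
  final_value <- NA_real_
  first_level <- TRUE
  for (f in levels) {
    if (min(dim(fixed$data)) / f < 12) next
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    grid <- jittered_grid(fx)
    fixed_vals <- as.numeric(resample(fx, transform_identity(), grid)$data)
    # keep the joint histogram populated: ~bins^2 cells need >> samples
    bins_lvl <- max(8L, min(bins, as.integer(round(prod(grid$dim)^(1 / 3)))))
    obj <- function(q) metric_value(fixed_vals, mv, make_tf(q * sc), grid,
                                    metric, bins_lvl)
    if (first_level && is.null(init_par)) {
      # coarse exhaustive translation search for capture range
      steps <- mean(fixed$spacing) * c(-8, -4, 0, 4, 8)
      best <- obj(par / sc)
      for (tx in steps) for (ty in steps) for (tz in steps) {
        cand <- par
        cand[tr_idx] <- c(tx, ty, tz)
        v <- obj(cand / sc)
        if (v < best) { best <- v; par <- cand }
      }
      first_level <- FALSE
    }
    q <- par / sc
    if (kind == "affine") {
      # stage 1: diagonal scale + translation only — Nelder-Mead is weak
      # in 12 dimensions, so recover the dominant degrees of freedom first
      sub <- c(1L, 5L, 9L, 10L, 11L, 12L)
      obj_sub <- function(qs) { qq <- q; qq[sub] <- qs; obj(qq) }
      os <- stats::optim(q[sub], obj_sub, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-9))
      q[sub] <- os$par
    }
    # restarted Nelder-Mead: a fresh simplex around the incumbent escapes
    # the premature shrinkage NM is prone to in >= 6 dimensions
    value <- Inf
    for (restart in 1:3) {
      opt <- stats::optim(q, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-9))
      improved <- !is.finite(value) ||
        opt$value < value - 1e-6 * abs(value)
      q <- opt$par
      value <- opt$value
      if (!improved) break
    }
    par <- q * sc
    final_value <- value
  }
  if (!is.finite(final_value))
    stop("registration optimizer diverged (final metric ", final_value, ")")
  tf <- make_tf(par)
  attr(tf, "metric_value") <- final_value
  attr(tf, "par") <- par
  tf
}

#' Rigid registration (6 degrees of freedom)
#'
#' Multi-resolution Nelder-Mead over translation + rotation, maximizing
#' mutual information (default) between the fixed image and the resampled
#' moving image.  Deterministic given its inputs.
#'
#' @param fixed,moving [mri_volume()]s with overlapping fields of view.
#' @param metric `"mi"` (mutual information) or `"mse"`.
#' @param bins histogram bins for MI.
#' @param levels pyramid decimation factors, coarse to fine.
#' @param maxit optimizer iterations per level.
#' @return a rigid [spatial_transform()] (fixed -> moving, mm) with the
#'   final metric value in attribute `"metric_value"`.
#' @export
register_rigid <- function(fixed, moving, metric = c("mi", "mse"),
                           bins = 32L, levels = c(4L, 2L, 1L),
                           maxit = 400L) {
  metric <- match.arg(metric)
  register_matrix(fixed, moving, "rigid", NULL, metric, bins, levels, maxit)
}

#' Affine registration (12 degrees of freedom)
#'
#' Runs at full resolution by default: coarse pyramid levels bias the
#' scale estimate in 12 dimensions, and capture range is supplied by the
#' rigid initialization (or the built-in translation search) instead.
#'
#' @inheritParams register_rigid
#' @param init initializing transform, typically from [register_rigid()].
#' @export
register_affine <- function(fixed, moving, init = NULL,
                            metric = c("mi", "mse"), bins = 32L,
                            levels = 1L, maxit = 600L) {
  metric <- match.arg(metric)
  init_par <- if (is.null(init)) NULL else {
    center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
    # convert absolute (A, t) into center-relative parameters
    c(as.numeric(init$A - diag(3)),
      as.numeric(init$t - center + init$A %*% center))
  }
  register_matrix(fixed, moving, "affine", init_par, metric, bins, levels,
                  maxit)
}

#' Deformable registration through an external plug-in
#'
#' The deformable engine itself (e.g. a SyN implementation) is external by
#' design.  The plug-in is an R function
#' `function(fixed, moving) -> list(dx, dy, dz)` returning per-voxel
#' displacements (mm) on the fixed grid.  When no plug-in is configured
#' the affine route is used instead, with a warning — degraded, never
#' fatal.
#'
#' @param fixed,moving [mri_volume()]s.
#' @param plugin plug-in callable, or `NULL`.
#' @param init optional initialization for the affine fallback.
#' @return a displacement-field [spatial_transform()], or an affine one
#'   flagged with attribute `"fallback" = TRUE`.
#' @export
deformable_backend <- function(fixed, moving, plugin = NULL, init = NULL) {
  if (is.null(plugin) || !is.function(plugin)) {
    warning("no deformable plug-in configured; falling back to affine ",
            "registration", call. = FALSE)
    tf <- register_affine(fixed, moving, init = init)
    attr(tf, "fallback") <- TRUE
    return(tf)
  }
  disp <- plugin(fixed, moving)
  if (!is.list(disp) || length(disp) != 3L)
    stop("plug-in must return a list of 3 displacement arrays")
  d <- dim(fixed$data)
  for (comp in disp) {
    if (!identical(dim(comp), d))
      stop("plug-in displacement grid does not match the fixed grid")
  }
  spatial_transform("displacement", disp = disp, grid = grid_of(fixed))
}

#' Fuse co-registered repeats by voxel-wise averaging
#'
#' Averaging k repeats reduces independent noise by a factor of sqrt(k).
#'
#' @param repeats a single [mri_volume()] or list of co-registered repeats.
#' @return an [mri_volume()].
#' @export
fuse_repeats <- function(repeats) {
  if (inherits(repeats, "mri_volume")) return(repeats)
  stopifnot(length(repeats) >= 1L)
  ref <- repeats[[1L]]
  if (length(repeats) == 1L) return(ref)
  for (v in repeats[-1L]) stopifnot_same_grid(ref, v, "repeats")
  acc <- Reduce(`+`, lapply(repeats, function(v) v$data))
  mri_volume(acc / length(repeats), ref$spacing, ref$origin)
}
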