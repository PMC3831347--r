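#' Create a 3-D scalar volume
#'
#' The basic container used throughout the package: a 3-D numeric array with
#' physical voxel spacing (mm) and the physical coordinate of voxel
#' `(0, 0, 0)` (0-based indexing convention; R arrays are addressed
#' `data[x + 1, y + 1, z + 1]`).  All modules operate in the native axis
#' order of the file the volume came from.
#'
#' @param data numeric 3-D array (a 4-D array with trailing singleton
#'   dimensions is squeezed).
#' @param spacing numeric length-3, per-axis voxel size in mm, all `> 0`.
#' @param origin numeric length-3, physical position of the first voxel.
#' @return object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- squeeze_to_3d(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop(sprintf("volume contains %d non-finite voxels", n_bad))
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_order = "native"),
            class = "mri_volume")
}

#' Create a labelled (integer code) volume
#'
#' @param data integer-valued 3-D array of class codes.
#' @param labels named integer vector mapping class name -> code; every code
#'   present in `data` must appear in the table.
#' @inheritParams mri_volume
#' @return object of class `label_volume` (also inherits `mri_volume`).
#' @export
label_volume <- function(data, labels, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  data <- squeeze_to_3d(data)
  if (any(!is.finite(data)) || any(data != round(data)))
    stop("label data must be finite integers")
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be a named integer vector (name -> code)")
  labels <- stats::setNames(as.integer(labels), names(labels))
  present <- sort(unique(as.integer(data)))
  missing <- setdiff(present, labels)
  if (length(missing) > 0L)
    stop("codes present in data but absent from label table: ",
         paste(missing, collapse = ", "))
  vol <- mri_volume(data, spacing, origin)
  vol$data <- array(as.integer(vol$data), dim(vol$data))
  vol$labels <- labels
  class(vol) <- c("label_volume", "mri_volume")
  vol
}

squeeze_to_3d <- function(data) {
  if (is.null(dim(data))) stop("data must be an array")
  d <- dim(data)
  if (length(d) > 3L) {
    if (any(d[-(1:3)] != 1L))
      stop(sprintf("payload is %d-D with non-singleton trailing dimensions",
                   length(d)))
    dim(data) <- d[1:3]
  } else if (length(d) < 3L) {
    stop("data must be a 3-D array")
  }
  data
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same voxel grid")
  invisible(TRUE)
}

#' Multi-modal, possibly repeated scan session
#'
#' Holds one or more repeats per modality, all on a common voxel grid.
#' Repeats are fused (voxel-wise mean) by [fuse_repeats()]; most downstream
#' code consumes the fused per-modality volumes via [session_matrix()].
#'
#' @param scans named list: modality name -> either a single `mri_volume` or
#'   a list of co-registered repeat `mri_volume`s.
#' @return object of class `image_session`.
#' @export
image_session <- function(scans) {
  if (length(scans) < 1L || is.null(names(scans)) || any(!nzchar(names(scans))))
    stop("scans must be a non-empty named list (modality -> volume(s))")
  scans <- lapply(scans, function(s) {
    if (inherits(s, "mri_volume")) list(s) else s
  })
  ref <- scans[[1L]][[1L]]
  for (m in names(scans)) {
    for (v in scans[[m]]) stopifnot_same_grid(ref, v, "session scans")
  }
  structure(list(scans = scans,
                 spacing = ref$spacing, origin = ref$origin,
                 dim = dim(ref$data)),
            class = "image_session")
}

#' @export
print.image_session <- function(x, ...) {
  reps <- vapply(x$scans, length, 1L)
  cat(sprintf("<image_session> %s voxels; %d modalities: %s\n",
              paste(x$dim, collapse = "x"), length(x$scans),
              paste(sprintf("%s (%d repeat%s)", names(reps), reps,
                            ifelse(reps > 1L, "s", "")), collapse = ", ")))
  invisible(x)
}

#' Modality names of a session
#' @param session an `image_session`.
#' @export
session_modalities <- function(session) names(session$scans)

#' Fused per-modality volumes of a session
#'
#' @param session an `image_session`.
#' @return named list of `mri_volume`, one per modality (repeats averaged).
#' @export
session_fused <- function(session) {
  lapply(session$scans, fuse_repeats)
}

#' Fused session intensities as an N x M matrix
#'
#' @param session an `image_session`.
#' @return numeric matrix, one row per voxel (column-major voxel order),
#'   one column per modality.
#' @export
session_matrix <- function(session) {
  fused <- session_fused(session)
  m <- vapply(fused, function(v) as.numeric(v$data),
              numeric(prod(session$dim)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(fused))
  colnames(m) <- names(fused)
  m
}

#' Rebuild a session from an intensity matrix
#'
#' Inverse of [session_matrix()] for a fused session: one repeat per
#' modality, grid metadata taken from `session`.
#' @param session template `image_session`.
#' @param mat numeric N x M matrix as returned by [session_matrix()].
#' @export
session_from_matrix <- function(session, mat) {
  stopifnot(nrow(mat) == prod(session$dim),
            ncol(mat) == length(session$scans))
  scans <- lapply(seq_len(ncol(mat)), function(j) {
    mri_volume(array(mat[, j], session$dim), session$spacing, session$origin)
  })
  names(scans) <- names(session$scans)
  image_session(scans)
}
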