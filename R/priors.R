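# Spatial tissue priors: the atlas container, weighted prior normalization,
# super-class collapse, and hard segmentation.
#
# Per-voxel class probabilities travel as a `prob_stack`: an N x K matrix
# (column-major voxel order, one column per tissue class) plus grid
# metadata.  Keeping the stack as a matrix makes every EM/prior operation a
# vectorized matrix expression.

#' Build a per-voxel class-probability stack
#'
#' @param p numeric N x K matrix, one column per class.
#' @param classes character class names (length K).
#' @param dim,spacing,origin grid metadata of the underlying volume.
#' @export
prob_stack <- function(p, classes, dim, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  p <- as.matrix(p)
  stopifnot(ncol(p) == length(classes), nrow(p) == prod(dim))
  colnames(p) <- classes
  structure(list(p = p, classes = classes, dim = dim,
                 spacing = spacing, origin = origin),
            class = "prob_stack")
}

#' @export
print.prob_stack <- function(x, ...) {
  cat(sprintf("<prob_stack> %s voxels x %d classes (%s)\n",
              paste(x$dim, collapse = "x"), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Extract one class of a stack as a volume
#' @param stack a `prob_stack`.
#' @param class class name or index.
#' @export
stack_volume <- function(stack, class) {
  j <- if (is.character(class)) match(class, stack$classes) else class
  if (is.na(j)) stop("unknown class: ", class)
  mri_volume(array(stack$p[, j], stack$dim), stack$spacing, stack$origin)
}

#' Prior atlas: per-class probability volumes plus the tissue configuration
#'
#' @param config a `tissue_config`; row order fixes class order and codes.
#' @param priors named list of `mri_volume`, one per config row, on a common
#'   grid; values must be nonnegative.
#' @param warped whether these priors already live on the subject grid
#'   (after registration) or on the atlas reference grid.
#' @export
prior_atlas <- function(config, priors, warped = FALSE) {
  stopifnot(inherits(config, "tissue_config"))
  if (!setequal(names(priors), config$name) ||
      length(priors) != nrow(config))
    stop("priors must be one volume per tissue config row")
  priors <- priors[config$name]
  ref <- priors[[1L]]
  for (v in priors) {
    stopifnot_same_grid(ref, v, "prior volumes")
    if (any(v$data < 0)) stop("prior probabilities must be nonnegative")
  }
  if (nrow(config) < 2L) stop("need at least 2 tissue classes")
  structure(list(config = config, priors = priors, warped = isTRUE(warped),
                 dim = dim(ref$data), spacing = ref$spacing,
                 origin = ref$origin),
            class = "prior_atlas")
}

#' @export
print.prior_atlas <- function(x, ...) {
  cat(sprintf("<prior_atlas> %d classes on %s grid (%s)\n",
              nrow(x$config), paste(x$dim, collapse = "x"),
              if (x$warped) "warped to subject" else "atlas space"))
  invisible(x)
}

#' Index of the deterministic fallback (background/Air) class
#' @keywords internal
background_class_index <- function(config) {
  i <- match("Air", config$name)
  if (!is.na(i)) return(i)
  i <- which(config$super_class == "Background")
  if (length(i) > 0L) return(i[1L])
  1L
}

#' Weighted spatial-prior normalization
#'
#' Computes `p(class l at voxel i) = w_l * t_il / sum_j w_j * t_ij`, the
#' weighted and renormalized atlas prior.  The per-class weight comes from
#' the tissue configuration (e.g. cerebellar WM is up-weighted 1.5x in the
#' packaged scheme).  Voxels where every weighted prior is zero carry no
#' spatial support for any tissue and are assigned the background/Air class
#' deterministically.
#'
#' @param atlas a [prior_atlas()].
#' @param use_warped use the warped (subject-space) priors; an error if the
#'   atlas is not warped.
#' @return a [prob_stack()]; attribute `n_degenerate` counts the
#'   zero-support voxels.
#' @export
normalize_priors <- function(atlas, use_warped = atlas$warped) {
  if (use_warped && !atlas$warped)
    stop("atlas priors are not warped to the subject grid")
  w <- atlas$config$weight
  n <- prod(atlas$dim)
  p <- matrix(0, n, nrow(atlas$config))
  for (j in seq_along(atlas$priors))
    p[, j] <- w[j] * as.numeric(atlas$priors[[j]]$data)
  tot <- rowSums(p)
  degenerate <- tot <= 0
  bg <- background_class_index(atlas$config)
  if (any(degenerate)) {
    p[degenerate, ] <- 0
    p[degenerate, bg] <- 1
    tot[degenerate] <- 1
  }
  p <- p / tot
  out <- prob_stack(p, atlas$config$name, atlas$dim, atlas$spacing,
                    atlas$origin)
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Collapse extended classes to super-classes
#'
#' Sums member-class probabilities into their super-class.  The
#' `"six-class"` scheme uses the configuration's own super-classes
#' (GM, WM, CSF, WM&GM, VB, Background).  The `"three-tissue"` scheme used
#' for evaluation maps WM&GM (deep gray: Thalamus, Globus) into GM and
#' pools VB with Background into an `Other` column so that the per-voxel
#' total probability is conserved; `Other` is excluded from evaluation.
#'
#' @param stack a [prob_stack()] whose classes match `config` rows.
#' @param config the `tissue_config` describing the stack's classes.
#' @param scheme `"six-class"` or `"three-tissue"`.
#' @return a collapsed [prob_stack()].
#' @export
collapse_to_superclass <- function(stack, config,
                                   scheme = c("three-tissue", "six-class")) {
  scheme <- match.arg(scheme)
  stopifnot(identical(stack$classes, config$name))
  if (scheme == "six-class") {
    groups <- split(seq_len(nrow(config)), config$super_class)
    groups <- groups[intersect(SUPER_CLASSES, names(groups))]
  } else {
    m <- three_tissue_members(config)
    for (need in c("GM", "WM", "CSF"))
      if (length(m[[need]]) == 0L)
        stop("three-tissue scheme needs super-class ", need)
    other <- setdiff(seq_len(nrow(config)), unlist(m))
    groups <- c(m, if (length(other) > 0L) list(Other = other))
  }
  p <- vapply(groups, function(idx) {
    if (length(idx) == 1L) stack$p[, idx] else rowSums(stack$p[, idx, drop = FALSE])
  }, numeric(nrow(stack$p)))
  prob_stack(p, names(groups), stack$dim, stack$spacing, stack$origin)
}

#' Hard (maximum a posteriori) segmentation of a probability stack
#'
#' Arg-max class per voxel; exact ties break to the lowest class index.
#' Codes are 0-based indices into the stack's class list.
#'
#' @param stack a [prob_stack()].
#' @return a [label_volume()].
#' @export
hard_segmentation <- function(stack) {
  idx <- max.col(stack$p, ties.method = "first")
  codes <- stats::setNames(seq_along(stack$classes) - 1L, stack$classes)
  label_volume(array(idx - 1L, stack$dim), codes, stack$spacing,
               stack$origin)
}

#' One-hot probability stack from a label volume
#' @param labels a [label_volume()].
#' @param classes optional class order (names of `labels$labels` by default).
#' @export
one_hot_stack <- function(labels, classes = names(labels$labels)) {
  codes <- labels$labels[classes]
  p <- vapply(codes, function(code) as.numeric(labels$data == code),
              numeric(length(labels$data)))
  prob_stack(p, classes, dim(labels$data), labels$spacing, labels$origin)
}
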