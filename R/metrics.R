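# Ground-truth agreement metrics: Dice overlap and the modified (average)
# Hausdorff boundary distance, plus the factorial phantom evaluation grid.

as_mask <- function(x) {
  if (inherits(x, "mri_volume")) x$data != 0 else x != 0
}

#' Dice overlap index
#'
#' `2|A n B| / (|A| + |B|)` between two binary volumes on the same grid.
#' Both masks empty counts as perfect agreement on absence (Dice 1,
#' reported via a message).
#'
#' @param a,b binary [mri_volume()]s or logical/numeric arrays.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ma <- as_mask(a); mb <- as_mask(b)
  stopifnot(identical(dim(ma), dim(mb)))
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) {
    message("dice: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(ma & mb) / (na + nb)
}

# boundary voxels: in mask with >= 1 face-adjacent neighbour outside
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- function(off) {
    shift_array(mask * 1, off, fill = 0) > 0
  }
  interior <- mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & pad(off)
  which(mask & !interior, arr.ind = TRUE)
}

# mean over rows of `a` of the distance to the nearest row of `b` (mm)
directed_mean_distance <- function(a, b, spacing, chunk = 512L) {
  a <- sweep(a - 1, 2L, spacing, "*")
  b <- sweep(b - 1, 2L, spacing, "*")
  b2 <- rowSums(b^2)
  total <- 0
  for (start in seq(1L, nrow(a), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(a))
    aa <- a[rows, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), b2, "+") - 2 * aa %*% t(b)
    total <- total + sum(sqrt(pmax(apply(d2, 1L, min), 0)))
  }
  total / nrow(a)
}

#' Average (modified) Hausdorff distance between segmentation boundaries
#'
#' Dubuisson's modified Hausdorff distance: boundary voxel sets are
#' extracted (face adjacency), each direction contributes the mean
#' nearest-boundary distance in physical mm, and the larger of the two
#' directed means is returned.  `variant = "mean"` averages the two
#' directed means instead.
#'
#' @param a,b binary [mri_volume()]s or arrays; both must be nonempty.
#' @param spacing voxel spacing in mm (taken from `a` when it is a
#'   volume).
#' @param variant `"max"` (Dubuisson, default) or `"mean"`.
#' @return distance in mm; 0 iff the boundaries coincide.
#' @export
average_hausdorff <- function(a, b, spacing = NULL,
                              variant = c("max", "mean")) {
  variant <- match.arg(variant)
  if (is.null(spacing))
    spacing <- if (inherits(a, "mri_volume")) a$spacing else c(1, 1, 1)
  ma <- as_mask(a); mb <- as_mask(b)
  stopifnot(identical(dim(ma), dim(mb)))
  if (sum(ma) == 0L || sum(mb) == 0L)
    stop("average_hausdorff is undefined for an empty mask")
  ba <- boundary_voxels(ma)
  bb <- boundary_voxels(mb)
  dab <- directed_mean_distance(ba, bb, spacing)
  dba <- directed_mean_distance(bb, ba, spacing)
  if (variant == "max") max(dab, dba) else (dab + dba) / 2
}

#' Score a segmentation against three-tissue ground truth
#'
#' Collapses the posterior stack to the three-tissue scheme, takes the
#' hard segmentation, and reports Dice and modified Hausdorff distance per
#' tissue against the ground-truth labels (collapsed the same way).
#'
#' @param posteriors final [prob_stack()] over the extended classes.
#' @param config the `tissue_config` of the stack.
#' @param truth_labels ground-truth [label_volume()] over the same
#'   extended classes.
#' @return data.frame with one row per tissue (GM, WM, CSF).
#' @export
score_three_tissue <- function(posteriors, config, truth_labels) {
  coll <- collapse_to_superclass(posteriors, config, "three-tissue")
  seg <- hard_segmentation(coll)
  truth_stack <- one_hot_stack(truth_labels, classes = config$name)
  truth_coll <- hard_segmentation(
    collapse_to_superclass(truth_stack, config, "three-tissue"))
  tissues <- c("GM", "WM", "CSF")
  res <- lapply(tissues, function(ts) {
    code <- seg$labels[[ts]]
    a <- seg$data == code
    b <- truth_coll$data == code
    data.frame(tissue = ts,
               dice = dice(a, b),
               mhd = if (sum(a) > 0L && sum(b) > 0L)
                 average_hausdorff(a, b, truth_labels$spacing) else NA_real_,
               n_seg = sum(a), n_truth = sum(b))
  })
  do.call(rbind, res)
}

#' Run the factorial phantom evaluation grid
#'
#' For every combination of bias amplitude `rf`, noise level `pn`,
#' context-prior setting and prior misregistration offset, generates a
#' phantom session, runs the pipeline (priors used as supplied — the
#' aligned/offset contrast emulates registration quality), and scores
#' three-tissue Dice and modified Hausdorff distance against ground truth.
#'
#' @param base_spec a [phantom_spec()] used as the template for every cell.
#' @param rf_levels bias amplitudes (percent).
#' @param noise_levels noise percentages.
#' @param context context-prior settings to cross (logical vector).
#' @param offsets list of prior offsets (voxel triples) to cross.
#' @param seeds one phantom per seed per cell.
#' @param config pipeline [run_config()] template (registration is forced
#'   to `"none"`; seeds are overridden per cell).
#' @return tidy data.frame: one row per tissue x cell x seed.
#' @export
run_grid <- function(base_spec = phantom_spec(n = 32),
                     rf_levels = c(20, 40),
                     noise_levels = c(1, 5, 9),
                     context = c(TRUE, FALSE),
                     offsets = list(c(0, 0, 0)),
                     seeds = 1:5,
                     config = run_config(max_outer_iter = 2L,
                                         em_max_iter = 15L)) {
  config$registration <- "none"
  rows <- list()
  for (rf in rf_levels) for (pn in noise_levels) for (off in offsets)
    for (ctx in context) for (sd in seeds) {
      spec <- base_spec
      spec$rf <- rf; spec$pn <- pn
      spec$prior_offset <- rep_len(as.integer(off), 3L)
      spec$seed <- as.integer(sd)
      ph <- generate_phantom_session(spec)
      cfg <- config
      cfg$use_context_prior <- ctx
      cfg$seed <- as.integer(sd)
      cfg$modalities <- names(spec$means)
      res <- run_pipeline(ph$session, ph$atlas, cfg)
      sc <- score_three_tissue(res$posteriors, ph$config, ph$labels)
      sc$rf <- rf; sc$pn <- pn
      sc$offset <- paste(spec$prior_offset, collapse = ",")
      sc$context <- ctx; sc$seed <- sd
      rows[[length(rows) + 1L]] <- sc
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
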