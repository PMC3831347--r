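SUPER_CLASSES <- c("GM", "WM", "CSF", "WM&GM", "VB", "Background")

#' Load a tissue configuration table
#'
#' The tissue configuration drives the whole classifier: one row per tissue
#' class with its super-class (hierarchy), prior weight, whether the class
#' participates in bias-field estimation, and per-modality quantile bounds
#' for the intensity-context prior.  The file is tab-separated text with
#' columns `name`, `super_class`, `weight`, `use_in_bias` and one
#' `q_lower.<MOD>` / `q_upper.<MOD>` pair per modality.
#'
#' The packaged default (`default_tissue_config()`) is the 17-class extended
#' scheme: 12 biological classes plus 5 background "Not-tissue" nuisance
#' classes, with conservatively chosen T1/T2 quantile bounds.
#'
#' @param path path to a tissue configuration TSV.
#' @return a `tissue_config` data.frame with attribute `modalities`.
#' @export
load_tissue_config <- function(path) {
  if (!file.exists(path)) stop("tissue config file does not exist: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_tissue_config(df)
}

validate_tissue_config <- function(df) {
  req <- c("name", "super_class", "weight", "use_in_bias")
  if (!all(req %in% names(df)))
    stop("tissue config must have columns: ", paste(req, collapse = ", "))
  qcols <- grep("^q_(lower|upper)\\.", names(df), value = TRUE)
  mods <- unique(sub("^q_(lower|upper)\\.", "", qcols))
  if (length(mods) < 1L) stop("tissue config has no quantile-bound columns")
  for (m in mods) {
    lo <- df[[paste0("q_lower.", m)]]
    hi <- df[[paste0("q_upper.", m)]]
    if (is.null(lo) || is.null(hi))
      stop("incomplete quantile bound pair for modality ", m)
    if (any(lo < 0 | hi > 1))
      stop("quantile bounds must lie in [0, 1] (modality ", m, ")")
    bad <- which(lo > hi)
    if (length(bad) > 0L)
      stop(sprintf("q_lower > q_upper for tissue '%s', modality %s",
                   df$name[bad[1L]], m))
  }
  if (anyDuplicated(df$name))
    stop("duplicate tissue name: ",
         df$name[duplicated(df$name)][1L])
  unknown <- setdiff(df$super_class, SUPER_CLASSES)
  if (length(unknown) > 0L)
    stop("unknown super-class: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(df$weight) | df$weight <= 0))
    stop("weights must be positive")
  df$use_in_bias <- as.logical(df$use_in_bias)
  if (any(is.na(df$use_in_bias))) stop("use_in_bias must be TRUE/FALSE")
  attr(df, "modalities") <- mods
  class(df) <- c("tissue_config", "data.frame")
  df
}

#' Quantile bounds of one tissue row for one modality
#' @param config a `tissue_config`.
#' @param tissue tissue name.
#' @param modality modality name.
#' @return numeric `c(q_lower, q_upper)`.
#' @export
tissue_quantiles <- function(config, tissue, modality) {
  i <- match(tissue, config$name)
  if (is.na(i)) stop("unknown tissue: ", tissue)
  lo <- config[[paste0("q_lower.", modality)]]
  hi <- config[[paste0("q_upper.", modality)]]
  if (is.null(lo)) stop("no quantile bounds for modality: ", modality)
  c(lo[i], hi[i])
}

#' The packaged 17-class extended tissue configuration
#'
#' T1w/T2w quantile bounds, weights and bias-eligibility for the extended
#' prior scheme (cortical and subcortical GM split into Accumben, Caudate,
#' cerebellar GM, Hippocampus, Putamen and surface GM; WM split into
#' cerebral and cerebellar WM; mixed WM&GM deep-gray classes Thalamus and
#' Globus; venous blood; plus five "Not-tissue"/Air background classes).
#'
#' @return a `tissue_config` data.frame (17 rows).
#' @export
default_tissue_config <- function() {
  load_tissue_config(system.file("extdata", "tissue_config_17.tsv",
                                 package = "emtseg", mustWork = TRUE))
}

#' Minimal 4-class tissue configuration matching the synthetic phantom
#'
#' Air / CSF / GM / WM with conservative T1/T2 quantile bounds; used by the
#' phantom-driven tests and the evaluation grid.
#' @return a `tissue_config` data.frame (4 rows).
#' @export
phantom_tissue_config <- function() {
  load_tissue_config(system.file("extdata", "tissue_config_phantom.tsv",
                                 package = "emtseg", mustWork = TRUE))
}

#' Three-tissue collapse membership used for evaluation
#'
#' Maps extended classes onto \{GM, WM, CSF\} for comparison against a
#' three-tissue ground truth: the GM block plus the deep-gray WM&GM classes
#' (Thalamus, Globus) count as GM, following the BrainWeb convention of
#' assigning deep gray to GM; VB and Background classes are excluded.
#'
#' @param config a `tissue_config`.
#' @return named list of integer class-index vectors for `GM`, `WM`, `CSF`.
#' @export
three_tissue_members <- function(config) {
  list(GM = which(config$super_class %in% c("GM", "WM&GM")),
       WM = which(config$super_class == "WM"),
       CSF = which(config$super_class == "CSF"))
}

#' Run configuration
#'
#' Plumbing knobs for the pipeline; every run logs its seed.
#'
#' @param modalities character vector of modality names, in order.
#' @param max_outer_iter outer-loop iterations (posterior estimation, bias
#'   correction, registration update), `>= 1`.
#' @param em_max_iter,em_tol inner EM iteration cap and relative
#'   log-likelihood tolerance.
#' @param outer_tol outer-loop relative log-likelihood tolerance.
#' @param bias_order polynomial order of the bias-field basis.
#' @param mask_threshold summed non-background warped-prior threshold
#'   defining the quantile-histogram mask.
#' @param registration one of `"none"`, `"affine"`, `"plugin"`.
#' @param use_context_prior apply the intensity-context constraint.
#' @param seed integer random seed, recorded in every log.
#' @param out_dir output directory (`NULL` = no files written).
#' @export
run_config <- function(modalities = c("T1", "T2"),
                       max_outer_iter = 5L,
                       em_max_iter = 30L, em_tol = 1e-5,
                       outer_tol = 1e-4,
                       bias_order = 4L,
                       mask_threshold = 0.5,
                       registration = c("affine", "none", "plugin"),
                       use_context_prior = TRUE,
                       seed = 1L, out_dir = NULL) {
  registration <- match.arg(registration)
  stopifnot(max_outer_iter >= 1L, em_max_iter >= 1L,
            em_tol > 0, outer_tol > 0, bias_order >= 0L,
            mask_threshold >= 0)
  structure(list(modalities = modalities,
                 max_outer_iter = as.integer(max_outer_iter),
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 outer_tol = outer_tol, bias_order = as.integer(bias_order),
                 mask_threshold = mask_threshold,
                 registration = registration,
                 use_context_prior = isTRUE(use_context_prior),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}
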