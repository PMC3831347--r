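# The outer loop: intra-session alignment and fusion, atlas-to-subject
# registration, then iterated posterior estimation (EM with context-
# constrained warped priors), bias correction, and registration update.

#' Run the full iterative segmentation pipeline
#'
#' Stages: (1) optional rigid alignment of every scan to the first scan
#' and voxel-wise fusion of repeats; (2) atlas-to-subject registration
#' (affine or deformable plug-in; skipped when the atlas is already
#' warped); (3) the outer loop — recompute quantile bounds on the current
#' bias-corrected images, constrain the warped spatial priors with the
#' intensity-context indicators, run EM, estimate and accumulate the
#' per-modality polynomial bias field in log-intensity space, optionally
#' re-register the atlas to the corrected reference image — until the
#' relative outer log-likelihood change falls below `config$outer_tol` or
#' `config$max_outer_iter` is reached; (4) a final E-step on the fully
#' corrected images.
#'
#' @param session an [image_session()] (any modalities, any repeats).
#' @param atlas a [prior_atlas()]; either already warped to the subject
#'   grid or accompanied by `atlas_template` for registration.
#' @param config a [run_config()].
#' @param atlas_template reference [mri_volume()] in atlas space (required
#'   when `config$registration != "none"` and the atlas is unwarped).
#' @param plugin deformable plug-in for [deformable_backend()].
#' @param align_scans rigid-align all scans to the first scan before
#'   fusion (default `FALSE`: synthetic and pre-aligned sessions).
#' @return list with `posteriors`, `state`, `labels` (extended hard
#'   segmentation), `labels_three`, `corrected` (linear-space fused
#'   session), `bias` ([bias_field()], log space, accumulated), `atlas`
#'   (warped), `transform`, `mask`, `bounds`, `trace` (per-outer-iteration
#'   data.frame), `log` (character), and `config`.
#' @export
run_pipeline <- function(session, atlas, config = run_config(),
                         atlas_template = NULL, plugin = NULL,
                         align_scans = FALSE) {
  lg <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    lg <<- c(lg, msg)
    message("[emtseg] ", msg)
  }
  say("seed=%d modalities=%s registration=%s context=%s",
      config$seed, paste(session_modalities(session), collapse = "+"),
      config$registration, config$use_context_prior)

  stage <- "intra-session alignment"
  out <- tryCatch({
    if (align_scans) session <- align_session(session)
    fused <- session_fused(session)
    fused_session <- image_session(lapply(fused, list))
    mods <- session_modalities(fused_session)
    ref_img <- fused[[1L]]

    stage <- "atlas-to-subject registration"
    tf <- NULL
    if (config$registration == "none") {
      if (!atlas$warped)
        stop("registration = 'none' requires an already-warped atlas")
      warped <- atlas
    } else if (atlas$warped) {
      say("atlas already warped; skipping initial registration")
      warped <- atlas
    } else {
      if (is.null(atlas_template))
        stop("unwarped atlas requires an atlas_template image")
      tf0 <- register_rigid(ref_img, atlas_template)
      tf <- if (config$registration == "plugin")
        deformable_backend(ref_img, atlas_template, plugin, init = tf0)
      else register_affine(ref_img, atlas_template, init = tf0)
      warped <- resample_atlas(atlas, tf, ref_img)
      say("atlas warped (%s)", config$registration)
    }

    stage <- "working-space transform"
    mask <- quantile_mask(warped, config$mask_threshold)
    if (!any(mask)) stop("empty quantile mask")
    ws <- list()
    eps <- numeric(0)
    for (m in mods) {
      w <- to_working_space(fused[[m]], mask = mask)
      eps[[m]] <- attr(w, "eps")
      ws[[m]] <- w
    }
    ws_session <- image_session(lapply(ws, list))
    basis <- poly_basis(fused_session$dim, config$bias_order)
    phi <- lapply(mods, function(m) numeric(prod(fused_session$dim)))
    names(phi) <- mods

    state <- NULL
    trace <- list()
    prev_ll <- NULL
    bounds <- NULL
    priors_c <- NULL
    for (outer in seq_len(config$max_outer_iter)) {
      stage <- sprintf("outer iteration %d: posterior estimation", outer)
      corrected_ws <- apply_phi(ws_session, phi)
      bounds <- compute_bounds(corrected_ws, warped$config, mask)
      sp <- normalize_priors(warped)
      n_fb <- 0L
      if (config$use_context_prior) {
        ind <- indicator_stack(corrected_ws, bounds)
        # background/Air classes are exempt from the constraint: their job
        # is to absorb non-tissue voxels, and removing them from the
        # denominator would hand air voxels wholesale to whichever tissue
        # interval happens to reach lowest
        ind[, warped$config$super_class == "Background"] <- 1
        priors_c <- constrain_priors(sp, ind)
        n_fb <- attr(priors_c, "n_fallback")
      } else priors_c <- sp
      if (is.null(state)) state <- initialize_state(corrected_ws, priors_c)
      em <- run_em(corrected_ws, state, priors_c,
                   max_iter = config$em_max_iter, tol = config$em_tol)
      state <- em$state
      ll <- em$trace[length(em$trace)]

      stage <- sprintf("outer iteration %d: bias correction", outer)
      bf <- estimate_bias(corrected_ws, state, em$posteriors,
                          warped$config, config$bias_order, mask,
                          basis = basis)
      for (m in mods) phi[[m]] <- phi[[m]] + bf$fields[[m]]
      max_phi <- max(vapply(bf$fields, function(f) max(abs(f[mask])), 0))

      stage <- sprintf("outer iteration %d: registration update", outer)
      if (config$registration != "none" && !is.null(tf) &&
          tf$kind != "displacement") {
        corr_lin <- from_working_space(
          session_fused(apply_phi(ws_session, phi))[[1L]], eps[[1L]])
        tf <- register_affine(corr_lin, atlas_template, init = tf,
                              maxit = 200L)
        warped <- resample_atlas(atlas, tf, ref_img)
        mask <- quantile_mask(warped, config$mask_threshold)
      }

      trace[[outer]] <- data.frame(outer = outer,
                                   em_iters = length(em$trace),
                                   loglik = ll, n_fallback = n_fb,
                                   max_bias_update = max_phi)
      say("outer %d: loglik=%.4f em_iters=%d fallback_voxels=%d |dPhi|=%.4g",
          outer, ll, length(em$trace), n_fb, max_phi)
      if (!is.null(prev_ll)) {
        rel <- abs(ll - prev_ll) / max(abs(prev_ll), .Machine$double.eps)
        if (rel < config$outer_tol) { say("outer loop converged"); break }
      }
      prev_ll <- ll
    }

    stage <- "final posterior estimation"
    corrected_ws <- apply_phi(ws_session, phi)
    final <- e_step(corrected_ws, state, priors_c)
    corrected_lin <- lapply(mods, function(m)
      from_working_space(session_fused(corrected_ws)[[m]], eps[[m]]))
    names(corrected_lin) <- mods
    corrected_session <- image_session(lapply(corrected_lin, list))
    bias_total <- bias_field(NULL, phi, config$bias_order, mask,
                             fused_session$dim, fused_session$spacing,
                             fused_session$origin, space = "log")
    labels <- hard_segmentation(final$posteriors)
    labels3 <- hard_segmentation(
      collapse_to_superclass(final$posteriors, warped$config,
                             "three-tissue"))
    list(posteriors = final$posteriors, state = state, labels = labels,
         labels_three = labels3, corrected = corrected_session,
         bias = bias_total, atlas = warped, transform = tf, mask = mask,
         bounds = bounds, trace = do.call(rbind, trace), log = lg,
         config = config)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

apply_phi <- function(ws_session, phi) {
  Y <- session_matrix(ws_session)
  for (m in colnames(Y)) Y[, m] <- Y[, m] - phi[[m]]
  session_from_matrix(ws_session, Y)
}

# rigid-align every scan to the first scan of the first modality
align_session <- function(session) {
  ref <- session$scans[[1L]][[1L]]
  scans <- session$scans
  for (m in names(scans)) {
    for (r in seq_along(scans[[m]])) {
      if (m == names(scans)[1L] && r == 1L) next
      tf <- register_rigid(ref, scans[[m]][[r]])
      scans[[m]][[r]] <- resample(scans[[m]][[r]], tf, ref, "linear")
    }
  }
  image_session(scans)
}

#' Write pipeline outputs to a run directory
#'
#' Posterior maps (one NIfTI per class), hard and three-tissue label maps,
#' corrected images, accumulated log-space bias field per modality, the
#' atlas transform, the iteration trace, the final context bounds, the run
#' log, and a manifest (seed, configuration, versions, output checksums).
#'
#' @param result value of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  for (cl in result$posteriors$classes) {
    fn <- file.path(dir, sprintf("posterior_%s.nii.gz",
                                 gsub("[^A-Za-z0-9]+", "_", cl)))
    write_volume(stack_volume(result$posteriors, cl), fn)
  }
  write_volume(result$labels, file.path(dir, "labels.nii.gz"))
  write_volume(result$labels_three, file.path(dir, "labels_three.nii.gz"))
  for (m in session_modalities(result$corrected)) {
    write_volume(session_fused(result$corrected)[[m]],
                 file.path(dir, sprintf("corrected_%s.nii.gz", m)))
    write_volume(bias_volume(result$bias, m),
                 file.path(dir, sprintf("bias_log_%s.nii.gz", m)))
  }
  if (!is.null(result$transform) && result$transform$kind != "displacement")
    write_transform(result$transform, file.path(dir, "atlas_transform.txt"))
  utils::write.table(result$trace, file.path(dir, "trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bounds_df <- data.frame(tissue = rownames(result$bounds$lower))
  for (m in result$bounds$modalities) {
    bounds_df[[paste0("lower.", m)]] <- result$bounds$lower[, m]
    bounds_df[[paste0("upper.", m)]] <- result$bounds$upper[, m]
  }
  utils::write.table(bounds_df, file.path(dir, "bounds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(result$log, file.path(dir, "run.log"))
  nii <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  sums <- tools::md5sum(sort(nii))
  names(sums) <- basename(names(sums))
  cfg_plain <- unclass(cfg)
  manifest <- list(
    seed = cfg$seed,
    config = cfg_plain[setdiff(names(cfg_plain), "out_dir")],
    package_version = as.character(utils::packageVersion("emtseg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = as.list(sums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
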