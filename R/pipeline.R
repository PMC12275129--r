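#' Assemble a pipeline run configuration
#'
#' Collects the parameter set of the whole analysis: band definitions,
#' FCD parameters, ASL constants, vesselness parameters, FDR level and the
#' master seed. Defaults reproduce the published protocol values
#' (CVR band 0–0.1164 Hz, standard band 0.01–0.08 Hz, r > 0.6, alpha 0.05).
#'
#' @param cvr_band,std_band Bands in Hz.
#' @param fcd [fcd_params()].
#' @param asl [asl_constants()].
#' @param vesselness [vesselness_params()].
#' @param alpha FDR significance level.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = return results only).
#' @return List of class `run_config`.
#' @export
run_config <- function(cvr_band = c(0, 0.1164), std_band = c(0.01, 0.08),
                       fcd = fcd_params(), asl = asl_constants(),
                       vesselness = vesselness_params(), alpha = 0.05,
                       seed = 1, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(cvr_band = cvr_band, std_band = std_band, fcd = fcd,
                 asl = asl, vesselness = vesselness, alpha = alpha,
                 seed = seed, out_dir = out_dir), class = "run_config")
}

#' Run the imaging stages for one subject
#'
#' From raw inputs to the full set of normalized metric maps and (when an
#' atlas is supplied) ROI means: CVR branch, standard branch with ALFF and
#' the three FCD maps, CBF quantification, and the vessel-radius pipeline.
#' Any input left `NULL` skips its stage.
#'
#' @param cfg A [run_config()].
#' @param bold List `(vol, mask, motion)` of raw BOLD inputs.
#' @param asl List `(dm, m0, mask)` of ASL inputs.
#' @param vessel 3D bright-vessel volume.
#' @param atlas Atlas from [make_atlas()] (applied to the BOLD/ASL grid).
#' @return List of stage outputs: `cvr`, `alff`, `gfcd`, `lfcd`, `lrfcd`,
#'   `cbf`, `cbf_global`, `radii`, and `roi` (long data.frame of ROI
#'   means per metric).
#' @export
run_subject_pipeline <- function(cfg, bold = NULL, asl = NULL, vessel = NULL,
                                 atlas = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list()
  maps <- list()
  if (!is.null(bold)) {
    pre_cvr <- preprocess_bold(bold$vol, bold$mask, "cvr",
                               band = cfg$cvr_band)
    out$cvr <- cvr_map(pre_cvr$filtered, bold$mask)
    maps$cvr <- out$cvr$relative
    pre_std <- preprocess_bold(bold$vol, bold$mask, "standard",
                               motion = bold$motion, band = cfg$std_band)
    alff <- alff_map(pre_std$prefilter, bold$mask, band = cfg$std_band)
    maps$alff <- relative_map(alff, bold$mask)
    g <- gfcd_map(pre_std$filtered, bold$mask, cfg$fcd)
    l <- lfcd_map(pre_std$filtered, bold$mask, cfg$fcd)
    lr <- lrfcd_map(g, l)
    out$alff <- alff; out$gfcd <- g; out$lfcd <- l; out$lrfcd <- lr
    nz <- function(m) if (mean(m[bold$mask != 0]) == 0) m else
      relative_map(m, bold$mask)
    maps$gfcd <- nz(g); maps$lfcd <- nz(l); maps$lrfcd <- nz(lr)
  }
  if (!is.null(asl)) {
    cbf <- quantify_cbf(asl$dm, asl$m0, asl$mask, cfg$asl)
    out$cbf <- cbf
    out$cbf_global <- global_mean_cbf(cbf, asl$mask)
    maps$cbf <- normalize_cbf(cbf, asl$mask)
  }
  if (!is.null(vessel)) {
    vp <- vessel_radius_pipeline(vessel, params = cfg$vesselness)
    out$radii <- vp$radii
    out$vessel_mask <- vp$mask
  }
  if (!is.null(atlas) && length(maps)) {
    roi <- NULL
    for (mn in names(maps)) {
      rm_ <- roi_means(maps[[mn]], atlas)
      rm_$metric <- mn
      roi <- rbind(roi, rm_)
    }
    out$roi <- roi
  }
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(cfg, out, maps)
  out
}

# serialize maps/tables/manifest for a subject run
write_pipeline_outputs <- function(cfg, out, maps) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mn in names(maps))
    write_nifti(maps[[mn]], file.path(cfg$out_dir, paste0(mn, "_rel.nii.gz")))
  if (!is.null(out$roi))
    utils::write.table(out$roi, file.path(cfg$out_dir, "roi_means.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(out$radii))
    utils::write.table(out$radii, file.path(cfg$out_dir, "radii.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "neurohemo",
    version = as.character(utils::packageVersion("neurohemo")),
    seed = cfg$seed, alpha = cfg$alpha,
    cvr_band_hz = cfg$cvr_band, std_band_hz = cfg$std_band,
    fcd_r_thr = cfg$fcd$r_thr, fcd_connectivity = cfg$fcd$connectivity,
    asl = unclass(cfg$asl),
    vessel_scales_mm = cfg$vesselness$scales,
    global_cbf = out$cbf_global)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' End-to-end synthetic study: phantoms, maps, ROI extraction, statistics
#'
#' Generates a cohort with planted group effects, runs the omnibus/FDR/
#' post-hoc plan, fits the LASSO-logistic discrimination of the two
#' patient groups on all simulated ROI metrics, and reports per-predictor
#' AUCs. One call exercises every module downstream of the phantoms.
#'
#' @param cfg A [run_config()].
#' @param cohort_spec A [cohort_spec()]; defaults to the study design
#'   (48/34/25) with one planted effect.
#' @return List: `cohort`, `stats` (from [fdr_scope_runner()]), `lasso`,
#'   `auc` (per selected predictor, PD-NC vs PD-MCI).
#' @export
run_cohort_study <- function(cfg, cohort_spec) {
  cohort <- make_cohort(cohort_spec)
  plan <- list(kw = list(all = cohort_spec$metrics), alpha = cfg$alpha)
  st <- fdr_scope_runner(cohort, plan)
  pd <- cohort[cohort$group != "HC", ]
  out <- list(cohort = cohort, stats = st)
  sig <- st$omnibus$roi[st$omnibus$significant]
  y <- droplevels(pd$group)
  if (length(sig) >= 2) {
    ls <- lasso_logistic_cv(as.matrix(pd[sig]), y, seed = cfg$seed)
    out$lasso <- ls
    out$auc <- lapply(stats::setNames(ls$selected, ls$selected), function(v)
      roc_auc(pd[[v]], y, ci_boot = 2000, seed = cfg$seed))
  } else if (length(sig) == 1) {
    out$auc <- stats::setNames(
      list(roc_auc(pd[[sig]], y, ci_boot = 2000, seed = cfg$seed)), sig)
  }
  out
}
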