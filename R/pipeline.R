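# Synthetic cohort generation and the end-to-end pipeline:
# phantom -> projection -> VOI geometry -> quantification -> cohort report.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Anatomical phantom specification for one cohort subject
#'
#' A torso-section phantom on the SPECT grid: an ellipsoidal body with
#' uniform soft-tissue background uptake, two ~150 ml kidneys placed
#' dorsally with elevated uptake, a large liver surrogate placed ventrally
#' and cranially to the kidneys, a smaller spleen surrogate, and a hot
#' tumour in the liver region. Sizes, positions and uptake values are
#' jittered per subject from `seed`, emulating inter-patient variability.
#'
#' @param seed integer; drives the per-subject jitter and the noise
#'   realisation.
#' @param grid_shape,voxel_spacing grid geometry (SPECT defaults).
#' @param bg_ac soft-tissue background concentration, counts/ml.
#' @param kidney_ac_mult kidney uptake as a multiple of background.
#' @param liver_ac_mult liver-surrogate uptake as a multiple of the kidney
#'   uptake.
#' @param psf_fwhm_mm Gaussian PSF FWHM emulating reconstruction resolution.
#' @param poisson add Poisson counting noise.
#' @return A `phantom_spec` with kidneys named "kidney_right" / "kidney_left".
#' @export
cohort_phantom_spec <- function(seed,
                                grid_shape = c(128L, 128L, 64L),
                                voxel_spacing = c(2.21, 2.21, 4.42),
                                bg_ac = 450, kidney_ac_mult = 10,
                                liver_ac_mult = 5, psf_fwhm_mm = 12,
                                poisson = TRUE) {
  extent <- grid_shape * voxel_spacing
  ctr <- extent / 2
  with_local_seed(seed, {
    jit <- function(x, rel) x * (1 + stats::runif(length(x), -rel, rel))
    body_semi <- jit(c(125, 105, 138), 0.03)
    kid_ac <- bg_ac * kidney_ac_mult * exp(stats::rnorm(1, 0, 0.2))
    liv_ac <- kid_ac * liver_ac_mult * jit(1, 0.15)
    kid_semi_r <- jit(c(33, 33, 33), 0.06)
    kid_semi_l <- jit(c(33, 33, 33), 0.06)
    # +x = patient left; anterior at small y; +z = cranial
    kid_ctr <- function(sx) ctr + c(sx * jit(50, 0.06), jit(40, 0.08), -jit(20, 0.25))
    body <- organ_spec("body", "ellipsoid", ctr, body_semi, bg_ac, hu = 40)
    kidneys <- list(
      organ_spec("kidney_right", "ellipsoid", kid_ctr(-1), kid_semi_r, kid_ac, hu = 35),
      organ_spec("kidney_left", "ellipsoid", kid_ctr(+1), kid_semi_l, kid_ac, hu = 35))
    # liver/spleen overlie the kidneys ventrally and extend cranially, the
    # overlap pattern seen in patients (rarely dorsal to the kidney)
    extra <- list(
      organ_spec("liver", "ellipsoid",
                 ctr + c(-jit(45, 0.1), -jit(35, 0.15), jit(30, 0.15)),
                 jit(c(60, 40, 58), 0.08), liv_ac, hu = 55),
      organ_spec("spleen", "ellipsoid",
                 ctr + c(jit(50, 0.1), -jit(30, 0.15), jit(35, 0.15)),
                 jit(c(30, 28, 42), 0.08), liv_ac * jit(0.8, 0.1), hu = 50),
      organ_spec("tumour", "ellipsoid",
                 ctr + c(-jit(30, 0.3), -jit(10, 0.5), jit(30, 0.3)),
                 jit(c(14, 14, 14), 0.2), kid_ac * 3, hu = 45))
    phantom_spec(body, kidneys, extra, grid_shape, voxel_spacing,
                 psf_fwhm_mm = psf_fwhm_mm, poisson = poisson,
                 seed = as.integer(seed))
  })
}

#' Homogeneous slab phantom for analytic recovery checks
#'
#' A slab body of AP thickness `t_p_cm` containing a box kidney of AP
#' thickness `t_k_cm` whose posterior surface lies `d_k_cm` in front of the
#' posterior body surface. With kidney-only activity (`bg_ac = 0`) the
#' conjugate-view and posterior-view formulas recover the kidney
#' concentration exactly in the continuous limit, which is the analytic
#' oracle for the discrete projector.
#'
#' @param t_k_cm,t_p_cm,d_k_cm slab geometry in cm.
#' @param kidney_ac,bg_ac concentrations in counts/ml.
#' @param refine integer grid-refinement factor (1 = SPECT spacing).
#' @param poisson,seed optional Poisson noise for robustness studies.
#' @return A `phantom_spec` with one kidney named "kidney".
#' @export
slab_phantom_spec <- function(t_k_cm = 4, t_p_cm = 20, d_k_cm = 5,
                              kidney_ac = 4500, bg_ac = 0, refine = 1L,
                              poisson = FALSE, seed = 1L) {
  stopifnot(t_k_cm > 0, t_p_cm > t_k_cm + d_k_cm, d_k_cm >= 0, refine >= 1)
  spacing <- c(2.21, 2.21, 4.42) / refine
  shape <- c(32L, 110L, 20L) * as.integer(refine)
  extent <- shape * spacing
  yc <- extent[2] / 2
  post_surf <- yc + t_p_cm * 10 / 2
  kid_y <- post_surf - d_k_cm * 10 - t_k_cm * 10 / 2
  body <- organ_spec("body", "box", c(extent[1] / 2, yc, extent[3] / 2),
                     c(extent[1], t_p_cm * 10 / 2, extent[3]), bg_ac, hu = 0)
  kidney <- organ_spec("kidney", "box", c(extent[1] / 2, kid_y, extent[3] / 2),
                       c(15, t_k_cm * 10 / 2, 12), kidney_ac, hu = 0)
  phantom_spec(body, list(kidney), grid_shape = shape, voxel_spacing = spacing,
               poisson = poisson, seed = seed)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end evaluation. Defaults reproduce
#' the study's fixed settings: body threshold 5 counts, background band at a
#' 2-pixel gap with 4-pixel width, 10 angular sectors, SPECT grid geometry.
#'
#' @param n_subjects cohort size (>= 2).
#' @param seed master seed; all per-subject seeds derive from it.
#' @param phantom "anatomical" (torso cohort) or "slab".
#' @param grid_shape,voxel_spacing phantom grid (anatomical cohort).
#' @param mu_w effective water attenuation coefficient at 208 keV, 1/cm.
#' @param threshold body segmentation threshold in counts.
#' @param gap,width,n_sectors background band parameters in pixels / count.
#' @param frac fraction-of-max threshold for kidney segmentation.
#' @param use_truth_masks use phantom ground-truth kidney masks (default)
#'   instead of running the fraction-of-max segmentation.
#' @param bg_ac,kidney_ac_mult,liver_ac_mult,psf_fwhm_mm,poisson cohort
#'   generator settings (see [cohort_phantom_spec()]).
#' @param calibration scalar converting counts/ml to calibrated units
#'   (1 keeps relative concentrations).
#' @param out_dir optional output directory for CSV reports and volumes.
#' @param write_volumes also write per-subject volumes and planar images
#'   (requires `out_dir`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 20L, seed = 1L,
                            phantom = c("anatomical", "slab"),
                            grid_shape = c(128L, 128L, 64L),
                            voxel_spacing = c(2.21, 2.21, 4.42),
                            mu_w = 0.136, threshold = 5,
                            gap = 2, width = 4, n_sectors = 10L,
                            frac = 0.5, use_truth_masks = TRUE,
                            bg_ac = 450, kidney_ac_mult = 10,
                            liver_ac_mult = 5, psf_fwhm_mm = 12,
                            poisson = TRUE, calibration = 1,
                            out_dir = NULL, write_volumes = FALSE) {
  phantom <- match.arg(phantom)
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (mu_w <= 0 || threshold < 0 || gap < 0 || width <= 0 || n_sectors < 1 ||
      frac <= 0 || frac > 1 || bg_ac < 0 || calibration <= 0)
    stop("config parameter out of range")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 phantom = phantom, grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing), mu_w = mu_w,
                 threshold = threshold, gap = gap, width = width,
                 n_sectors = as.integer(n_sectors), frac = frac,
                 use_truth_masks = isTRUE(use_truth_masks), bg_ac = bg_ac,
                 kidney_ac_mult = kidney_ac_mult, liver_ac_mult = liver_ac_mult,
                 psf_fwhm_mm = psf_fwhm_mm, poisson = isTRUE(poisson),
                 calibration = calibration, out_dir = out_dir,
                 write_volumes = isTRUE(write_volumes)),
            class = "pipeline_config")
}

#' Quantify one phantom subject under every background ROI placement
#'
#' Runs the full single-subject chain on a built phantom: attenuation map,
#' anterior/posterior attenuated projections, body mask, kidney VOIs,
#' column/true-background VOIs, sector background ROIs, net counts and the
#' conjugate-view / posterior-view / SPECT-reference concentrations.
#'
#' @param ph a `labeled_phantom`.
#' @param cfg a `pipeline_config`.
#' @param subject subject identifier stored in the output rows.
#' @return data.frame with one row per (kidney, background ROI).
#' @export
quantify_subject <- function(ph, cfg = pipeline_config(), subject = 1L) {
  stopifnot(inherits(ph, "labeled_phantom"))
  obs <- ph$observed
  att <- hu_to_mu(ph$hu, cfg$mu_w)
  ant <- attenuated_project(obs, att, "anterior")
  post <- attenuated_project(obs, att, "posterior")
  body <- body_mask(obs, cfg$threshold)

  kidney_names <- vapply(ph$spec$kidneys, `[[`, "", "name")
  rows <- list()
  for (kn in kidney_names) {
    side <- if (grepl("left$", kn)) "left" else if (grepl("right$", kn)) "right" else kn
    if (cfg$use_truth_masks) {
      kid <- ph$organ_masks[[kn]]
      kid <- mask3d(kid$voxels & body$voxels, kid$spacing, kid$label)
    } else {
      spec_k <- ph$spec$kidneys[[match(kn, kidney_names)]]
      seed_vox <- pmax(1L, pmin(dim(obs$data),
                                as.integer(round(spec_k$center / obs$spacing + 0.5))))
      kid <- segment_kidney(obs, seed_vox, cfg$frac)
      kid <- mask3d(kid$voxels & body$voxels, kid$spacing, kn)
    }
    roi_k <- project_mask_to_roi(kid)
    column <- backproject_roi_to_column(roi_k, body)
    tb <- true_background_voi(column, kid)
    geom <- measure_geometry(kid, body)
    tb_conc <- voi_mean_concentration(obs, tb)
    spect_ac <- voi_mean_concentration(obs, kid) * cfg$calibration
    k_a <- roi_counts(ant, roi_k)
    k_p <- roi_counts(post, roi_k)
    bgs <- build_background_rois(roi_k, cfg$gap, cfg$width, cfg$n_sectors)

    for (bg in bgs) {
      bg_col <- backproject_roi_to_column(bg, body)
      bg_conc <- voi_mean_concentration(obs, bg_col)
      scl <- background_scale_factor(column, kid, bg_col)
      nc <- net_counts(k_a, k_p, roi_counts(ant, bg), roi_counts(post, bg),
                       scl, bg$label)
      acc <- if (!nc$conjv_negative)
        ac_conjv(nc, geom, cfg$mu_w)$value * cfg$calibration else NA_real_
      acp <- if (!nc$postv_negative)
        ac_postv(nc, geom, cfg$mu_w)$value * cfg$calibration else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, side = side, bg_label = bg$label,
        btr = btr(bg_conc, tb_conc), scale = scl,
        a_net = nc$a_net, p_net = nc$p_net,
        conjv_negative = nc$conjv_negative, postv_negative = nc$postv_negative,
        ac_conjv = acc, ac_postv = acp, ac_spect = spect_ac,
        rel_ac_conjv = if (is.na(acc)) NA_real_ else relative_ac(acc, spect_ac),
        rel_ac_postv = if (is.na(acp)) NA_real_ else relative_ac(acp, spect_ac),
        t_k = geom$t_k, t_p = geom$t_p, d_k = geom$d_k, v_k = geom$v_k)
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic-cohort evaluation
#'
#' Builds `n_subjects` phantoms (seeds derived deterministically from the
#' master seed), quantifies each subject under all background placements,
#' and assembles the cohort report. With `out_dir` set, writes
#' `subjects.csv`, `table1.csv`, `fig4.csv` and `run_log.txt` (and,
#' optionally, per-subject volumes and planar images).
#'
#' @param cfg a `pipeline_config`.
#' @return A `study_report` with the per-subject rows attached as `$runs`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  subject_seeds <- with_local_seed(cfg$seed,
                                  sample.int(.Machine$integer.max - 1L, cfg$n_subjects))
  runs <- list()
  for (s in seq_len(cfg$n_subjects)) {
    spec <- if (cfg$phantom == "anatomical") {
      cohort_phantom_spec(subject_seeds[s], cfg$grid_shape, cfg$voxel_spacing,
                          cfg$bg_ac, cfg$kidney_ac_mult, cfg$liver_ac_mult,
                          cfg$psf_fwhm_mm, cfg$poisson)
    } else {
      slab_phantom_spec(kidney_ac = cfg$bg_ac * cfg$kidney_ac_mult,
                        bg_ac = cfg$bg_ac, poisson = cfg$poisson,
                        seed = subject_seeds[s])
    }
    ph <- build_phantom(spec)
    runs[[s]] <- quantify_subject(ph, cfg, subject = s)
    if (!is.null(cfg$out_dir) && cfg$write_volumes) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_volume(ph$observed, file.path(cfg$out_dir, sprintf("subject%02d_activity.mha", s)))
      write_volume(ph$hu, file.path(cfg$out_dir, sprintf("subject%02d_hu.mha", s)))
    }
  }
  runs <- do.call(rbind, runs)
  report <- build_study_report(runs)
  report$runs <- runs
  report$config <- cfg

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(runs, file.path(cfg$out_dir, "subjects.csv"), row.names = FALSE)
    utils::write.csv(report$table1, file.path(cfg$out_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(report$fig4, file.path(cfg$out_dir, "fig4.csv"), row.names = FALSE)
    log <- c(sprintf("conjview run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("%s = %s", names(unclass(cfg))[!names(unclass(cfg)) %in% "out_dir"],
                     vapply(unclass(cfg)[!names(unclass(cfg)) %in% "out_dir"],
                            function(v) paste(format(v), collapse = " "), "")),
             "sector convention: 0 deg = cranial (+z), increasing toward patient left (+x)")
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  }
  report
}
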