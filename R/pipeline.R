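#' Configuration for one kVCT/MVCT registration study
#'
#' Bundles the inputs and every stage's parameters.  Images may be given
#' in-memory (`fixed`, `moving`) or as file paths; landmarks likewise.
#' Defaults reproduce the standard schedules of [rigid_config()] and
#' [elastic_schedules()]; overrides are recorded in the study provenance.
#'
#' @param fixed,moving [image_volume()]s, or `NULL` when paths are given.
#' @param fixed_path,moving_path image files readable by [read_image()].
#' @param landmarks_fixed,landmarks_moving [landmark_set()]s or CSV paths
#'   ([read_landmarks()]); optional.
#' @param visible_labels labels of the landmarks visible in this MVCT
#'   session (an explicit inclusion list; all common labels when `NULL`).
#' @param preprocess a [preprocess_config()].
#' @param rigid a [rigid_config()].
#' @param elastic an [elastic_config()].
#' @param schedules an [elastic_schedules()] tibble, or `NULL` for the
#'   defaults derived from the images.
#' @param cc_border_xy,cc_border_z border exclusion for the correlation
#'   coefficient (capped automatically on small grids).
#' @param lung_low,lung_high region-growing intensity window (HU).
#' @param seed master seed propagated to the stochastic samplers.
#' @param patient,session identifiers carried into cohort tables.
#' @param output_dir when set, transforms and metric reports are written
#'   there.
#' @return A `study_config` list.
#' @export
study_config <- function(fixed = NULL, moving = NULL,
                         fixed_path = NULL, moving_path = NULL,
                         landmarks_fixed = NULL, landmarks_moving = NULL,
                         visible_labels = NULL,
                         preprocess = preprocess_config(),
                         rigid = rigid_config(),
                         elastic = elastic_config(),
                         schedules = NULL,
                         cc_border_xy = 30, cc_border_z = 2,
                         lung_low = -1000, lung_high = -500,
                         seed = NULL,
                         patient = 1L, session = 1L,
                         output_dir = NULL) {
  if (!is.null(seed)) {
    rigid$seed <- as.integer(seed)
    elastic$seed <- as.integer(seed)
  }
  structure(list(fixed = fixed, moving = moving, fixed_path = fixed_path,
                 moving_path = moving_path,
                 landmarks_fixed = landmarks_fixed,
                 landmarks_moving = landmarks_moving,
                 visible_labels = visible_labels,
                 preprocess = preprocess, rigid = rigid, elastic = elastic,
                 schedules = schedules,
                 cc_border_xy = cc_border_xy, cc_border_z = cc_border_z,
                 lung_low = lung_low, lung_high = lung_high,
                 patient = patient, session = session,
                 output_dir = output_dir),
            class = "study_config")
}

resolve_image <- function(img, path, modality) {
  if (!is.null(img)) return(img)
  if (is.null(path)) stop(sprintf("no %s image provided", modality),
                          call. = FALSE)
  read_image(path, modality = modality)
}

resolve_landmarks <- function(x, frame) {
  if (is.null(x) || inherits(x, "landmark_set")) return(x)
  read_landmarks(x, frame = frame)
}

#' Run one complete registration study
#'
#' Executes the full pipeline on a kVCT/MVCT pair: the three
#' pre-processing steps (couch suppression, body masking, axial cropping
#' of the kVCT to the MVCT extent), rigid then elastic registration,
#' warping of the MVCT onto the kVCT grid at both stages, and the full
#' validation suite (correlation coefficient, landmark TRE when landmarks
#' are available, region-growing lung segmentation with per-lung volume,
#' centroid and Jaccard correspondence on the commonly imaged sub-region)
#' for both the rigid and the elastic stage.
#'
#' @param cfg a [study_config()].
#' @param keep_images retain the pre-processed and warped volumes in the
#'   result (set `FALSE` to save memory in cohort runs).
#' @param verbose print stage progress.
#' @return A `study_result`: transforms, per-stage `metrics` (tibbles `cc`,
#'   `tre`, `lung`), optional images, and `provenance`.
#' @export
run_study <- function(cfg, keep_images = TRUE, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  fixed <- resolve_image(cfg$fixed, cfg$fixed_path, "kVCT")
  moving <- resolve_image(cfg$moving, cfg$moving_path, "MVCT")
  lm_f <- resolve_landmarks(cfg$landmarks_fixed, "kVCT")
  lm_m <- resolve_landmarks(cfg$landmarks_moving, "MVCT")

  # pre-processing steps 1-3
  body_f <- extract_body_mask(fixed, cfg$preprocess)
  fixed_m <- mask_background(fixed, body_f, cfg$preprocess)
  body_m <- extract_body_mask(moving, cfg$preprocess)
  moving_m <- mask_background(moving, body_m, cfg$preprocess)
  fixed_c <- crop_axial_to_overlap(fixed_m, moving_m)
  k0 <- round((fixed_c$origin[3] - fixed_m$origin[3]) / fixed_m$spacing[3])
  body_fc <- new_mask(body_f$voxels[, , k0 + seq_len(img_dim(fixed_c)[3]),
                                    drop = FALSE], fixed_c)

  if (verbose) message("rigid stage ...")
  rigid <- register_rigid(fixed_c, moving_m, cfg = cfg$rigid,
                          verbose = verbose)
  if (verbose) message("elastic stage ...")
  elastic <- register_elastic(fixed_c, moving_m, rigid,
                              schedules = cfg$schedules, cfg = cfg$elastic,
                              body = body_fc, verbose = verbose)

  warped_rigid <- warp_moving_image(moving_m, rigid, fixed_c)
  warped_elastic <- warp_moving_image(moving_m, elastic, fixed_c)

  stages <- list(rigid = list(T = composite_transform(rigid),
                              warped = warped_rigid),
                 elastic = list(T = elastic, warped = warped_elastic))

  d <- img_dim(fixed_c)
  bxy <- min(cfg$cc_border_xy, floor(min(d[1:2]) / 4))
  bz <- min(cfg$cc_border_z, floor(d[3] / 8))
  cc_tbl <- dplyr::bind_rows(lapply(names(stages), function(s) {
    tibble::tibble(stage = s,
                   cc = correlation_coefficient(fixed_c, stages[[s]]$warped,
                                                bxy, bz))
  }))

  tre_tbl <- NULL
  if (!is.null(lm_f) && !is.null(lm_m)) {
    labels <- intersect(lm_f$label, lm_m$label)
    if (!is.null(cfg$visible_labels))
      labels <- intersect(labels, cfg$visible_labels)
    sub_f <- lm_f[match(labels, lm_f$label), ]
    tre_tbl <- dplyr::bind_rows(lapply(names(stages), function(s) {
      tr <- target_registration_error(
        transform_landmarks(sub_f, stages[[s]]$T), lm_m)
      tibble::tibble(stage = s, n_marks = tr$n, tre_mean = tr$mean,
                     tre_sd = tr$sd, tre_max = tr$max)
    }))
  }

  lungs_ct <- tryCatch(
    split_left_right(segment_lungs_region_growing(
      fixed_c, cfg$lung_low, cfg$lung_high, body_fc), body_fc),
    error = function(e) NULL)
  fov_z <- c(max(physical_extent(fixed_c, 3)[1], physical_extent(moving, 3)[1]),
             min(physical_extent(fixed_c, 3)[2], physical_extent(moving, 3)[2]))
  lung_tbl <- NULL
  if (!is.null(lungs_ct)) {
    lung_tbl <- dplyr::bind_rows(lapply(names(stages), function(s) {
      lungs_reg <- tryCatch(
        split_left_right(segment_lungs_region_growing(
          stages[[s]]$warped, cfg$lung_low, cfg$lung_high, body_fc), body_fc),
        error = function(e) NULL)
      if (is.null(lungs_reg)) return(NULL)
      dplyr::bind_rows(lapply(c("left", "right"), function(side) {
        a <- lungs_ct[[side]]
        b <- lungs_reg[[side]]
        if (is.null(a) || is.null(b)) return(NULL)
        r <- restrict_to_common_extent(a, b, fov_z)
        v_ct <- lung_volume(r$a)
        v_reg <- lung_volume(r$b)
        if (v_ct == 0) return(NULL)
        tibble::tibble(stage = s, lung = side,
                       v_ct_mm3 = v_ct, v_reg_mm3 = v_reg,
                       ve_percent = volume_error(v_ct, v_reg),
                       ce_mm = centroid_error(r$a, r$b),
                       jac = jaccard_index(r$a, r$b))
      }))
    }))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("mvctreg")),
    seed_rigid = cfg$rigid$seed, seed_elastic = cfg$elastic$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg),
                                          c("fixed", "moving"))]),
    schedule = attr(elastic, "levels"),
    cc_border = c(xy = bxy, z = bz))

  res <- structure(list(
    patient = cfg$patient, session = cfg$session,
    transform_rigid = rigid, transform = elastic,
    metrics = list(cc = cc_tbl, tre = tre_tbl, lung = lung_tbl),
    images = if (keep_images)
      list(fixed = fixed_c, moving = moving_m, warped_rigid = warped_rigid,
           warped_elastic = warped_elastic) else NULL,
    provenance = provenance), class = "study_result")

  if (!is.null(cfg$output_dir)) write_study_outputs(res, cfg$output_dir)
  res
}

write_study_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transform(res$transform, file.path(dir, "transform_elastic.json"))
  write_transform(composite_transform(res$transform_rigid),
                  file.path(dir, "transform_rigid.json"))
  m <- res$metrics
  jsonlite::write_json(
    list(patient = res$patient, session = res$session,
         cc = m$cc, tre = m$tre, lung = m$lung,
         provenance = res$provenance[c("package_version", "seed_rigid",
                                       "seed_elastic", "config_hash")]),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (nm in c("cc", "tre", "lung"))
    if (!is.null(m[[nm]]))
      write.csv(as.data.frame(m[[nm]]),
                file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> patient %s session %s\n", x$patient, x$session))
  print(x$metrics$cc)
  if (!is.null(x$metrics$tre)) print(x$metrics$tre)
  if (!is.null(x$metrics$lung)) print(x$metrics$lung)
  invisible(x)
}

#' Run and aggregate a multi-session cohort
#'
#' Runs each study (or accepts already-run `study_result`s), collects the
#' per-session metric tibbles, and aggregates them with
#' [aggregate_cohort()], including the rigid-vs-elastic Wilcoxon
#' signed-rank comparisons (skipped with a notice below 5 pairs).
#'
#' @param studies a list of [study_config()]s or `study_result`s.
#' @param verbose print per-study progress.
#' @return A `cohort_table` with an extra element `sessions` holding the
#'   raw per-session tibbles.
#' @export
run_cohort <- function(studies, verbose = FALSE) {
  results <- lapply(studies, function(s) {
    if (inherits(s, "study_result")) return(s)
    run_study(s, keep_images = FALSE, verbose = verbose)
  })
  key <- function(r, tbl) {
    if (is.null(tbl)) return(NULL)
    dplyr::mutate(tbl, patient = r$patient, session = r$session,
                  .before = 1L)
  }
  sessions <- list(
    cc = dplyr::bind_rows(lapply(results, function(r) key(r, r$metrics$cc))),
    tre = dplyr::bind_rows(lapply(results, function(r) key(r, r$metrics$tre))),
    lung = dplyr::bind_rows(lapply(results, function(r) key(r, r$metrics$lung))))
  if (nrow(sessions$tre) == 0L) sessions$tre <- NULL
  if (nrow(sessions$lung) == 0L) sessions$lung <- NULL
  out <- aggregate_cohort(sessions)
  out$sessions <- sessions
  out
}

#' Phantom validation scenario suite
#'
#' The synthetic analogue of a patient evaluation: for each scenario a
#' thorax phantom is generated, deformed by a known smooth field, degraded
#' to MVCT quality, and registered end-to-end; accuracy is then measured
#' against the ground truth (landmark recovery TRE per stage) and with the
#' full lung-correspondence suite.
#'
#' @param scenarios list of [deformation_spec()]s; by default one scenario
#'   per deformation mode (mediastinal shift, atelectasis, pleural
#'   effusion, body shrink).
#' @param spec the [phantom_spec()] shared by all scenarios.
#' @param seed master seed (phantom texture, MVCT noise, samplers).
#' @param mvct_spacing,mvct_noise_sd,mvct_contrast,fov_frac MVCT
#'   degradation settings; `fov_frac` is the central fraction of the z
#'   extent imaged by the MVCT.
#' @param rigid,elastic,schedules stage configurations (see [run_study()]).
#' @param verbose print progress.
#' @return A list with `report` (tibble: scenario, stage, ground-truth TRE
#'   and lung metrics) and `studies` (per-scenario details).
#' @export
run_phantom_validation <- function(scenarios = NULL, spec = phantom_spec(),
                                   seed = 1L,
                                   mvct_spacing = c(0.754, 0.754, 4),
                                   mvct_noise_sd = 30, mvct_contrast = 0.9,
                                   fov_frac = 0.7,
                                   rigid = rigid_config(),
                                   elastic = elastic_config(),
                                   schedules = NULL, verbose = FALSE) {
  if (is.null(scenarios))
    scenarios <- lapply(c("mediastinal_shift", "atelectasis",
                          "pleural_effusion", "body_shrink"),
                        function(m) deformation_spec(m, seed = seed,
                                                     background_amplitude = 10))
  spec$seed <- as.integer(seed)
  rigid$seed <- as.integer(seed)
  elastic$seed <- as.integer(seed)
  base <- generate_thorax_phantom(spec)
  rows <- list()
  studies <- list()
  for (i in seq_along(scenarios)) {
    d <- scenarios[[i]]
    if (verbose) message(sprintf("scenario %d: %s", i, d$mode))
    def <- apply_synthetic_deformation(base$image, base$truth, d)
    ext <- physical_extent(def$image, 3L)
    half <- (ext[2] - ext[1]) * (1 - fov_frac) / 2
    mv <- degrade_to_mvct(def$image, mvct_spacing,
                          fov_z = c(ext[1] + half, ext[2] - half),
                          noise_sd = mvct_noise_sd,
                          contrast_scale = mvct_contrast, seed = seed + i)
    cfg <- study_config(fixed = base$image, moving = mv, rigid = rigid,
                        elastic = elastic, schedules = schedules,
                        patient = i, session = 1L)
    st <- run_study(cfg, keep_images = FALSE, verbose = verbose)
    gt <- lapply(list(rigid = composite_transform(st$transform_rigid),
                      elastic = st$transform),
                 function(T) ground_truth_error(T, def$truth))
    row <- dplyr::bind_rows(lapply(names(gt), function(s) {
      lung_s <- if (!is.null(st$metrics$lung))
        dplyr::filter(st$metrics$lung, .data$stage == s) else NULL
      tibble::tibble(
        scenario = d$mode, stage = s,
        gt_tre_mean = gt[[s]]$mean, gt_tre_max = gt[[s]]$max,
        n_marks = gt[[s]]$n,
        cc = st$metrics$cc$cc[st$metrics$cc$stage == s],
        mean_abs_ve = if (!is.null(lung_s) && nrow(lung_s) > 0)
          mean(abs(lung_s$ve_percent)) else NA_real_,
        mean_ce = if (!is.null(lung_s) && nrow(lung_s) > 0)
          mean(lung_s$ce_mm) else NA_real_,
        mean_jac = if (!is.null(lung_s) && nrow(lung_s) > 0)
          mean(lung_s$jac) else NA_real_)
    }))
    rows[[i]] <- row
    studies[[d$mode]] <- list(study = st, truth = def$truth,
                              ground_truth_tre = gt)
  }
  list(report = dplyr::bind_rows(rows), studies = studies)
}
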