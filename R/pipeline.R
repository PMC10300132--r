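#' Study configuration
#'
#' Bundles every tunable of the end-to-end synthetic study with species
#' presets: dogs use the earlier-peaking HRF, CDT p < 0.005, a 4-mm
#' searchlight with minimum 15 in-mask voxels and a 30-mm FD rotation radius;
#' humans the canonical HRF, CDT p < 0.001, an 8-mm searchlight with minimum
#' 30 voxels and a 50-mm radius.
#'
#' @param species "dog" or "human" preset.
#' @param n_subjects cohort size (default 15, the dog sample).
#' @param n_per_condition images per condition (default 30).
#' @param grid simulation grid dimensions.
#' @param voxel_mm voxel size (mm).
#' @param TR repetition time (s).
#' @param seed master seed; all stage streams derive from it.
#' @param n_perm permutations for group cluster tests (default 5000).
#' @param localizer_n_perm permutations for the localizer one-sample test.
#' @param cdt_p cluster-defining threshold (species default if NULL).
#' @param top_pct fROI top-percent threshold.
#' @param fd_threshold_mm scrubbing threshold (mm).
#' @param fd_radius_mm FD rotation radius (species default if NULL).
#' @param hpf_cutoff_s high-pass cut-off (s).
#' @param sl_radius_mm searchlight radius (species default if NULL).
#' @param min_gray_voxels minimum in-mask sphere voxels (species default).
#' @param noise_sd simulation noise SD.
#' @param comparisons RSA comparison ids to run (subset of "a".."f").
#' @param do_sweep run the top-percent stability sweep.
#' @param do_resampling run the subsample resampling control.
#' @param resample_n_sub,resample_n_iter resampling parameters.
#' @param write_nifti write simulated 4D runs to disk (large).
#' @param out_dir output directory or NULL for in-memory results only.
#' @return Object of class `study_config`.
#' @export
study_config <- function(species = c("dog", "human"), n_subjects = 15,
                         n_per_condition = 30, grid = c(32, 32, 24),
                         voxel_mm = 1.5, TR = 1, seed = 20230627,
                         n_perm = 5000, localizer_n_perm = 1000,
                         cdt_p = NULL, top_pct = 10,
                         fd_threshold_mm = 0.5, fd_radius_mm = NULL,
                         hpf_cutoff_s = 128, sl_radius_mm = NULL,
                         min_gray_voxels = NULL, noise_sd = 1.5,
                         comparisons = letters[1:6],
                         do_sweep = FALSE, do_resampling = FALSE,
                         resample_n_sub = 15, resample_n_iter = 1000,
                         write_nifti = FALSE, out_dir = NULL) {
  species <- match.arg(species)
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  cfg <- list(
    species = species,
    n_subjects = n_subjects,
    n_per_condition = check_count(n_per_condition, "n_per_condition"),
    grid = as.integer(grid), voxel_mm = voxel_mm, TR = TR,
    seed = check_count(seed, "seed", min = 0L),
    n_perm = n_perm, localizer_n_perm = localizer_n_perm,
    cdt_p = cdt_p %||% if (species == "dog") 0.005 else 0.001,
    top_pct = top_pct,
    fd_threshold_mm = fd_threshold_mm,
    fd_radius_mm = fd_radius_mm %||% if (species == "dog") 30 else 50,
    hpf_cutoff_s = hpf_cutoff_s,
    sl_radius_mm = sl_radius_mm %||% if (species == "dog") 4 else 8,
    min_gray_voxels = min_gray_voxels %||% if (species == "dog") 15L else 30L,
    noise_sd = noise_sd,
    hrf = hrf_params(if (species == "dog") "dog" else "human"),
    comparisons = comparisons,
    do_sweep = isTRUE(do_sweep), do_resampling = isTRUE(do_resampling),
    resample_n_sub = resample_n_sub, resample_n_iter = resample_n_iter,
    write_nifti = isTRUE(write_nifti), out_dir = out_dir)
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0(
    "study_config: %s preset, %d subjects, grid %s @ %g mm, TR %g s\n",
    "  seed %d, CDT p=%g, top %g%%, FD>%g mm (radius %g mm), ",
    "searchlight r=%g mm (min %d)\n"),
    x$species, x$n_subjects, paste(x$grid, collapse = "x"), x$voxel_mm, x$TR,
    x$seed, x$cdt_p, x$top_pct, x$fd_threshold_mm, x$fd_radius_mm,
    x$sl_radius_mm, x$min_gray_voxels))
  invisible(x)
}

stage_log <- function(stage, seed, t0) {
  message(sprintf("[%s] seed=%s elapsed=%.1fs", stage, as.character(seed),
                  as.numeric(proc.time()[3] - t0)))
}

## standard contrast weight sets over the six conditions
contrast_sets <- function() {
  faces <- c(dog_face = 0.5, human_face = 0.5)
  bodies <- c(dog_body = 0.5, human_body = 0.5)
  list(
    all_gt_baseline = setNames(rep(1 / 6, 6), study_conditions()),
    faces_gt_bodies = c(faces, -bodies),
    bodies_gt_faces = c(bodies, -faces),
    faces_gt_objects = c(faces, object = -1),
    bodies_gt_objects = c(bodies, object = -1),
    faces_gt_scrambled = c(faces, scrambled = -1),
    bodies_gt_scrambled = c(bodies, scrambled = -1),
    objects_gt_scrambled = c(object = 1, scrambled = -1),
    dog_face_gt_scrambled = c(dog_face = 1, scrambled = -1),
    human_face_gt_scrambled = c(human_face = 1, scrambled = -1),
    dog_body_gt_scrambled = c(dog_body = 1, scrambled = -1),
    human_body_gt_scrambled = c(human_body = 1, scrambled = -1))
}

#' Run the full synthetic study end to end
#'
#' Simulates a cohort from the planted ground truth, fits the first-level
#' GLMs with motion scrubbing, localizes visual-responsive search spaces,
#' defines split-half fROIs and runs the group ANOVAs with FDR-corrected
#' planned comparisons, runs the searchlight RSA comparisons with
#' permutation cluster inference, and (optionally) the top-percent sweep and
#' subsample resampling controls. All randomness derives from the config
#' seed via named substreams, so identical configs give identical results.
#'
#' @param config a [study_config()].
#' @param truth optional ground-truth override (a list as returned by
#'   [default_ground_truth()]).
#' @return Object of class `study_report` (see components in the vignette);
#'   when `config$out_dir` is set the results manifest, cluster tables,
#'   fROI maps and per-subject events/motion files are also written there.
#' @export
run_study <- function(config, truth = NULL) {
  stopifnot(inherits(config, "study_config"))
  t0 <- proc.time()[3]
  gt <- truth %||% default_ground_truth(config$grid, config$voxel_mm,
                                        noise_sd = config$noise_sd,
                                        hrf = config$hrf)
  tr <- gt$truth
  stimset <- generate_stimulus_set(config$n_per_condition,
                                   seed = substream_seed(config$seed, "stimuli"))
  stage_log("simulate:stimuli", config$seed, t0)

  cs <- contrast_sets()
  run1_names <- c("all_gt_baseline", "faces_gt_bodies", "bodies_gt_faces",
                  "faces_gt_objects", "bodies_gt_objects")
  run2_names <- c("faces_gt_scrambled", "bodies_gt_scrambled",
                  "objects_gt_scrambled", "dog_face_gt_scrambled",
                  "human_face_gt_scrambled", "dog_body_gt_scrambled",
                  "human_body_gt_scrambled")

  subjects <- vector("list", config$n_subjects)
  sl_spec <- searchlight_spec(config$sl_radius_mm, config$voxel_mm,
                              config$min_gray_voxels)
  sl_centers <- valid_centers(tr$mask, sl_spec)

  for (s in seq_len(config$n_subjects)) {
    sseed <- substream_seed(config$seed, sprintf("subject%03d", s))
    sess <- simulate_subject_session(stimset, tr, sseed, TR = config$TR)
    sub <- list(seed = sseed, contrasts = list(), scrub_fraction = numeric(2))
    trial_fits <- list()
    for (r in 1:2) {
      fd <- compute_fd(sess$motion[[r]], config$fd_radius_mm)
      scr <- scrub_indices(fd, config$fd_threshold_mm)
      sub$scrub_fraction[r] <- attr(scr, "removed_fraction")
      X <- build_design_matrix(sess$designs[[r]], config$hrf,
                               motion = sess$motion[[r]], scrub_idx = scr,
                               hpf_cutoff = config$hpf_cutoff_s)
      fit <- fit_glm(sess$runs[[r]], X, mask = tr$mask, run = r)
      wanted <- if (r == 1) run1_names else run2_names
      for (nm in wanted)
        sub$contrasts[[nm]] <- contrast_map(fit, cs[[nm]], label = nm)
      trial_fits[[r]] <- fit_single_block_glms(
        sess$runs[[r]], sess$designs[[r]], config$hrf,
        motion = sess$motion[[r]], scrub_idx = scr, mask = tr$mask,
        hpf_cutoff = config$hpf_cutoff_s, run = r)
    }
    stack <- trial_pattern_stack(combine_trial_betas(trial_fits), tr$mask)
    sub$n_trials <- nrow(stack$labels)
    sub$similarity <- similarity_contrast_maps(stack, sl_spec,
                                               ids = config$comparisons)
    subjects[[s]] <- sub
  }
  stage_log("simulate+glm+rsa-maps", config$seed, t0)

  ## ---- group localizer and search spaces -------------------------------
  loc <- localize_visual_responsive(
    lapply(subjects, function(su) su$contrasts$all_gt_baseline),
    gt$candidate_masks, cdt_p = config$cdt_p, alpha = 0.05,
    n_perm = config$localizer_n_perm,
    seed = substream_seed(config$seed, "localizer"),
    mask = tr$mask, affine = tr$affine)
  stage_log("froi:localizer", config$seed, t0)

  ## ---- fROIs, extraction, group ANOVAs ---------------------------------
  froi_types <- list(
    body = list(pref = "bodies_gt_faces", target = "bodies_gt_objects",
                test = c(bodies = "bodies_gt_scrambled",
                         faces = "faces_gt_scrambled",
                         objects = "objects_gt_scrambled"),
                truth_region = "body_region"),
    face = list(pref = "faces_gt_bodies", target = "faces_gt_objects",
                test = c(faces = "faces_gt_scrambled",
                         bodies = "bodies_gt_scrambled",
                         objects = "objects_gt_scrambled"),
                truth_region = "face_region"))
  con_sp <- if (config$species == "dog") "dog" else "human"
  het_sp <- if (config$species == "dog") "human" else "dog"
  sp_test <- c(conspecific_face = sprintf("%s_face_gt_scrambled", con_sp),
               heterospecific_face = sprintf("%s_face_gt_scrambled", het_sp),
               conspecific_body = sprintf("%s_body_gt_scrambled", con_sp),
               heterospecific_body = sprintf("%s_body_gt_scrambled", het_sp))

  froi_results <- list()
  for (space_nm in names(loc$search_spaces)) {
    space <- loc$search_spaces[[space_nm]]
    for (type in names(froi_types)) {
      ft <- froi_types[[type]]
      frois <- vector("list", config$n_subjects)
      ok <- rep(TRUE, config$n_subjects)
      for (s in seq_len(config$n_subjects)) {
        frois[[s]] <- tryCatch(
          define_froi(subjects[[s]]$contrasts[[ft$pref]],
                      subjects[[s]]$contrasts[[ft$target]], space,
                      top_pct = config$top_pct,
                      name = paste(space_nm, type, sep = "_")),
          error = function(e) NULL)
        ok[s] <- !is.null(frois[[s]])
      }
      if (!any(ok)) next
      oneway_tab <- t(sapply(which(ok), function(s)
        extract_froi_means(setNames(subjects[[s]]$contrasts[ft$test],
                                    names(ft$test)), frois[[s]])))
      twoway_tab <- t(sapply(which(ok), function(s)
        extract_froi_means(setNames(subjects[[s]]$contrasts[sp_test],
                                    names(sp_test)), frois[[s]])))
      dice <- vapply(which(ok), function(s)
        froi_dice(frois[[s]], tr$regions[[ft$truth_region]]), numeric(1))
      froi_results[[paste(space_nm, type, sep = "_")]] <- list(
        space = space_nm, type = type,
        n_subjects = sum(ok),
        mean_size = mean(vapply(frois[which(ok)], function(f)
          length(froi_voxels(f)), numeric(1))),
        mean_dice = mean(dice),
        values = oneway_tab,
        values_2x2 = twoway_tab,
        oneway = rm_anova_oneway(oneway_tab),
        twoway = rm_anova_2x2(twoway_tab),
        frois = frois)
    }
  }
  ## FDR within each question family: for every fROI of one type, the two
  ## planned comparisons "preferred > other" and "preferred > objects"
  planned <- list()
  for (nm in names(froi_results)) {
    fr <- froi_results[[nm]]
    pref_cond <- if (fr$type == "body") "bodies" else "faces"
    pw <- fr$oneway$pairwise
    sel <- pw$a == pref_cond | pw$b == pref_cond
    pw <- pw[sel, , drop = FALSE]
    ## orient as preferred-minus-other
    flip <- pw$b == pref_cond
    pw$mean_diff[flip] <- -pw$mean_diff[flip]
    pw$t[flip] <- -pw$t[flip]
    other <- ifelse(pw$a == pref_cond, pw$b, pw$a)
    planned[[nm]] <- data.frame(froi = nm, family = fr$type,
                                comparison = paste0(pref_cond, "_gt_", other),
                                t = pw$t, df = pw$df, p = pw$p,
                                mean_diff = pw$mean_diff,
                                stringsAsFactors = FALSE)
  }
  planned <- if (length(planned)) do.call(rbind, planned) else
    data.frame(froi = character(0), family = character(0),
               comparison = character(0), t = numeric(0), df = numeric(0),
               p = numeric(0), mean_diff = numeric(0),
               p_fdr = numeric(0))
  if (nrow(planned)) {
    planned$p_fdr <- NA_real_
    for (fam in unique(planned$family)) {
      i <- planned$family == fam
      planned$p_fdr[i] <- fdr_bh(planned$p[i])
    }
  }
  rownames(planned) <- NULL
  stage_log("froi:anovas", config$seed, t0)

  ## ---- optional controls ------------------------------------------------
  sweep <- NULL
  if (config$do_sweep && length(froi_results)) {
    nm <- names(froi_results)[1]
    fr <- froi_results[[nm]]
    space <- loc$search_spaces[[fr$space]]
    ft <- froi_types[[fr$type]]
    per_sub <- lapply(seq_len(config$n_subjects), function(s)
      cbind(subject = s, froi_threshold_sweep(
        subjects[[s]]$contrasts[[ft$pref]],
        subjects[[s]]$contrasts[[ft$target]], space,
        setNames(subjects[[s]]$contrasts[ft$test], names(ft$test)))))
    sweep <- do.call(rbind, per_sub)
    stage_log("froi:sweep", config$seed, t0)
  }
  resampling <- NULL
  if (config$do_resampling && length(froi_results)) {
    resampling <- resample_subsamples(
      froi_results[[1]]$values, n_sub = config$resample_n_sub,
      n_iter = config$resample_n_iter,
      seed = substream_seed(config$seed, "resample"))
    stage_log("froi:resampling", config$seed, t0)
  }

  ## ---- RSA group inference ---------------------------------------------
  rsa <- list()
  for (id in config$comparisons) {
    rsa[[id]] <- permutation_paired_test(
      lapply(subjects, function(su) su$similarity[[id]]$A),
      lapply(subjects, function(su) su$similarity[[id]]$B),
      n_perm = config$n_perm, cdt_p = config$cdt_p, alpha = 0.05,
      seed = substream_seed(config$seed, paste0("rsa_", id)),
      affine = tr$affine)
  }
  stage_log("rsa:inference", config$seed, t0)

  report <- structure(list(
    config = config,
    truth = tr,
    candidate_masks = gt$candidate_masks,
    region_sizes = vapply(tr$regions, length, numeric(1)),
    scrub_fractions = t(sapply(subjects, `[[`, "scrub_fraction")),
    n_trials = vapply(subjects, `[[`, numeric(1), "n_trials"),
    localizer = loc,
    froi = froi_results,
    planned_comparisons = planned,
    sweep = sweep,
    resampling = resampling,
    rsa = rsa,
    searchlight = list(spec = sl_spec, n_valid_centers = length(sl_centers))
  ), class = "study_report")
  if (!is.null(config$out_dir)) write_study_outputs(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %s preset, %d subjects, seed %d\n",
              x$config$species, x$config$n_subjects, x$config$seed))
  cat(sprintf("  search spaces: %s\n",
              paste(names(x$localizer$search_spaces), collapse = ", ")))
  for (nm in names(x$froi)) {
    fr <- x$froi[[nm]]
    cat(sprintf("  fROI %-18s mean size %5.1f, Dice %.2f, RM-ANOVA F=%.1f p=%.2g\n",
                nm, fr$mean_size, fr$mean_dice, fr$oneway$F, fr$oneway$p))
  }
  if (nrow(x$planned_comparisons)) {
    cat("  planned comparisons (FDR):\n")
    print(x$planned_comparisons[, c("froi", "comparison", "t", "p_fdr")],
          row.names = FALSE)
  }
  for (id in names(x$rsa)) {
    cl <- x$rsa[[id]]$clusters
    sig <- sum(cl$significant)
    cat(sprintf("  RSA comparison (%s): %d significant cluster(s)%s\n", id, sig,
                if (sig) sprintf(", max extent %d", max(cl$extent[cl$significant]))
                else ""))
  }
  invisible(x)
}

## machine-readable manifest: every reported number, no timing information
study_manifest <- function(report) {
  list(
    species = report$config$species,
    seed = report$config$seed,
    n_subjects = report$config$n_subjects,
    grid = report$config$grid,
    region_sizes = as.list(report$region_sizes),
    n_trials = report$n_trials,
    mean_scrub_fraction = mean(report$scrub_fractions),
    search_spaces = names(report$localizer$search_spaces),
    localizer_clusters = report$localizer$result$clusters,
    froi = lapply(report$froi, function(fr)
      list(space = fr$space, type = fr$type, mean_size = fr$mean_size,
           mean_dice = fr$mean_dice,
           oneway = fr$oneway[c("F", "df1", "df2", "p")],
           twoway = fr$twoway)),
    planned_comparisons = report$planned_comparisons,
    rsa = lapply(report$rsa, function(r)
      list(n_perm = r$n_perm, cdt_t = r$cdt$t_threshold,
           clusters = r$clusters)),
    searchlight_voxels = nrow(report$searchlight$spec$offsets),
    searchlight_valid_centers = report$searchlight$n_valid_centers)
}

write_study_outputs <- function(report, out_dir) {
  dir.create(file.path(out_dir, "derivatives"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(study_manifest(report),
                       file.path(out_dir, "derivatives", "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  for (id in names(report$rsa))
    write_cluster_table(report$rsa[[id]],
                        file.path(out_dir, "derivatives",
                                  sprintf("rsa_%s_clusters.tsv", id)))
  write_cluster_table(report$localizer$result,
                      file.path(out_dir, "derivatives",
                                "localizer_clusters.tsv"))
  if (nrow(report$planned_comparisons))
    utils::write.table(report$planned_comparisons,
                       file.path(out_dir, "derivatives",
                                 "planned_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "derivatives", "report.txt"))
  invisible(out_dir)
}
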