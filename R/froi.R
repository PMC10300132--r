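#' Hemisphere labels for voxels
#'
#' Assigns left/right by the sign of the world x coordinate from the affine;
#' exact midline voxels (x = 0) are assigned left.
#'
#' @param idx linear voxel indices.
#' @param dim grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Character vector "left"/"right".
#' @export
hemisphere_of <- function(idx, dim, affine) {
  x <- ijk_to_mm(index_to_ijk(idx, dim), affine)[, 1]
  ifelse(x > 0, "right", "left")
}

#' Localize visual-responsive search spaces at the group level
#'
#' Runs a one-sample permutation cluster test on the subjects'
#' all-conditions > baseline contrast maps and returns as search spaces all
#' candidate anatomical masks that intersect a significant cluster (the
#' "all gyri with visual-responsive voxels" rule).
#'
#' @param contrast_maps list of per-subject 3D all > baseline maps.
#' @param candidate_masks named list of logical 3D anatomical masks.
#' @param cdt_p cluster-defining threshold (0.005 dog / 0.001 human presets).
#' @param alpha cluster-level FWE threshold.
#' @param n_perm permutations for the one-sample test.
#' @param seed integer seed.
#' @param mask analysis mask.
#' @param affine 4x4 affine (hemisphere labelling of the search spaces).
#' @return List with `result` (the `cluster_result`), `search_spaces`
#'   (named list of `search_space` objects; empty, with a warning, when no
#'   cluster survives).
#' @export
localize_visual_responsive <- function(contrast_maps, candidate_masks,
                                       cdt_p = 0.005, alpha = 0.05,
                                       n_perm = 1000, seed = 20230627,
                                       mask = NULL, affine = NULL) {
  res <- permutation_onesample_test(contrast_maps, n_perm = n_perm,
                                    cdt_p = cdt_p, alpha = alpha, seed = seed,
                                    mask = mask, affine = affine)
  sig <- res$clusters$cluster[res$clusters$significant]
  if (!length(sig)) {
    warning("no significant visual-responsive cluster; no search spaces")
    return(list(result = res, search_spaces = list()))
  }
  sig_vox <- which(array(res$label_map %in% sig, dim(res$label_map)))
  spaces <- list()
  for (nm in names(candidate_masks)) {
    m <- candidate_masks[[nm]]
    if (any(which(m) %in% sig_vox))
      spaces[[nm]] <- search_space(nm, m, affine)
  }
  list(result = res, search_spaces = spaces)
}

#' Construct a search space
#'
#' @param name label.
#' @param mask logical 3D array.
#' @param affine 4x4 affine used for the hemisphere rule.
#' @return Object of class `search_space` with per-hemisphere voxel indices.
#' @export
search_space <- function(name, mask, affine = NULL) {
  idx <- which(mask)
  if (!length(idx)) stopf("search space `%s` is empty", name)
  affine <- affine %||% default_affine(dim(mask), 1.5)
  hemi <- hemisphere_of(idx, dim(mask), affine)
  structure(list(name = name, mask = mask, dim = dim(mask), affine = affine,
                 voxels = split(idx, factor(hemi, c("left", "right")))),
            class = "search_space")
}

#' Define a functional ROI by split-half localization
#'
#' Two-step top-percent selection inside an anatomical search space, using
#' localizer-run contrasts only: (1) keep voxels whose preference contrast is
#' strictly positive (e.g. bodies > faces for a body area); (2) per
#' hemisphere, keep the k voxels with the largest target contrast (e.g.
#' bodies > objects), k = max(1, ceiling(top_pct/100 x number of preference
#' voxels in that hemisphere)). A hemisphere with no preference voxels stays
#' empty (with a message); both hemispheres empty is an error.
#'
#' @param preference_map 3D contrast map gating the preference (step 1).
#' @param target_map 3D contrast map ranked for selection (step 2).
#' @param space a [search_space()].
#' @param top_pct percentage of preference voxels to keep (default 10).
#' @param name fROI label.
#' @return Object of class `froi`: per-hemisphere voxel indices plus
#'   provenance (search space, contrast labels and run, top_pct).
#' @export
define_froi <- function(preference_map, target_map, space, top_pct = 10,
                        name = NULL) {
  if (!inherits(space, "search_space")) stopf("`space` must be a search_space")
  if (!is.finite(top_pct) || top_pct <= 0 || top_pct > 100)
    stopf("`top_pct` must be in (0, 100]")
  run_pref <- attr(preference_map, "run")
  run_targ <- attr(target_map, "run")
  if (!is.null(run_pref) && !is.null(run_targ) &&
      !is.na(run_pref) && !is.na(run_targ) && !identical(run_pref, run_targ))
    stopf("preference and target maps come from different runs")
  vox <- lapply(c(left = "left", right = "right"), function(h) {
    sp <- space$voxels[[h]]
    pref <- sp[preference_map[sp] > 0 & is.finite(preference_map[sp])]
    if (!length(pref)) {
      message(sprintf("define_froi: no preference voxels in %s hemisphere", h))
      return(integer(0))
    }
    k <- max(1L, ceiling(top_pct / 100 * length(pref)))
    pref[order(target_map[pref], decreasing = TRUE)[seq_len(min(k, length(pref)))]]
  })
  if (!length(vox$left) && !length(vox$right))
    stopf("no preference voxels in either hemisphere")
  structure(list(
    name = name %||% "froi",
    voxels = vox,
    dim = space$dim,
    provenance = list(search_space = space$name,
                      preference = attr(preference_map, "label"),
                      target = attr(target_map, "label"),
                      run = if (is.null(run_pref) || is.na(run_pref)) NA
                            else run_pref,
                      top_pct = top_pct)
  ), class = "froi")
}

#' @export
print.froi <- function(x, ...) {
  cat(sprintf("froi `%s`: %d left + %d right voxels (top %g%% in %s, run %s)\n",
              x$name, length(x$voxels$left), length(x$voxels$right),
              x$provenance$top_pct, x$provenance$search_space,
              as.character(x$provenance$run)))
  invisible(x)
}

#' All voxel indices of an fROI
#' @param froi a `froi`.
#' @return Integer vector (both hemispheres).
#' @export
froi_voxels <- function(froi) unlist(froi$voxels, use.names = FALSE)

#' Extract mean left-out-run responses from an fROI
#'
#' Unweighted mean over the bilateral fROI voxels of each test-run contrast
#' map (conditions of interest > scrambled control). Enforces the split-half
#' discipline: extracting from maps carrying the same run tag as the
#' localizer that defined the fROI is an error.
#'
#' @param test_maps named list of 3D contrast maps from the left-out run.
#' @param froi a [define_froi()] object.
#' @return Named numeric vector of per-condition means.
#' @export
extract_froi_means <- function(test_maps, froi) {
  vox <- froi_voxels(froi)
  if (!length(vox)) stopf("fROI is empty")
  vapply(names(test_maps), function(nm) {
    m <- test_maps[[nm]]
    run <- attr(m, "run")
    if (!is.null(run) && !is.na(run) && !is.na(froi$provenance$run) &&
        identical(run, froi$provenance$run))
      stopf("split-half violation: fROI was defined on run %s",
            as.character(run))
    v <- m[vox]
    bad <- !is.finite(v)
    if (all(bad)) stopf("all fROI voxels are NaN in map `%s`", nm)
    if (any(bad))
      message(sprintf("extract_froi_means: %d NaN voxel(s) excluded in `%s`",
                      sum(bad), nm))
    mean(v[!bad])
  }, numeric(1))
}

#' fROI stability sweep over the top-percent threshold
#'
#' Repeats define-and-extract over a grid of top-percent cut-offs (the
#' validation grid is 1% and then 5% steps up to 100%) and returns the
#' per-condition mean curves.
#'
#' @inheritParams define_froi
#' @param test_maps named list of left-out-run contrast maps.
#' @param pct_grid percentages in (0, 100].
#' @return Data frame: top_pct, condition, mean, n_voxels.
#' @export
froi_threshold_sweep <- function(preference_map, target_map, space, test_maps,
                                 pct_grid = c(1, seq(5, 100, by = 5))) {
  if (any(pct_grid <= 0 | pct_grid > 100)) stopf("pct_grid must be in (0, 100]")
  out <- lapply(pct_grid, function(pct) {
    fr <- define_froi(preference_map, target_map, space, top_pct = pct)
    means <- extract_froi_means(test_maps, fr)
    data.frame(top_pct = pct, condition = names(means), mean = unname(means),
               n_voxels = length(froi_voxels(fr)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Serialize an fROI as a NIfTI label map with a JSON sidecar
#'
#' Left-hemisphere voxels get label 1, right 2; provenance goes to
#' `<path>.json`.
#'
#' @param froi a `froi`.
#' @param path NIfTI output path.
#' @param affine 4x4 affine.
#' @return the path, invisibly.
#' @export
write_froi <- function(froi, path, affine) {
  lab <- array(0L, froi$dim)
  lab[froi$voxels$left] <- 1L
  lab[froi$voxels$right] <- 2L
  write_volume(lab, affine, path)
  jsonlite::write_json(froi$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Dice overlap between an fROI and a reference voxel set
#'
#' @param froi a `froi`.
#' @param reference_idx linear voxel indices of the reference region.
#' @return Dice coefficient in \[0, 1\].
#' @export
froi_dice <- function(froi, reference_idx) {
  vox <- froi_voxels(froi)
  2 * length(intersect(vox, reference_idx)) /
    (length(vox) + length(reference_idx))
}
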