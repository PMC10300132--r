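#' Searchlight sphere offsets
#'
#' All integer voxel offsets whose centre-to-centre distance in mm is within
#' the radius. The dog preset (r = 4 mm on a 1.5 mm isotropic grid) gives 81
#' offsets; the human preset (r = 8 mm on a 2 mm grid, exclusive boundary)
#' gives 251. Anisotropic voxel sizes are supported via per-axis scaling.
#'
#' @param radius_mm sphere radius in mm (> 0).
#' @param voxel_mm voxel size in mm, scalar or 3-vector (> 0).
#' @param boundary "inclusive" (distance <= r) or "exclusive" (< r).
#' @return Integer matrix n x 3 of offsets (includes the centre 0,0,0).
#' @export
sphere_offsets <- function(radius_mm, voxel_mm = 1.5,
                           boundary = c("inclusive", "exclusive")) {
  boundary <- match.arg(boundary)
  if (!is.finite(radius_mm) || radius_mm <= 0) stopf("`radius_mm` must be > 0")
  voxel_mm <- rep(voxel_mm, length.out = 3L)
  if (any(voxel_mm <= 0)) stopf("voxel sizes must be > 0")
  r <- floor(radius_mm / voxel_mm)
  g <- as.matrix(expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3]))
  d2 <- (g[, 1] * voxel_mm[1])^2 + (g[, 2] * voxel_mm[2])^2 +
        (g[, 3] * voxel_mm[3])^2
  keep <- if (boundary == "inclusive") d2 <= radius_mm^2 else d2 < radius_mm^2
  out <- g[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j", "k"))
  out
}

#' Searchlight specification
#'
#' @param radius_mm sphere radius (mm).
#' @param voxel_mm voxel size (mm), scalar or 3-vector.
#' @param min_gray_voxels minimum in-mask sphere voxels for a valid centre
#'   (15 for the dog preset, 30 for the human preset).
#' @param boundary sphere boundary rule (see [sphere_offsets()]).
#' @return Object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius_mm = 4, voxel_mm = 1.5,
                             min_gray_voxels = 15,
                             boundary = c("inclusive", "exclusive")) {
  boundary <- match.arg(boundary)
  structure(list(radius_mm = radius_mm,
                 voxel_mm = rep(voxel_mm, length.out = 3L),
                 min_gray_voxels = min_gray_voxels,
                 boundary = boundary,
                 offsets = sphere_offsets(radius_mm, voxel_mm, boundary)),
            class = "searchlight_spec")
}

#' @export
print.searchlight_spec <- function(x, ...) {
  cat(sprintf(
    "searchlight_spec: r=%g mm on %s mm grid (%s) -> %d voxels, min %d in-mask\n",
    x$radius_mm, paste(x$voxel_mm, collapse = "x"), x$boundary,
    nrow(x$offsets), x$min_gray_voxels))
  invisible(x)
}

#' Valid searchlight centres in a gray-matter mask
#'
#' In-mask voxels whose sphere contains at least `min_gray_voxels` in-mask
#' voxels (spheres are clipped at the grid boundary).
#'
#' @param mask logical 3D array.
#' @param spec a [searchlight_spec()].
#' @return Integer vector of linear voxel indices.
#' @export
valid_centers <- function(mask, spec) {
  if (!any(mask)) stopf("mask is empty")
  d <- dim(mask)
  counts <- array(0L, d)
  m <- array(as.integer(mask), d)
  for (o in seq_len(nrow(spec$offsets))) {
    off <- spec$offsets[o, ]
    src_i <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
    src_j <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
    src_k <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
    counts[src_i, src_j, src_k] <-
      counts[src_i, src_j, src_k] +
      m[src_i + off[1], src_j + off[2], src_k + off[3]]
  }
  which(mask & counts >= spec$min_gray_voxels)
}

#' Build a trial pattern stack
#'
#' Collects the single-block beta maps of one participant (both runs) with
#' their labels and the gray-matter mask, the unit the searchlight consumes.
#'
#' @param trial_betas a [combine_trial_betas()] object (36 maps for the
#'   default design).
#' @param gray_mask logical 3D array.
#' @return Object of class `trial_pattern_stack`.
#' @export
trial_pattern_stack <- function(trial_betas, gray_mask) {
  if (!inherits(trial_betas, "trial_betas"))
    stopf("`trial_betas` must be a trial_betas object")
  d <- dim(trial_betas$maps[[1]])
  if (!identical(dim(gray_mask), d)) stopf("mask grid mismatch")
  P <- do.call(cbind, lapply(trial_betas$maps, as.vector))
  structure(list(patterns = P,               # all-voxels x trials
                 labels = trial_betas$labels,
                 mask = gray_mask, dim = d),
            class = "trial_pattern_stack")
}

## Fisher z with |r| clipped below 1 (identical patterns give the capped z,
## not infinity)
fisher_z <- function(r, cap = 1 - 1e-6) atanh(pmin(pmax(r, -cap), cap))

## Core searchlight sweep. pair_sets is a named list of logical trial x trial
## matrices marking which unordered pairs enter each mean. Returns one 3D map
## per pair set. Pairs involving a zero-variance trial pattern are skipped;
## centres where a set has no usable pair get NaN.
searchlight_mean_z <- function(stack, spec, pair_sets, centers = NULL) {
  d <- stack$dim
  centers <- centers %||% valid_centers(stack$mask, spec)
  n_tr <- ncol(stack$patterns)
  sets <- lapply(pair_sets, function(m) {
    m <- m | t(m)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    m
  })
  set_idx <- lapply(sets, which)
  maps <- lapply(sets, function(.) array(NaN, d))
  if (!length(centers)) return(maps)
  mask_arr <- stack$mask
  offs <- spec$offsets
  cijk <- index_to_ijk(centers, d)
  skipped <- 0L
  for (ci in seq_along(centers)) {
    ijk <- cijk[ci, ]
    ni <- ijk[1] + offs[, 1]; nj <- ijk[2] + offs[, 2]; nk <- ijk[3] + offs[, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    vox <- ijk_to_index(cbind(ni[ok], nj[ok], nk[ok]), d)
    vox <- vox[mask_arr[vox]]
    if (length(vox) < 2L) next
    X <- stack$patterns[vox, , drop = FALSE]
    sds <- apply(X, 2, sd)
    degen <- sds == 0 | !is.finite(sds)
    if (any(degen)) skipped <- skipped + sum(degen)
    R <- suppressWarnings(cor(X))
    Z <- fisher_z(R)
    for (s in names(sets)) {
      if (any(degen)) {
        pm <- sets[[s]] & outer(!degen, !degen, `&`)
        vals <- Z[pm]
        vals <- vals[is.finite(vals)]
        maps[[s]][centers[ci]] <- if (length(vals)) mean(vals) else NaN
      } else {
        maps[[s]][centers[ci]] <- mean(Z[set_idx[[s]]])
      }
    }
  }
  if (skipped > 0)
    message(sprintf("searchlight: %d zero-variance trial pattern(s) skipped",
                    skipped))
  maps
}

#' Searchlight pattern-similarity map for one trial set
#'
#' For every valid searchlight centre: extract the trial x voxel patterns
#' over the in-mask sphere voxels, Pearson-correlate every unordered pair of
#' distinct trials in the set (self-pairs excluded; pairs spanning the two
#' runs included), Fisher-z transform each correlation, and assign the mean z
#' to the centre voxel.
#'
#' @param stack a [trial_pattern_stack()].
#' @param spec a [searchlight_spec()].
#' @param trial_set logical or integer index of the trials in the set, or a
#'   predicate function over the label data.frame.
#' @return 3D map of mean Fisher z (NaN outside valid centres).
#' @export
searchlight_similarity <- function(stack, spec, trial_set) {
  sel <- resolve_trials(stack, trial_set)
  if (sum(sel) < 2L) stopf("trial set needs >= 2 trials")
  pm <- outer(sel, sel, `&`)
  searchlight_mean_z(stack, spec, list(set = pm))$set
}

resolve_trials <- function(stack, trial_set) {
  n <- ncol(stack$patterns)
  if (is.function(trial_set)) {
    sel <- trial_set(stack$labels)
  } else if (is.logical(trial_set)) {
    sel <- trial_set
  } else {
    sel <- rep(FALSE, n); sel[trial_set] <- TRUE
  }
  if (length(sel) != n) stopf("trial selector length mismatch")
  sel
}

#' Trial sets of the six similarity comparisons
#'
#' The registry behind [similarity_contrast_pair()]: (a) faces (dog x human
#' pooled) vs inanimate objects, (b) bodies vs objects, (c) animate (all
#' faces and bodies) vs objects, (d) faces vs bodies, (e) dog faces vs human
#' faces, (f) dog bodies vs human bodies.
#'
#' @param id comparison id, one of "a".."f".
#' @return List with `A` and `B` condition-label vectors.
#' @export
similarity_comparison <- function(id) {
  faces <- c("dog_face", "human_face")
  bodies <- c("dog_body", "human_body")
  switch(id,
         a = list(A = faces, B = "object"),
         b = list(A = bodies, B = "object"),
         c = list(A = c(faces, bodies), B = "object"),
         d = list(A = faces, B = bodies),
         e = list(A = "dog_face", B = "human_face"),
         f = list(A = "dog_body", B = "human_body"),
         stopf("unknown comparison id `%s` (use \"a\"..\"f\")", id))
}

#' Similarity-map pair for one group comparison
#'
#' Computes the two per-participant mean-similarity maps that enter the
#' group-level paired test for comparison (a)-(f). Each pooled set's
#' similarity is the mean pairwise Fisher z among all trials of the set;
#' cross-species trial pairs are included in pooled sets by default
#' (`within_species_pairs_only = TRUE` restricts pooled-set pairs to
#' same-species trials).
#'
#' @param stack a [trial_pattern_stack()].
#' @param spec a [searchlight_spec()].
#' @param id comparison id "a".."f".
#' @param within_species_pairs_only alternative reading of the pooled sets.
#' @return List with `A` and `B` 3D similarity maps (class attributes label
#'   the comparison).
#' @export
similarity_contrast_pair <- function(stack, spec, id,
                                     within_species_pairs_only = FALSE) {
  similarity_contrast_maps(stack, spec, ids = id,
                           within_species_pairs_only)[[id]]
}

#' Similarity-map pairs for several comparisons in one searchlight sweep
#'
#' Computes the trial x trial correlation matrix once per sphere and derives
#' every requested comparison's set means from it, so running all six
#' comparisons costs one sweep.
#'
#' @inheritParams similarity_contrast_pair
#' @param ids comparison ids (subset of "a".."f").
#' @return Named list (by id) of lists with `A` and `B` 3D similarity maps.
#' @export
similarity_contrast_maps <- function(stack, spec, ids = letters[1:6],
                                     within_species_pairs_only = FALSE) {
  make_pm <- function(conds, id) {
    sel <- stack$labels$condition %in% conds
    if (sum(sel) < 2L) stopf("comparison %s: fewer than 2 trials in a set", id)
    pm <- outer(sel, sel, `&`)
    if (within_species_pairs_only && length(conds) > 1L) {
      sp <- condition_species(stack$labels$condition)
      pm <- pm & outer(sp, sp, `==`)
    }
    pm
  }
  sets <- list()
  for (id in ids) {
    cmp <- similarity_comparison(id)
    sets[[paste0(id, "_A")]] <- make_pm(cmp$A, id)
    sets[[paste0(id, "_B")]] <- make_pm(cmp$B, id)
  }
  maps <- searchlight_mean_z(stack, spec, sets)
  out <- lapply(setNames(nm = ids), function(id) {
    pair <- list(A = maps[[paste0(id, "_A")]], B = maps[[paste0(id, "_B")]])
    attr(pair$A, "label") <- paste0("similarity_", id, "_A")
    attr(pair$B, "label") <- paste0("similarity_", id, "_B")
    pair
  })
  out
}
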