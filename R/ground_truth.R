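#' Ellipsoidal brain mask
#'
#' @param dim grid dimensions (3-vector).
#' @param semi_axes ellipsoid semi-axes in voxels (default scaled to the grid).
#' @return Logical 3D array.
#' @export
make_brain_mask <- function(dim, semi_axes = dim * c(0.47, 0.47, 0.46)) {
  cx <- (dim + 1) / 2
  i <- (seq_len(dim[1]) - cx[1]) / semi_axes[1]
  j <- (seq_len(dim[2]) - cx[2]) / semi_axes[2]
  k <- (seq_len(dim[3]) - cx[3]) / semi_axes[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(r2 <= 1, dim = dim)
}

#' Voxel indices of an axis-aligned box
#'
#' @param dim grid dimensions.
#' @param x,y,z integer index ranges (2-vectors, inclusive).
#' @return Integer vector of linear voxel indices.
#' @export
box_region <- function(dim, x, y, z) {
  g <- expand.grid(i = x[1]:x[2], j = y[1]:y[2], k = z[1]:z[2])
  ijk_to_index(as.matrix(g), dim)
}

#' Assemble a ground-truth activation layout
#'
#' Defines the forward model that [simulate_bold_run()] realises: a voxel
#' grid with affine, named regions (voxel index sets), a region x condition
#' amplitude table (in raw signal units on top of `baseline`), Gaussian noise,
#' slow cosine drift, and optional multivoxel patterns. A region listed in
#' `pattern_sd` gives every condition in the matching `pattern_groups` entry a
#' shared per-voxel gain field (drawn per subject), so trials of those
#' conditions carry a reliable spatial pattern on top of their mean amplitude
#' — the substrate that representational similarity analysis detects.
#'
#' @param dim grid dimensions (3-vector).
#' @param voxel_mm voxel size in mm (scalar or 3-vector).
#' @param regions named list of voxel index vectors.
#' @param amplitudes numeric matrix, rows = regions, columns = the six
#'   conditions, effect sizes in signal units.
#' @param mask logical 3D brain mask (regions outside are clipped).
#' @param baseline mean signal level.
#' @param noise_sd SD of white Gaussian scanner noise.
#' @param drift_sd SD of the random coefficients on the slow cosine drift
#'   components (periods longer than `drift_cutoff` seconds).
#' @param drift_cutoff slowest fluctuation modelled as drift, in seconds.
#' @param subject_gain_sd SD of the multiplicative between-subject amplitude
#'   variation.
#' @param pattern_sd named numeric vector (per region) of multivoxel pattern
#'   strength relative to the mean amplitude; regions not named get none.
#' @param pattern_groups named list of condition groups that share one
#'   pattern field within a region (e.g. `list(animate = c("dog_face", ...))`).
#' @param hrf an [hrf_params()] object used as the simulated response.
#' @return Object of class `ground_truth`.
#' @export
make_ground_truth <- function(dim, voxel_mm = 1.5, regions, amplitudes,
                              mask = make_brain_mask(dim),
                              baseline = 100, noise_sd = 1.5,
                              drift_sd = 1, drift_cutoff = 128,
                              subject_gain_sd = 0.1,
                              pattern_sd = numeric(0),
                              pattern_groups = list(),
                              hrf = hrf_params("dog")) {
  if (!is.matrix(amplitudes) || nrow(amplitudes) != length(regions))
    stopf("`amplitudes` must be a regions x conditions matrix")
  if (is.null(rownames(amplitudes))) rownames(amplitudes) <- names(regions)
  if (is.null(colnames(amplitudes))) colnames(amplitudes) <- study_conditions()
  if (any(!is.finite(amplitudes))) stopf("amplitudes must be finite")
  mask_idx <- which(mask)
  regions <- lapply(regions, function(r) intersect(as.integer(r), mask_idx))
  structure(list(
    dim = as.integer(dim),
    voxel_mm = rep(voxel_mm, length.out = 3L),
    affine = default_affine(as.integer(dim), voxel_mm),
    mask = mask,
    regions = regions,
    amplitudes = amplitudes,
    baseline = baseline,
    noise_sd = noise_sd,
    drift_sd = drift_sd,
    drift_cutoff = drift_cutoff,
    subject_gain_sd = subject_gain_sd,
    pattern_sd = pattern_sd,
    pattern_groups = pattern_groups,
    hrf = hrf
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: grid %s, %d mask voxels, noise_sd %g\n",
              paste(x$dim, collapse = "x"), sum(x$mask), x$noise_sd))
  for (r in names(x$regions))
    cat(sprintf("  region %-14s %4d voxels\n", r, length(x$regions[[r]])))
  invisible(x)
}

#' Default desk-scale ground truth for the dog study simulation
#'
#' A 32 x 32 x 24 grid at 1.5 mm isotropic with four planted sources inside
#' an ellipsoidal brain mask:
#' \describe{
#'   \item{visual}{posterior region responding equally to all conditions
#'     (drives the all > baseline localizer).}
#'   \item{body_region}{small bilateral region preferring bodies over faces
#'     and objects (the body-sensitive fROI target).}
#'   \item{face_region}{small bilateral region preferring faces.}
#'   \item{animate_patch}{region whose four animate conditions share a
#'     multivoxel pattern (the RSA animacy target); objects evoke the same
#'     mean response but no reliable pattern.}
#' }
#' Amplitudes are 1-3% of the baseline of 100 (typical BOLD effect sizes) and
#' the noise SD of 1.5 gives a temporal SNR near 65. Also returns candidate
#' "gyrus" masks used as anatomical search spaces: two containing the planted
#' category regions and one visually unresponsive control.
#'
#' @param dim grid dimensions.
#' @param voxel_mm voxel size (mm).
#' @param noise_sd scanner noise SD.
#' @param hrf simulated response function.
#' @return List with `truth` (a `ground_truth`) and `candidate_masks`
#'   (named list of logical 3D arrays).
#' @export
default_ground_truth <- function(dim = c(32, 32, 24), voxel_mm = 1.5,
                                 noise_sd = 1.5, hrf = hrf_params("dog")) {
  stopifnot(all(dim >= c(32, 32, 24) * 0 + 16))
  mask <- make_brain_mask(dim)
  sc <- dim / c(32, 32, 24)                 # geometry scales with the grid
  bx <- function(x, y, z) box_region(dim, round(x * sc[1]), round(y * sc[2]),
                                     round(z * sc[3]))
  xm <- function(lo, hi) c(lo, hi)
  regions <- list(
    visual        = bx(xm(9, 24), xm(5, 10), xm(9, 16)),
    body_region   = c(bx(xm(6, 9), xm(14, 15), xm(10, 11)),
                      bx(xm(24, 27), xm(14, 15), xm(10, 11))),
    face_region   = c(bx(xm(6, 9), xm(19, 20), xm(11, 12)),
                      bx(xm(24, 27), xm(19, 20), xm(11, 12))),
    ## placed so that the gap to every other source exceeds the searchlight
    ## diameter: sources closer than that merge into one similarity cluster
    animate_patch = bx(xm(16, 21), xm(20, 23), xm(17, 20))
  )
  conds <- study_conditions()
  A <- rbind(
    visual        = c(2, 2, 2, 2, 2, 2),
    body_region   = c(1.5, 3, 1.5, 3, 1.5, 1),
    face_region   = c(3, 1.5, 3, 1.5, 1.5, 1),
    animate_patch = c(2, 2, 2, 2, 2, 1.5)
  )
  colnames(A) <- conds
  truth <- make_ground_truth(dim, voxel_mm, regions, A, mask = mask,
                             noise_sd = noise_sd,
                             pattern_sd = c(animate_patch = 0.5),
                             pattern_groups = list(
                               animate = c("dog_face", "dog_body",
                                           "human_face", "human_body")),
                             hrf = hrf)
  as_mask <- function(idx) {
    m <- array(FALSE, dim = dim)
    m[idx] <- TRUE
    m & mask
  }
  candidate_masks <- list(
    gyrus_body = as_mask(c(bx(xm(4, 11), xm(13, 17), xm(9, 12)),
                           bx(xm(22, 29), xm(13, 17), xm(9, 12)))),
    gyrus_face = as_mask(c(bx(xm(4, 11), xm(18, 21), xm(10, 13)),
                           bx(xm(22, 29), xm(18, 21), xm(10, 13)))),
    gyrus_quiet = as_mask(c(bx(xm(13, 19), xm(8, 11), xm(18, 20))))
  )
  list(truth = truth, candidate_masks = candidate_masks)
}

#' Per-subject amplitude maps from a ground truth
#'
#' Realises the subject-level forward model: every region x condition
#' amplitude is scaled by a subject gain (1 + N(0, subject_gain_sd)), and
#' pattern regions add their shared per-voxel gain fields. The result is one
#' 3D amplitude map per condition.
#'
#' @param truth a `ground_truth`.
#' @param seed integer seed (use one per subject).
#' @return Named list (by condition) of 3D amplitude arrays.
#' @export
subject_amplitude_maps <- function(truth, seed) {
  set.seed(substream_seed(seed, "subject_amplitudes"))
  conds <- colnames(truth$amplitudes)
  maps <- lapply(conds, function(c) array(0, dim = truth$dim))
  names(maps) <- conds
  for (rn in rownames(truth$amplitudes)) {
    idx <- truth$regions[[rn]]
    if (!length(idx)) next
    gain <- 1 + rnorm(1, sd = truth$subject_gain_sd)
    psd <- if (rn %in% names(truth$pattern_sd)) truth$pattern_sd[[rn]] else 0
    fields <- list()
    if (psd > 0)
      for (gname in names(truth$pattern_groups))
        fields[[gname]] <- rnorm(length(idx))
    for (cond in conds) {
      a <- truth$amplitudes[rn, cond] * gain
      vox <- rep(a, length(idx))
      if (psd > 0) {
        for (gname in names(truth$pattern_groups)) {
          if (cond %in% truth$pattern_groups[[gname]])
            vox <- a * (1 + psd * fields[[gname]])
        }
      }
      maps[[cond]][idx] <- maps[[cond]][idx] + vox
    }
  }
  maps
}
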