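#' Simulate one BOLD run
#'
#' Linear forward model matching the analysis GLM: every voxel's time series
#' is baseline + sum over conditions of amplitude x (12-s boxcar convolved
#' with the HRF) + slow cosine drift + white Gaussian noise. Voxels outside
#' the brain mask are zero. The motion trace does not perturb the signal; it
#' exists to exercise framewise-displacement scrubbing downstream.
#'
#' @param design a `run_design`.
#' @param truth a `ground_truth`.
#' @param motion optional n_scans x 6 motion trace (checked against the
#'   design length).
#' @param seed integer seed for noise and drift.
#' @param amplitude_maps per-condition 3D amplitude maps from
#'   [subject_amplitude_maps()]; by default drawn from `seed` (so pass the
#'   same maps for both runs of one subject).
#' @param noise_sd,drift_sd overrides of the ground-truth values.
#' @return Object of class `bold_run`: list with `data` (4D array
#'   x,y,z,scan), `TR`, `affine`, `n_scans`.
#' @export
simulate_bold_run <- function(design, truth, motion = NULL, seed = 20230627,
                              amplitude_maps = NULL,
                              noise_sd = NULL, drift_sd = NULL) {
  if (!inherits(design, "run_design")) stopf("`design` must be a run_design")
  if (!inherits(truth, "ground_truth")) stopf("`truth` must be a ground_truth")
  n <- design$n_scans
  TR <- design$TR
  if (!is.null(motion) && nrow(motion) != n)
    stopf("motion trace length %d does not match %d scans", nrow(motion), n)
  noise_sd <- noise_sd %||% truth$noise_sd
  drift_sd <- drift_sd %||% truth$drift_sd
  amplitude_maps <- amplitude_maps %||% subject_amplitude_maps(truth, seed)

  mask_idx <- which(truth$mask)
  nv <- length(mask_idx)
  conds <- intersect(study_conditions(), unique(design$blocks$condition))

  ## scans x conditions convolved regressors (shared forward model with the
  ## analysis design matrix)
  Xc <- sapply(conds, function(cond) {
    sel <- design$blocks$condition == cond
    convolve_blocks(design$blocks$onset[sel], design$blocks$duration[sel],
                    n, TR, truth$hrf)
  })
  Xc <- matrix(Xc, nrow = n)

  A <- sapply(conds, function(cond) amplitude_maps[[cond]][mask_idx])
  A <- matrix(A, nrow = nv)
  Y <- Xc %*% t(A)                               # scans x voxels signal
  Y <- Y + truth$baseline

  set.seed(substream_seed(seed, "bold_noise"))
  D <- dct_drift_basis(n, TR, truth$drift_cutoff)
  if (ncol(D) > 0 && drift_sd > 0) {
    coefs <- matrix(rnorm(ncol(D) * nv, sd = drift_sd * sqrt(n)), ncol(D), nv)
    Y <- Y + D %*% coefs
  }
  if (noise_sd > 0)
    Y <- Y + matrix(rnorm(n * nv, sd = noise_sd), n, nv)

  data <- array(0, dim = c(truth$dim, n))
  flat <- matrix(data, nrow = prod(truth$dim))
  flat[mask_idx, ] <- t(Y)
  structure(list(data = array(flat, dim = c(truth$dim, n)),
                 TR = TR, affine = truth$affine, n_scans = n),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("bold_run: grid %s, %d scans, TR %g s\n",
              paste(dim(x$data)[1:3], collapse = "x"), x$n_scans, x$TR))
  invisible(x)
}

#' Write a simulated run as NIfTI
#'
#' @param run a `bold_run`.
#' @param path output `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_bold_run <- function(run, path) {
  write_volume(run$data, run$affine, path)
}

#' Simulate a full subject session
#'
#' Two (or more) runs with a shared image partition, per-run motion traces
#' with occasional FD spikes, and subject-level amplitude maps shared across
#' runs.
#'
#' @param stimulus_set a [generate_stimulus_set()] object.
#' @param truth a `ground_truth`.
#' @param subject_seed integer seed for this subject.
#' @param n_runs runs per session.
#' @param TR repetition time (s).
#' @param spike_rate expected fraction of scans receiving a motion spike
#'   large enough to exceed the 0.5-mm FD threshold.
#' @return List with `designs`, `runs` (bold_run list), `motion` (list of
#'   matrices), `amplitude_maps`.
#' @export
simulate_subject_session <- function(stimulus_set, truth, subject_seed,
                                     n_runs = 2, TR = 1, spike_rate = 0.02) {
  designs <- make_subject_designs(stimulus_set, n_runs = n_runs, TR = TR,
                                  seed = substream_seed(subject_seed, "designs"))
  amplitude_maps <- subject_amplitude_maps(truth, subject_seed)
  runs <- vector("list", n_runs)
  motion <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    n <- designs[[r]]$n_scans
    set.seed(substream_seed(subject_seed, paste0("spikes", r)))
    n_spikes <- stats::rbinom(1, n, spike_rate)
    times <- if (n_spikes > 0) sort(sample(2:n, n_spikes)) else integer(0)
    motion[[r]] <- simulate_motion_trace(
      n, spike_times = times,
      spike_magnitudes = runif(n_spikes, 0.7, 1.5),
      seed = substream_seed(subject_seed, paste0("motion", r)))
    runs[[r]] <- simulate_bold_run(designs[[r]], truth, motion[[r]],
                                   seed = substream_seed(subject_seed,
                                                         paste0("bold", r)),
                                   amplitude_maps = amplitude_maps)
  }
  list(designs = designs, runs = runs, motion = motion,
       amplitude_maps = amplitude_maps)
}
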