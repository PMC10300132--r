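#' Voxel-wise ordinary least squares GLM
#'
#' Fits the design matrix to every in-mask voxel time series by OLS. Voxel
#' series that are entirely NaN are dropped from the mask (with a message);
#' a rank-deficient design is solved by Moore-Penrose pseudoinverse with a
#' warning.
#'
#' @param volume a `bold_run` or a 4D array (x, y, z, scan).
#' @param X a [build_design_matrix()] object.
#' @param mask logical 3D array of voxels to fit.
#' @param run optional run label stored on the outputs (provenance used by
#'   the split-half fROI discipline).
#' @return Object of class `glm_fit`: list with `betas` (named list of 3D
#'   arrays, NaN outside the mask), `sigma2` (residual variance map), `df`
#'   residual degrees of freedom, `condition_cols`, `mask`, `affine`, `run`.
#' @export
fit_glm <- function(volume, X, mask = NULL, run = NA) {
  if (inherits(volume, "bold_run")) {
    affine <- volume$affine
    vol <- volume$data
  } else {
    affine <- attr(volume, "affine") %||% default_affine(dim(volume)[1:3], 1)
    vol <- volume
  }
  if (!inherits(X, "design_matrix")) stopf("`X` must be a design_matrix")
  d <- dim(vol)
  if (length(d) != 4L || d[4L] != X$n_scans)
    stopf("volume scans (%d) do not match design (%d)",
          if (length(d) == 4L) d[4L] else NA, X$n_scans)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (!any(mask)) stopf("mask is empty")

  flat <- matrix(vol, nrow = prod(d[1:3]))
  mask_idx <- which(mask)
  Y <- t(flat[mask_idx, , drop = FALSE])        # scans x voxels
  all_nan <- colSums(is.finite(Y)) == 0L
  if (any(all_nan)) {
    message(sprintf("fit_glm: dropping %d all-NaN voxel(s) from the mask",
                    sum(all_nan)))
    mask_idx <- mask_idx[!all_nan]
    Y <- Y[, !all_nan, drop = FALSE]
    mask <- array(FALSE, d[1:3]); mask[mask_idx] <- TRUE
  }

  Xm <- X$X
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    warning("design matrix is rank deficient; using pseudoinverse")
    sv <- svd(Xm)
    pos <- sv$d > max(dim(Xm)) * .Machine$double.eps * sv$d[1]
    B <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  } else {
    B <- qr.coef(qrX, Y)
  }
  resid <- Y - Xm %*% B
  df <- nrow(Xm) - qrX$rank
  s2 <- colSums(resid^2) / max(df, 1L)

  to_map <- function(v) {
    m <- array(NaN, d[1:3])
    m[mask_idx] <- v
    m
  }
  betas <- lapply(seq_len(ncol(Xm)), function(j) to_map(B[j, ]))
  names(betas) <- colnames(Xm)
  structure(list(betas = betas, sigma2 = to_map(s2), df = df,
                 condition_cols = X$condition_cols, mask = mask,
                 affine = affine, run = run),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit: %d regressors over %d voxels (df %d, run %s)\n",
              length(x$betas), sum(x$mask), x$df, as.character(x$run)))
  invisible(x)
}

#' Weighted contrast of condition beta maps
#'
#' Voxel-wise weighted sum of the condition parameter-estimate maps, e.g.
#' `c(dog_face = 0.5, human_face = 0.5, object = -1)` for the pooled
#' faces > objects contrast (conspecific and heterospecific stimuli pooled
#' with equal weights).
#'
#' @param fit a `glm_fit` (or a named list of 3D beta maps).
#' @param weights named numeric vector over condition names.
#' @param label optional contrast label.
#' @return 3D contrast map with attributes `label`, `run`, `affine`.
#' @export
contrast_map <- function(fit, weights, label = NULL) {
  betas <- if (inherits(fit, "glm_fit")) fit$betas else fit
  if (is.null(names(weights))) stopf("`weights` must be named by condition")
  unknown <- setdiff(names(weights), names(betas))
  if (length(unknown))
    stopf("unknown condition(s): %s", paste(unknown, collapse = ", "))
  out <- array(0, dim = dim(betas[[1]]))
  for (cond in names(weights)) out <- out + weights[[cond]] * betas[[cond]]
  attr(out, "label") <- label %||%
    paste(names(weights), sprintf("%+g", weights), collapse = " ")
  attr(out, "run") <- if (inherits(fit, "glm_fit")) fit$run else NA
  attr(out, "affine") <- if (inherits(fit, "glm_fit")) fit$affine else NULL
  out
}

#' Single-block (least-squares-single) GLMs
#'
#' For every block, fits a separate GLM with that block as the task regressor
#' and all remaining blocks of the run combined into one regressor of no
#' interest, plus the shared nuisance set (drift, motion, scrubbing,
#' intercept). Runs are modelled independently. With the default design of 6
#' conditions x 3 blocks x 2 runs this yields the 36 single-trial beta
#' estimates per participant that enter the representational similarity
#' analysis.
#'
#' @param volume a `bold_run` (or 4D array) for one run.
#' @param design the run's `run_design` (needs at least 2 blocks).
#' @param hrf an [hrf_params()] object.
#' @param motion optional n_scans x 6 motion trace.
#' @param scrub_idx scrubbed scan indices.
#' @param mask logical 3D fit mask.
#' @param hpf_cutoff high-pass cut-off (s).
#' @param run run label for the trial metadata.
#' @return Object of class `trial_betas`: list with `maps` (list of 3D
#'   arrays) and `labels` (data.frame condition, run, block).
#' @export
fit_single_block_glms <- function(volume, design, hrf, motion = NULL,
                                  scrub_idx = integer(0), mask = NULL,
                                  hpf_cutoff = 128, run = 1) {
  if (!inherits(design, "run_design")) stopf("`design` must be a run_design")
  nb <- nrow(design$blocks)
  if (nb < 2L) stopf("single-block GLMs need at least 2 blocks")
  n <- design$n_scans
  TR <- design$TR

  ## per-block convolved regressors, computed once
  Xb <- sapply(seq_len(nb), function(b)
    convolve_blocks(design$blocks$onset[b], design$blocks$duration[b],
                    n, TR, hrf))
  nuis <- dct_drift_basis(n, TR, hpf_cutoff)
  if (!is.null(motion))
    nuis <- cbind(nuis, scale(as.matrix(motion), center = TRUE, scale = FALSE))
  if (length(scrub_idx)) {
    S <- matrix(0, n, length(scrub_idx))
    S[cbind(as.integer(scrub_idx), seq_along(scrub_idx))] <- 1
    nuis <- cbind(nuis, S)
  }

  vol <- if (inherits(volume, "bold_run")) volume$data else volume
  d <- dim(vol)
  if (d[4L] != n) stopf("volume scans do not match design")
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  mask_idx <- which(mask)
  Y <- t(matrix(vol, nrow = prod(d[1:3]))[mask_idx, , drop = FALSE])

  other_all <- rowSums(Xb)
  maps <- vector("list", nb)
  for (b in seq_len(nb)) {
    X <- cbind(target = Xb[, b], other = other_all - Xb[, b],
               nuis, intercept = 1)
    beta <- qr.coef(qr(X), Y)[1L, ]
    m <- array(NaN, d[1:3])
    m[mask_idx] <- beta
    maps[[b]] <- m
  }
  structure(list(maps = maps,
                 labels = data.frame(condition = design$blocks$condition,
                                     run = run,
                                     block = seq_len(nb),
                                     stringsAsFactors = FALSE)),
            class = "trial_betas")
}

#' @export
print.trial_betas <- function(x, ...) {
  cat(sprintf("trial_betas: %d single-block beta maps\n", length(x$maps)))
  invisible(x)
}

#' Concatenate single-block fits across runs
#'
#' @param ... `trial_betas` objects (one per run).
#' @return A combined `trial_betas`.
#' @export
combine_trial_betas <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "trial_betas")) parts <- parts[[1]]
  structure(list(maps = do.call(c, lapply(parts, `[[`, "maps")),
                 labels = do.call(rbind, lapply(parts, `[[`, "labels"))),
            class = "trial_betas")
}
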