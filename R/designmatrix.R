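## Boxcar-convolved regressor sampled at scan times.
## Convolution runs on a fine time grid (dt = TR/16 by default) so fractional
## block onsets are honoured; scans are sampled at mid-TR.
convolve_blocks <- function(onsets, durations, n_scans, TR, hrf,
                            dt = TR / 16) {
  t_max <- n_scans * TR
  grid <- seq(0, t_max, by = dt)
  u <- numeric(length(grid))
  durations <- rep(durations, length.out = length(onsets))
  for (b in seq_along(onsets)) {
    on <- onsets[b]
    off <- on + durations[b]
    u[grid >= on & grid < off] <- 1
  }
  k <- hrf_kernel(hrf, dt = dt)
  conv <- convolve(u, rev(k), type = "open")[seq_along(grid)] * dt
  scan_t <- (seq_len(n_scans) - 0.5) * TR
  conv[pmin(length(grid), round(scan_t / dt) + 1L)]
}

#' Discrete-cosine drift basis
#'
#' High-pass filtering is implemented by including slow discrete-cosine
#' regressors: all components with period longer than `cutoff` seconds,
#' i.e. `floor(2 * n_scans * TR / cutoff)` columns.
#'
#' @param n_scans number of scans.
#' @param TR repetition time (s).
#' @param cutoff high-pass cut-off period (s); `Inf` gives no columns.
#' @return n_scans x K matrix (K possibly 0), unit-norm columns.
#' @export
dct_drift_basis <- function(n_scans, TR, cutoff = 128) {
  if (!is.finite(cutoff)) return(matrix(0, n_scans, 0))
  K <- floor(2 * n_scans * TR / cutoff)
  if (K < 1) return(matrix(0, n_scans, 0))
  t <- seq_len(n_scans) - 1L
  X <- sapply(seq_len(K), function(k)
    sqrt(2 / n_scans) * cos(pi * k * (2 * t + 1) / (2 * n_scans)))
  matrix(X, nrow = n_scans, ncol = K,
         dimnames = list(NULL, paste0("drift_", seq_len(K))))
}

#' Build a first-level design matrix
#'
#' One boxcar-convolved column per condition (12-s blocks convolved with the
#' species HRF, sampled at scan times), discrete-cosine drift columns for the
#' 128-s high-pass, the six realignment parameters, one indicator column per
#' scrubbed scan, and an intercept.
#'
#' @param design a `run_design`.
#' @param hrf an [hrf_params()] object.
#' @param motion n_scans x 6 realignment matrix, or NULL to omit.
#' @param scrub_idx scan indices to scrub (one-hot nuisance columns).
#' @param hpf_cutoff high-pass cut-off in seconds (default 128; `Inf` = none).
#' @return Object of class `design_matrix`: list with `X`, `condition_cols`
#'   (named column indices), `n_scans`, `TR`, `rank_deficient` flag.
#' @export
build_design_matrix <- function(design, hrf, motion = NULL,
                                scrub_idx = integer(0), hpf_cutoff = 128) {
  if (!inherits(design, "run_design")) stopf("`design` must be a run_design")
  if (nrow(design$blocks) == 0L) stopf("design contains no blocks")
  n <- design$n_scans
  TR <- design$TR
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n || ncol(motion) != 6L)
      stopf("`motion` must be %d x 6", n)
  }
  scrub_idx <- as.integer(scrub_idx)
  if (length(scrub_idx) && (any(scrub_idx < 1L) || any(scrub_idx > n)))
    stopf("scrub indices out of 1..%d", n)

  conds <- intersect(study_conditions(), unique(design$blocks$condition))
  Xc <- sapply(conds, function(cond) {
    sel <- design$blocks$condition == cond
    convolve_blocks(design$blocks$onset[sel], design$blocks$duration[sel],
                    n, TR, hrf)
  })
  Xc <- matrix(Xc, nrow = n, dimnames = list(NULL, conds))

  Xd <- dct_drift_basis(n, TR, hpf_cutoff)
  Xm <- if (is.null(motion)) matrix(0, n, 0) else
    scale(motion, center = TRUE, scale = FALSE)
  if (ncol(Xm)) colnames(Xm) <- paste0("mot_", colnames(motion) %||% 1:6)
  Xs <- matrix(0, n, length(scrub_idx))
  if (length(scrub_idx)) {
    Xs[cbind(scrub_idx, seq_along(scrub_idx))] <- 1
    colnames(Xs) <- paste0("scrub_", scrub_idx)
  }
  X <- cbind(Xc, Xd, Xm, Xs, intercept = 1)
  rank <- qr(X)$rank
  structure(list(X = X,
                 condition_cols = setNames(match(conds, colnames(X)), conds),
                 n_scans = n, TR = TR,
                 rank_deficient = rank < ncol(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d scans x %d regressors (%d conditions)%s\n",
              nrow(x$X), ncol(x$X), length(x$condition_cols),
              if (x$rank_deficient) " [RANK DEFICIENT]" else ""))
  invisible(x)
}
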