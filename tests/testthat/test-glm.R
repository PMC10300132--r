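test_that("HRF kernels have the canonical shape and species timing", {
  kh <- hrf_kernel(hrf_params("human"), dt = 0.01)
  th <- attr(kh, "time")
  expect_equal(kh[1], 0)                        # zero at origin, shape > 1
  expect_equal(max(kh), 1)                      # peak-normalised
  peak_h <- th[which.max(kh)]
  expect_gte(peak_h, 4); expect_lte(peak_h, 6.5)
  expect_lt(min(kh), 0)                         # undershoot present
  expect_gt(which.min(kh), which.max(kh))       # ...after the peak
  kd <- hrf_kernel(hrf_params("dog"), dt = 0.01)
  peak_d <- attr(kd, "time")[which.max(kd)]
  expect_gte(peak_h - peak_d, 2)
  expect_lte(peak_h - peak_d, 3)
  expect_error(hrf_params(peak_dispersion = -1), "positive")
})

test_that("design matrix has the specified column structure", {
  ss <- generate_stimulus_set(30, seed = 12)
  des <- make_subject_designs(ss, seed = 13)[[1]]
  n <- des$n_scans
  mo <- simulate_motion_trace(n, seed = 14)
  X <- build_design_matrix(des, hrf_params("dog"), motion = mo,
                           scrub_idx = c(10L, 20L))
  K <- floor(2 * n * des$TR / 128)
  expect_equal(ncol(X$X), 6 + K + 6 + 2 + 1)
  expect_named(X$condition_cols, study_conditions(), ignore.order = TRUE)
  expect_false(X$rank_deficient)
  ## drift count formula cross-checked: 300 scans at TR 1 -> 4 columns
  expect_equal(ncol(dct_drift_basis(300, 1, 128)), 4)
  ## independent spectral check: each DCT column's dominant period > cutoff
  D <- dct_drift_basis(300, 1, 128)
  for (k in seq_len(ncol(D))) {
    sp <- Mod(fft(D[, k]))[2:150]
    expect_gt(300 / which.max(sp), 128 * 0.95)
  }
  expect_equal(ncol(dct_drift_basis(300, 1, Inf)), 0)
  ## scrub columns are orthogonal one-hot vectors
  S <- X$X[, grep("^scrub_", colnames(X$X)), drop = FALSE]
  expect_equal(colSums(S), c(scrub_10 = 1, scrub_20 = 1))
  expect_equal(crossprod(S), diag(2), ignore_attr = TRUE)
  expect_error(build_design_matrix(des, hrf_params("dog"), scrub_idx = n + 1),
               "out of")
  empty <- des; empty$blocks <- des$blocks[0, ]
  expect_error(build_design_matrix(empty, hrf_params("dog")), "no blocks")
})

test_that("framewise displacement combines translations and rotations", {
  m <- matrix(0, 10, 6)
  expect_equal(compute_fd(m, 50), rep(0, 10))
  m[5:10, 1] <- 0.5; m[1:4, 1] <- 0.2           # x-translation step 0.2 -> 0.5
  fd <- compute_fd(m, 50)
  expect_equal(fd[5], 0.3)
  expect_equal(fd[6], 0)
  m2 <- matrix(0, 5, 6); m2[3:5, 4] <- 0.01     # pitch step, radius 50
  expect_equal(compute_fd(m2, 50)[3], 0.5)
  ## invariance to constant offset
  m3 <- matrix(rnorm(60), 10, 6)
  off <- matrix(rep(c(1, -2, 0.5, 0.1, 0.2, -0.1), each = 10), 10, 6)
  expect_equal(compute_fd(m3 + off, 40), compute_fd(m3, 40))
  ## scrubbing picks exactly the exceedances
  fd4 <- c(0, 0.2, 0.8, 0.3, 0.6, 0.1, 0.9, 0.2)
  expect_equal(as.integer(scrub_indices(fd4, 0.5)), c(3, 5, 7))
  expect_length(scrub_indices(rep(0.1, 10), 0.5), 0)
})

test_that("GLM betas equal the normal-equations oracle", {
  set.seed(15)
  dim <- c(4, 3, 2); n <- 40
  Y <- array(rnorm(prod(dim) * n), dim = c(dim, n))
  ss <- generate_stimulus_set(30, seed = 16)
  des <- make_subject_designs(ss, TR = 5, seed = 17)[[1]]
  des$n_scans <- n  # truncate to a small synthetic problem
  des$blocks <- des$blocks[des$blocks$onset < n * 5 - 20, ]
  X <- build_design_matrix(des, hrf_params("human"))
  fit <- fit_glm(Y, X)
  B_oracle <- solve(crossprod(X$X)) %*% t(X$X) %*%
    t(matrix(Y, nrow = prod(dim)))
  for (j in seq_len(ncol(X$X))) {
    expect_equal(as.vector(fit$betas[[j]]), unname(B_oracle[j, ]),
                 tolerance = 1e-8)
  }
})

test_that("intercept-only design returns the time-series mean", {
  dim <- c(3, 3, 2); n <- 25
  set.seed(18)
  Y <- array(rnorm(prod(dim) * n, mean = 7), dim = c(dim, n))
  X <- structure(list(X = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
                      condition_cols = integer(0), n_scans = n, TR = 1,
                      rank_deficient = FALSE), class = "design_matrix")
  fit <- fit_glm(Y, X)
  expect_equal(as.vector(fit$betas$intercept),
               as.vector(apply(Y, 1:3, mean)), tolerance = 1e-12)
})

test_that("noiseless simulation is recovered exactly through the GLM", {
  tr <- tiny_truth()
  ses <- small_session(tr, seed = 19)
  X <- build_design_matrix(ses$designs[[1]], tr$hrf)
  fit <- fit_glm(ses$run1, X, mask = tr$mask)
  vox <- tr$regions$r1
  A <- tr$amplitudes
  for (cn in study_conditions()) {
    expect_lt(max(abs(fit$betas[[cn]][vox] - A[1, cn])), 1e-8)
  }
  expect_lt(max(abs(fit$betas$intercept[vox] - tr$baseline)), 1e-8)
  ## off-region in-mask voxels carry zero amplitude
  off_vox <- setdiff(which(tr$mask), vox)[1:50]
  expect_lt(max(abs(fit$betas$dog_body[off_vox])), 1e-8)
})

test_that("high-pass residualization leaves condition betas unchanged", {
  ## Frisch-Waugh: projecting out the drift columns from Y and the task
  ## columns gives the same task coefficients
  set.seed(20)
  tr <- tiny_truth(noise_sd = 1, drift_sd = 2)
  ses <- small_session(tr, seed = 20)
  X <- build_design_matrix(ses$designs[[1]], tr$hrf)
  fit <- fit_glm(ses$run1, X, mask = tr$mask)
  drift_cols <- grep("^drift_|^intercept$", colnames(X$X))
  D <- X$X[, drift_cols, drop = FALSE]
  Tk <- X$X[, -drift_cols, drop = FALSE]
  P <- diag(nrow(D)) - D %*% solve(crossprod(D)) %*% t(D)
  vox <- which(tr$mask)[seq(1, sum(tr$mask), length.out = 30)]
  flat <- matrix(ses$run1$data, nrow = prod(tr$dim))
  Yv <- t(flat[vox, , drop = FALSE])
  B2 <- solve(crossprod(P %*% Tk)) %*% t(P %*% Tk) %*% (P %*% Yv)
  for (cn in study_conditions()) {
    j <- match(cn, colnames(Tk))
    expect_equal(unname(B2[j, ]), unname(fit$betas[[cn]][vox]),
                 tolerance = 1e-8)
  }
})

test_that("contrast maps are linear in the betas", {
  tr <- tiny_truth()
  ses <- small_session(tr, seed = 23)
  X <- build_design_matrix(ses$designs[[1]], tr$hrf)
  fit <- fit_glm(ses$run1, X, mask = tr$mask, run = 1)
  z <- contrast_map(fit, c(dog_face = 0, human_face = 0))
  expect_true(all(z[tr$mask] == 0))
  ## pooled faces contrast equals the mean of the single-species contrasts
  pooled <- contrast_map(fit, c(dog_face = 0.5, human_face = 0.5,
                                object = -1))
  d1 <- contrast_map(fit, c(dog_face = 1, object = -1))
  d2 <- contrast_map(fit, c(human_face = 1, object = -1))
  expect_equal(pooled[tr$mask], ((d1 + d2) / 2)[tr$mask], tolerance = 1e-12)
  ## planted difference appears in the region
  vox <- tr$regions$r1
  fo <- contrast_map(fit, c(dog_face = 1, object = -1))
  expect_equal(unname(fo[vox]),
               rep(tr$amplitudes[1, "dog_face"] - tr$amplitudes[1, "object"],
                   length(vox)), tolerance = 1e-8)
  expect_error(contrast_map(fit, c(unicorn = 1)), "unknown condition")
  expect_equal(attr(pooled, "run"), 1)
})

test_that("single-block GLMs recover equal planted amplitudes exactly", {
  tr <- tiny_truth(amplitudes = rep(2, 6))
  ses <- small_session(tr, seed = 24)
  tb1 <- fit_single_block_glms(ses$run1, ses$designs[[1]], tr$hrf,
                               mask = tr$mask, run = 1)
  expect_length(tb1$maps, 18)
  expect_equal(tb1$labels$condition, ses$designs[[1]]$blocks$condition)
  vox <- tr$regions$r1[1]
  vals <- vapply(tb1$maps, function(m) m[vox], numeric(1))
  expect_lt(max(abs(vals - 2)), 1e-6)
  ## single-block run is rejected
  one <- ses$designs[[1]]; one$blocks <- one$blocks[1, ]
  expect_error(fit_single_block_glms(ses$run1, one, tr$hrf), "at least 2")
})

test_that("per-block beta means approximate the condition-level betas", {
  tr <- tiny_truth(amplitudes = c(2, 3, 1, 0.5, 1.5, 0.2))
  ses <- small_session(tr, seed = 25)
  X <- build_design_matrix(ses$designs[[1]], tr$hrf)
  fit <- fit_glm(ses$run1, X, mask = tr$mask)
  tb <- fit_single_block_glms(ses$run1, ses$designs[[1]], tr$hrf,
                              mask = tr$mask)
  vox <- tr$regions$r1[1]
  for (cn in study_conditions()) {
    per_block <- mean(vapply(which(tb$labels$condition == cn),
                             function(b) tb$maps[[b]][vox], numeric(1)))
    ## single-block models share the HRF overlap between blocks with the
    ## combined nuisance regressor, so agreement is approximate
    expect_lt(abs(per_block - fit$betas[[cn]][vox]), 0.25)
  }
})
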