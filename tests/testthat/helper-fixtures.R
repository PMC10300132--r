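## Shared fixtures: everything is generated in code at test time.

## A one-region ground truth on a small grid, full-cube mask.
tiny_truth <- function(dim = c(16, 16, 12),
                       amplitudes = c(2, 3, 1, 0.5, 1.5, 0.2),
                       noise_sd = 0, drift_sd = 0, subject_gain_sd = 0,
                       region = NULL, ...) {
  region <- region %||% box_region(dim, c(4, 6), c(4, 6), c(5, 7))
  A <- matrix(amplitudes, 1, 6,
              dimnames = list("r1", study_conditions()))
  make_ground_truth(dim, 1.5, list(r1 = region), A,
                    mask = make_brain_mask(dim), noise_sd = noise_sd,
                    drift_sd = drift_sd, subject_gain_sd = subject_gain_sd,
                    ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stimuli + two-run design + one simulated run, reused across GLM tests.
small_session <- function(truth, seed = 11) {
  ss <- generate_stimulus_set(30, seed = seed)
  des <- make_subject_designs(ss, seed = seed + 1)
  run1 <- simulate_bold_run(des[[1]], truth, seed = seed + 2)
  list(stimuli = ss, designs = des, run1 = run1)
}

## Random trial stack: n_blocks blocks per condition over two runs.
random_trial_stack <- function(dim = c(10, 10, 6), n_blocks = 6, seed = 42,
                               mask = array(TRUE, dim)) {
  set.seed(seed)
  conds <- rep(study_conditions(), each = n_blocks)
  maps <- lapply(seq_along(conds), function(i) array(rnorm(prod(dim)), dim))
  tb <- structure(list(
    maps = maps,
    labels = data.frame(condition = conds,
                        run = rep(1:2, length.out = length(conds)),
                        block = seq_along(conds))), class = "trial_betas")
  trial_pattern_stack(tb, mask)
}

## Independent searchlight oracle: plain triple loop, no shared machinery
## beyond the offset table.
naive_searchlight <- function(stack, spec, sel, cap = 1 - 1e-6) {
  d <- stack$dim
  out <- array(NaN, d)
  centers <- valid_centers(stack$mask, spec)
  sel_idx <- which(sel)
  for (ctr in centers) {
    k0 <- (ctr - 1) %/% (d[1] * d[2]) + 1
    rem <- (ctr - 1) %% (d[1] * d[2])
    j0 <- rem %/% d[1] + 1
    i0 <- rem %% d[1] + 1
    vox <- c()
    for (o in seq_len(nrow(spec$offsets))) {
      p <- c(i0, j0, k0) + spec$offsets[o, ]
      if (all(p >= 1) && all(p <= d)) {
        li <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (stack$mask[li]) vox <- c(vox, li)
      }
    }
    if (length(vox) < 2) next
    zs <- c()
    for (a in seq_along(sel_idx)) {
      for (b in seq_along(sel_idx)) {
        if (a < b) {
          r <- cor(stack$patterns[vox, sel_idx[a]],
                   stack$patterns[vox, sel_idx[b]])
          zs <- c(zs, atanh(min(max(r, -cap), cap)))
        }
      }
    }
    out[ctr] <- mean(zs)
  }
  out
}
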