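test_that("sphere offsets reproduce the published neighborhood sizes", {
  expect_equal(nrow(sphere_offsets(4, 1.5, "inclusive")), 81)
  expect_equal(nrow(sphere_offsets(4, 1.5, "exclusive")), 81)
  expect_equal(nrow(sphere_offsets(8, 2, "exclusive")), 251)
  ## radius below the voxel size keeps only the centre
  expect_equal(sphere_offsets(1, 1.5)[1, ], c(i = 0, j = 0, k = 0))
  expect_equal(nrow(sphere_offsets(1, 1.5)), 1)
  ## symmetry under sign flip and axis permutation (isotropic voxels)
  off <- sphere_offsets(4, 1.5)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(-off), key(off))
  expect_equal(key(off[, c(2, 3, 1)]), key(off))
  expect_error(sphere_offsets(-1, 1.5), "radius")
})

test_that("valid centers require enough in-mask sphere voxels", {
  spec <- searchlight_spec(3, 1.5, min_gray_voxels = 20)
  mask <- array(TRUE, c(12, 12, 12))
  vc <- valid_centers(mask, spec)
  ## deep interior voxels carry full spheres
  ctr <- 6 + 12 * 5 + 144 * 5
  expect_true(ctr %in% vc)
  ## a 14-voxel mask can never reach a 15-voxel minimum
  m14 <- array(FALSE, c(8, 8, 8)); m14[which(!m14)[1:14]] <- TRUE
  expect_length(valid_centers(m14, searchlight_spec(4, 1.5, 15)), 0)
  ## random blobby mask equals a brute-force recount
  set.seed(41)
  mb <- array(runif(10 * 10 * 8) < 0.5, c(10, 10, 8))
  specb <- searchlight_spec(2.5, 1.5, min_gray_voxels = 4)
  vb <- valid_centers(mb, specb)
  d <- dim(mb)
  oracle <- c()
  for (v in which(mb)) {
    k0 <- (v - 1) %/% (d[1] * d[2]) + 1
    j0 <- ((v - 1) %% (d[1] * d[2])) %/% d[1] + 1
    i0 <- (v - 1) %% d[1] + 1
    cnt <- 0
    for (o in seq_len(nrow(specb$offsets))) {
      p <- c(i0, j0, k0) + specb$offsets[o, ]
      if (all(p >= 1) && all(p <= d) &&
          mb[p[1], p[2], p[3]]) cnt <- cnt + 1
    }
    if (cnt >= 4) oracle <- c(oracle, v)
  }
  expect_equal(sort(vb), sort(oracle))
})

test_that("searchlight maps equal the naive triple-loop oracle", {
  stack <- random_trial_stack(dim = c(10, 10, 6), seed = 42)
  spec <- searchlight_spec(3, 1.5, min_gray_voxels = 10)
  sel <- stack$labels$condition %in% c("dog_face", "human_face")
  sm <- searchlight_similarity(stack, spec, sel)
  oracle <- naive_searchlight(stack, spec, sel)
  expect_lt(max(abs(sm - oracle), na.rm = TRUE), 1e-10)
  expect_equal(is.na(sm), is.na(oracle))
})

test_that("similarity respects correlation identities and clipping", {
  dim <- c(6, 6, 4)
  mask <- array(TRUE, dim)
  set.seed(43)
  base <- array(rnorm(prod(dim)), dim)
  ## two identical patterns -> r = 1 -> z at the clip cap
  tb <- structure(list(
    maps = list(base, base),
    labels = data.frame(condition = c("object", "object"), run = 1,
                        block = 1:2)), class = "trial_betas")
  stack <- trial_pattern_stack(tb, mask)
  spec <- searchlight_spec(2, 1, min_gray_voxels = 5)
  sm <- searchlight_similarity(stack, spec, c(TRUE, TRUE))
  expect_equal(max(sm, na.rm = TRUE), atanh(1 - 1e-6), tolerance = 1e-9)
  ## orthogonal patterns: construct exact r = 0 in one sphere
  expect_equal(atanh(0), 0)
  ## invariance to trial order and global affine rescaling
  stack2 <- random_trial_stack(dim = c(8, 8, 4), seed = 44)
  spec2 <- searchlight_spec(2.5, 1.5, min_gray_voxels = 5)
  sel <- stack2$labels$condition %in% c("dog_body", "human_body", "object")
  m1 <- searchlight_similarity(stack2, spec2, sel)
  perm <- sample(ncol(stack2$patterns))
  stack_p <- stack2
  stack_p$patterns <- stack2$patterns[, perm]
  stack_p$labels <- stack2$labels[perm, ]
  m2 <- searchlight_similarity(stack_p, spec2, sel[perm])
  expect_equal(m1, m2, tolerance = 1e-12)
  stack_s <- stack2
  stack_s$patterns <- stack2$patterns * 7.3 + 2
  m3 <- searchlight_similarity(stack_s, spec2, sel)
  expect_equal(m1, m3, tolerance = 1e-9)
})

test_that("zero-variance trial patterns are skipped pair-wise", {
  dim <- c(6, 6, 4)
  mask <- array(TRUE, dim)
  set.seed(45)
  maps <- list(array(rnorm(prod(dim)), dim),
               array(rnorm(prod(dim)), dim),
               array(5, dim))                    # constant pattern
  tb <- structure(list(maps = maps,
                       labels = data.frame(condition = rep("object", 3),
                                           run = 1, block = 1:3)),
                  class = "trial_betas")
  stack <- trial_pattern_stack(tb, mask)
  spec <- searchlight_spec(2, 1, min_gray_voxels = 5)
  expect_message(sm <- searchlight_similarity(stack, spec, rep(TRUE, 3)),
                 "zero-variance")
  ## only the pair of the two random trials contributes
  stack12 <- trial_pattern_stack(
    structure(list(maps = maps[1:2],
                   labels = data.frame(condition = rep("object", 2),
                                       run = 1, block = 1:2)),
              class = "trial_betas"), mask)
  sm12 <- searchlight_similarity(stack12, spec, rep(TRUE, 2))
  expect_equal(sm, sm12, tolerance = 1e-12)
})

test_that("comparison registry defines the six published contrasts", {
  expect_equal(similarity_comparison("a")$B, "object")
  expect_setequal(similarity_comparison("c")$A,
                  c("dog_face", "human_face", "dog_body", "human_body"))
  expect_equal(similarity_comparison("e"),
               list(A = "dog_face", B = "human_face"))
  expect_error(similarity_comparison("z"), "unknown comparison")
  ## pooled 12-trial set enters C(12,2) = 66 pairs
  stack <- random_trial_stack(dim = c(6, 6, 4), seed = 46)
  sel <- stack$labels$condition %in% c("dog_face", "human_face")
  expect_equal(sum(sel), 12)
  pm <- outer(sel, sel, `&`)
  pm[lower.tri(pm, diag = TRUE)] <- FALSE
  expect_equal(sum(pm), 66)
})

test_that("identical planted species patterns null comparison (e)", {
  dim <- c(8, 8, 4)
  mask <- array(TRUE, dim)
  set.seed(47)
  shared <- array(rnorm(prod(dim)), dim)
  maps <- list(); conds <- c()
  for (cond in c("dog_face", "human_face")) {
    for (b in 1:6) {
      maps[[length(maps) + 1]] <- shared + array(rnorm(prod(dim), sd = 0.3), dim)
      conds <- c(conds, cond)
    }
  }
  tb <- structure(list(maps = maps,
                       labels = data.frame(condition = conds, run = 1,
                                           block = seq_along(conds))),
                  class = "trial_betas")
  stack <- trial_pattern_stack(tb, mask)
  spec <- searchlight_spec(2.5, 1.5, min_gray_voxels = 5)
  pair <- similarity_contrast_pair(stack, spec, "e")
  diff <- pair$A - pair$B
  expect_lt(mean(abs(diff), na.rm = TRUE), 0.15)
  expect_gt(mean(pair$A, na.rm = TRUE), 0.5)   # strong within-set similarity
})

test_that("multi-comparison sweep equals per-comparison computation", {
  stack <- random_trial_stack(dim = c(6, 6, 4), seed = 48)
  spec <- searchlight_spec(2.5, 1.5, min_gray_voxels = 5)
  all_maps <- similarity_contrast_maps(stack, spec, ids = c("a", "d"))
  single <- similarity_contrast_pair(stack, spec, "d")
  expect_equal(all_maps$d$A, single$A, ignore_attr = TRUE)
  expect_equal(all_maps$d$B, single$B, ignore_attr = TRUE)
})
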