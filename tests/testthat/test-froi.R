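## shared toy maps for selection tests
froi_fixture <- function(seed = 31, dim = c(10, 8, 6)) {
  set.seed(seed)
  mask <- array(TRUE, dim)
  space <- search_space("toy", mask, default_affine(dim, 1.5))
  pref <- array(rnorm(prod(dim)), dim); attr(pref, "run") <- 1
  targ <- array(rnorm(prod(dim)), dim); attr(targ, "run") <- 1
  list(dim = dim, space = space, pref = pref, targ = targ)
}

test_that("top-percent selection matches an exhaustive sort oracle", {
  fx <- froi_fixture()
  fr <- define_froi(fx$pref, fx$targ, fx$space, top_pct = 10)
  for (h in c("left", "right")) {
    sp <- fx$space$voxels[[h]]
    pref_vox <- sp[fx$pref[sp] > 0]
    k <- max(1, ceiling(0.10 * length(pref_vox)))
    oracle <- pref_vox[order(fx$targ[pref_vox], decreasing = TRUE)][1:k]
    expect_setequal(fr$voxels[[h]], oracle)
  }
  ## degenerate: top 100% keeps every preference voxel
  fr100 <- define_froi(fx$pref, fx$targ, fx$space, top_pct = 100)
  all_pref <- unlist(lapply(fx$space$voxels, function(sp) sp[fx$pref[sp] > 0]))
  expect_setequal(froi_voxels(fr100), all_pref)
  ## arithmetic: 100 preference voxels at 10% -> 10 selected
  dim <- c(10, 10, 2)
  pref2 <- array(-1, dim); pref2[1:5, , ] <- 1  # 100 positives, all left
  targ2 <- array(rnorm(200), dim)
  attr(pref2, "run") <- 1; attr(targ2, "run") <- 1
  sp2 <- search_space("half", array(TRUE, dim), default_affine(dim, 1))
  suppressMessages(fr2 <- define_froi(pref2, targ2, sp2, top_pct = 10))
  expect_length(fr2$voxels$left, 10)
  expect_length(fr2$voxels$right, 0)
})

test_that("fROIs are monotone in the top-percent threshold", {
  fx <- froi_fixture(seed = 32)
  pcts <- c(1, 5, 10, 25, 50, 100)
  frois <- lapply(pcts, function(p)
    froi_voxels(define_froi(fx$pref, fx$targ, fx$space, top_pct = p)))
  for (i in seq_len(length(pcts) - 1)) {
    expect_true(all(frois[[i]] %in% frois[[i + 1]]))
  }
})

test_that("hemisphere handling and degenerate preference maps", {
  dim <- c(10, 8, 6)
  pref <- array(0, dim)
  targ <- array(rnorm(prod(dim)), dim)
  sp <- search_space("toy", array(TRUE, dim), default_affine(dim, 1.5))
  ## positive preference only in right hemisphere (x index > 5)
  pref[sp$voxels$right[1:20]] <- 1
  expect_message(fr <- define_froi(pref, targ, sp), "left hemisphere")
  expect_length(fr$voxels$left, 0)
  expect_gt(length(fr$voxels$right), 0)
  ## no preference voxels anywhere -> error
  expect_error(define_froi(array(-1, dim), targ, sp), "either hemisphere")
  ## invalid threshold
  expect_error(define_froi(targ, targ, sp, top_pct = 0), "top_pct")
})

test_that("extraction means match a direct loop and respect split-half", {
  fx <- froi_fixture(seed = 33)
  fr <- define_froi(fx$pref, fx$targ, fx$space)
  cmap <- array(rnorm(prod(fx$dim)), fx$dim); attr(cmap, "run") <- 2
  means <- extract_froi_means(list(bodies = cmap), fr)
  oracle <- mean(sapply(froi_voxels(fr), function(v) cmap[v]))
  expect_equal(unname(means["bodies"]), oracle, tolerance = 1e-12)
  ## constant map
  cc <- array(3.5, fx$dim); attr(cc, "run") <- 2
  expect_equal(unname(extract_froi_means(list(x = cc), fr)["x"]), 3.5)
  ## two-voxel mean
  fr2 <- fr; fr2$voxels <- list(left = froi_voxels(fr)[1:2], right = integer(0))
  v12 <- array(0, fx$dim); v12[fr2$voxels$left] <- c(1, 3)
  attr(v12, "run") <- 2
  expect_equal(unname(extract_froi_means(list(x = v12), fr2)["x"]), 2)
  ## NaN voxels excluded with a message; same-run extraction rejected
  cnan <- cmap; cnan[froi_voxels(fr)[1]] <- NaN
  expect_message(m2 <- extract_froi_means(list(x = cnan), fr), "excluded")
  vox <- setdiff(froi_voxels(fr), froi_voxels(fr)[1])
  expect_equal(unname(m2["x"]), mean(cmap[vox]), tolerance = 1e-12)
  same_run <- cmap; attr(same_run, "run") <- 1
  expect_error(extract_froi_means(list(x = same_run), fr), "split-half")
})

test_that("one-way repeated-measures ANOVA matches the SS decomposition", {
  ## identical columns -> F = 0, p = 1
  v <- matrix(rep(rnorm(6), 3), 6, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  r0 <- rm_anova_oneway(v)
  expect_equal(r0$F, 0); expect_equal(r0$p, 1)
  ## two conditions: F equals the squared paired t
  set.seed(34)
  v2 <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  r2 <- rm_anova_oneway(v2)
  tt <- t.test(v2[, 1] - v2[, 2])
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  ## random 8 x 3 table vs explicit sums of squares
  v3 <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  r3 <- rm_anova_oneway(v3)
  gm <- mean(v3)
  ss_cond <- 8 * sum((colMeans(v3) - gm)^2)
  ss_subj <- 3 * sum((rowMeans(v3) - gm)^2)
  ss_tot <- sum((v3 - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_oracle <- (ss_cond / 2) / (ss_err / 14)
  expect_equal(r3$F, F_oracle, tolerance = 1e-10)
  expect_equal(r3$df1, 2); expect_equal(r3$df2, 14)
  expect_equal(r3$p, pf(F_oracle, 2, 14, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(nrow(r3$pairwise), 3)
  expect_error(rm_anova_oneway(v3[, 1, drop = FALSE]), ">= 2")
  v3[2, 2] <- NA
  expect_error(rm_anova_oneway(v3), "missing cell")
})

test_that("2x2 within-subject ANOVA matches an aov oracle", {
  cols <- c("conspecific_face", "heterospecific_face",
            "conspecific_body", "heterospecific_body")
  ## all identical -> all F = 0
  v0 <- matrix(rep(rnorm(6), 4), 6, 4, dimnames = list(NULL, cols))
  expect_true(all(rm_anova_2x2(v0)$F == 0))
  ## pure interaction (+d, -d, -d, +d): main effects ~ 0
  set.seed(35)
  base <- rnorm(10)
  d <- 0.8
  vi <- cbind(base + d, base - d, base - d, base + d) +
    matrix(rnorm(40, sd = 0.1), 10, 4)
  colnames(vi) <- cols
  ri <- rm_anova_2x2(vi)
  expect_gt(ri$F[ri$effect == "species:category"], 10)
  ## random table: cross-check against aov with Error strata
  vr <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, cols))
  rr <- rm_anova_2x2(vr)
  dat <- data.frame(
    y = as.vector(vr),
    species = factor(rep(rep(c("c", "h"), 2), each = 8)),
    category = factor(rep(c("face", "body"), each = 16)),
    subject = factor(rep(1:8, 4)))
  a <- summary(aov(y ~ species * category +
                     Error(subject / (species * category)), data = dat))
  F_sp <- a[["Error: subject:species"]][[1]]["species", "F value"]
  F_cat <- a[["Error: subject:category"]][[1]]["category", "F value"]
  F_int <- a[["Error: subject:species:category"]][[1]][
    "species:category", "F value"]
  expect_equal(rr$F[rr$effect == "species"], F_sp, tolerance = 1e-8)
  expect_equal(rr$F[rr$effect == "category"], F_cat, tolerance = 1e-8)
  expect_equal(rr$F[rr$effect == "species:category"], F_int,
               tolerance = 1e-8)
  expect_true(all(rr$df1 == 1) && all(rr$df2 == 7))
  expect_equal(nrow(attr(rr, "pairwise")), 6)
})

test_that("threshold sweep is consistent with the main analysis", {
  fx <- froi_fixture(seed = 36)
  test_map <- array(rnorm(prod(fx$dim)), fx$dim); attr(test_map, "run") <- 2
  tm <- list(bodies = test_map)
  sw <- froi_threshold_sweep(fx$pref, fx$targ, fx$space, tm,
                             pct_grid = c(10, 100))
  ## grid = 100 equals whole-preference-mask means
  fr100 <- define_froi(fx$pref, fx$targ, fx$space, top_pct = 100)
  expect_equal(sw$mean[sw$top_pct == 100],
               unname(extract_froi_means(tm, fr100)["bodies"]))
  ## grid = 10 reproduces the main analysis
  fr10 <- define_froi(fx$pref, fx$targ, fx$space, top_pct = 10)
  expect_equal(sw$mean[sw$top_pct == 10],
               unname(extract_froi_means(tm, fr10)["bodies"]))
  expect_error(froi_threshold_sweep(fx$pref, fx$targ, fx$space, tm,
                                    pct_grid = c(0, 10)), "pct_grid")
})

test_that("subsample resampling covers the degenerate and powered cases", {
  set.seed(37)
  ## n_sub = n: every iteration reproduces the full-sample ANOVA
  v <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  full <- rm_anova_oneway(v)
  rs <- resample_subsamples(v, n_sub = 10, n_iter = 5, seed = 1)
  expect_true(all(abs(rs$F - full$F) < 1e-12))
  ## planted strong effect: almost every subsample significant
  v2 <- cbind(a = rnorm(40, 2), b = rnorm(40), c = rnorm(40))
  rs2 <- resample_subsamples(v2, n_sub = 15, n_iter = 100, seed = 2)
  expect_gte(attr(rs2, "significant_fraction"), 0.95)
  expect_error(resample_subsamples(v, n_sub = 11), "exceeds")
})

test_that("fROI serialization round-trips through NIfTI + JSON", {
  fx <- froi_fixture(seed = 38)
  fr <- define_froi(fx$pref, fx$targ, fx$space, name = "toy_body")
  path <- tempfile(fileext = ".nii.gz")
  write_froi(fr, path, default_affine(fx$dim, 1.5))
  back <- read_volume(path)
  expect_setequal(which(back$data == 1), fr$voxels$left)
  expect_setequal(which(back$data == 2), fr$voxels$right)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$top_pct, 10)
  expect_equal(side$search_space, "toy")
})
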