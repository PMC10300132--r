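## 18-connectivity neighbour offsets (faces + edges, no corners)
connectivity_offsets <- function(connectivity = 18) {
  g <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  d <- abs(g$i) + abs(g$j) + abs(g$k)
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stopf("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, ])
}

#' Label connected clusters of supra-threshold voxels
#'
#' Flood-fill connected-component labelling on a 3D logical array using
#' 18-connectivity by default (voxels sharing a face or an edge are
#' neighbours).
#'
#' @param supra logical 3D array (TRUE = supra-threshold).
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array of cluster labels (0 = background), with the
#'   cluster sizes as attribute `extents`.
#' @export
label_clusters <- function(supra, connectivity = 18) {
  d <- dim(supra)
  lab <- array(0L, d)
  idx <- which(supra)
  if (!length(idx)) {
    attr(lab, "extents") <- integer(0)
    return(lab)
  }
  offs <- connectivity_offsets(connectivity)
  n_off <- nrow(offs)
  current <- 0L
  extents <- integer(0)
  for (seed_idx in idx) {
    if (lab[seed_idx] != 0L) next
    current <- current + 1L
    queue <- seed_idx
    lab[seed_idx] <- current
    size <- 0L
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      size <- size + length(v)
      ijk <- index_to_ijk(v, d)
      for (o in seq_len(n_off)) {
        ni <- ijk[, 1L] + offs[o, 1L]
        nj <- ijk[, 2L] + offs[o, 2L]
        nk <- ijk[, 3L] + offs[o, 3L]
        ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] &
              nk >= 1L & nk <= d[3L]
        if (!any(ok)) next
        nidx <- ijk_to_index(cbind(ni[ok], nj[ok], nk[ok]), d)
        new <- nidx[supra[nidx] & lab[nidx] == 0L]
        if (length(new)) {
          lab[new] <- current
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
    extents[current] <- size
  }
  attr(lab, "extents") <- extents
  lab
}

## Stack per-subject 3D maps into subjects x voxels matrix over a mask.
stack_maps <- function(maps, mask = NULL) {
  if (is.array(maps) && length(dim(maps)) == 4L)
    maps <- lapply(seq_len(dim(maps)[4]), function(s) maps[, , , s])
  d <- dim(maps[[1]])
  if (is.null(mask)) {
    finite <- Reduce(`&`, lapply(maps, is.finite))
    mask <- finite
  }
  idx <- which(mask)
  M <- do.call(rbind, lapply(maps, function(m) m[idx]))
  list(M = M, mask = mask, idx = idx, dim = d)
}

## Sign-flip matrix: exhaustive (all 2^n rows, identity first) or sampled.
signflip_matrix <- function(n, n_perm, seed) {
  if (2^n <= n_perm) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))[, n:1, drop = FALSE]
    S <- S[order(rowSums(S == -1)), , drop = FALSE]   # identity row first
    dimnames(S) <- NULL
    attr(S, "exhaustive") <- TRUE
    return(S)
  }
  set.seed(substream_seed(seed, "signflips"))
  S <- matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n_perm, n)
  attr(S, "exhaustive") <- FALSE
  S
}

## Vectorised one-sample t statistics for many sign-flip patterns.
## D: subjects x voxels; S: perms x subjects of +-1. Sign flips leave the
## per-voxel sum of squares unchanged, so only the flipped means vary.
signflip_tmaps <- function(D, S) {
  n <- nrow(D)
  q <- colSums(D^2)                    # fixed under sign flips
  M <- (S %*% D) / n                   # perms x voxels means
  V <- sweep(-M^2, 2, q / n, `+`) * (n / (n - 1))
  V[V < 0] <- 0
  tmat <- M / sqrt(V / n)
  tmat[!is.finite(tmat)] <- 0          # degenerate-variance voxels
  tmat
}

perm_cluster_engine <- function(D, dim, idx, n_perm, cdt_p, alpha, seed,
                                connectivity, affine = NULL) {
  n <- nrow(D)
  if (n < 2L) stopf("need at least 2 subjects")
  if (any(apply(D, 2, function(x) all(x == x[1]) && x[1] != 0)))
    warning("constant nonzero difference maps at some voxels; t set by formula")
  t_thr <- qt(1 - cdt_p / 2, df = n - 1L)
  S <- signflip_matrix(n, n_perm, seed)
  exhaustive <- attr(S, "exhaustive")
  n_used <- nrow(S)

  max_extent <- numeric(n_used)
  obs_lab <- NULL
  obs_t <- NULL
  chunk <- max(1L, floor(2e7 / max(ncol(D), 1L)))
  row0 <- 0L
  while (row0 < n_used) {
    rows <- (row0 + 1L):min(row0 + chunk, n_used)
    tmat <- signflip_tmaps(D, S[rows, , drop = FALSE])
    for (r in seq_along(rows)) {
      supra <- array(FALSE, dim)
      supra[idx] <- tmat[r, ] > t_thr
      lab <- label_clusters(supra, connectivity)
      ext <- attr(lab, "extents")
      max_extent[rows[r]] <- if (length(ext)) max(ext) else 0
      if (rows[r] == 1L && exhaustive) { obs_lab <- lab; obs_t <- tmat[r, ] }
    }
    row0 <- rows[length(rows)]
  }

  ## observed statistics (identity flip)
  if (is.null(obs_lab)) {
    t_obs <- signflip_tmaps(D, matrix(1, 1, n))[1L, ]
    supra <- array(FALSE, dim)
    supra[idx] <- t_obs > t_thr
    obs_lab <- label_clusters(supra, connectivity)
    obs_t <- t_obs
  }
  extents <- attr(obs_lab, "extents")
  null_max <- if (exhaustive) max_extent else max_extent

  t_map <- array(NaN, dim)
  t_map[idx] <- obs_t

  clusters <- list()
  if (length(extents)) {
    for (cl in seq_along(extents)) {
      vox <- which(obs_lab == cl)
      peak <- vox[which.max(t_map[vox])]
      p_corr <- if (exhaustive)
        mean(null_max >= extents[cl])
      else
        (1 + sum(null_max >= extents[cl])) / (1 + n_used)
      pk <- index_to_ijk(peak, dim)
      pk_mm <- if (!is.null(affine)) ijk_to_mm(pk, affine) else
        matrix(NA_real_, 1, 3)
      clusters[[cl]] <- data.frame(
        cluster = cl, extent = extents[cl],
        peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
        peak_x_mm = pk_mm[1], peak_y_mm = pk_mm[2], peak_z_mm = pk_mm[3],
        peak_t = t_map[peak], p_corrected = p_corr)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster = integer(0), extent = integer(0),
               peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0),
               peak_t = numeric(0), p_corrected = numeric(0))
  clusters$significant <- clusters$p_corrected < alpha

  structure(list(clusters = clusters,
                 t_map = t_map,
                 label_map = obs_lab,
                 cdt = list(p = cdt_p, t_threshold = t_thr, df = n - 1L),
                 alpha = alpha,
                 n_perm = n_used,
                 exhaustive = exhaustive,
                 null_max_extents = null_max,
                 connectivity = connectivity),
            class = "cluster_result")
}

#' Permutation-based paired t-test with cluster-level FWE correction
#'
#' Voxel-wise paired t statistics on the per-subject difference maps A - B,
#' with the null distribution generated by random sign flips of the subject
#' difference maps (exhaustive enumeration of all 2^n patterns whenever
#' 2^n <= n_perm). Candidate clusters are formed from voxels exceeding the
#' cluster-defining threshold (positive tail of the two-sided t quantile at
#' `cdt_p`) under 18-connectivity; cluster-corrected p-values rank the
#' observed extent in the permutation distribution of the maximum cluster
#' extent, with the observed statistic counted in the null
#' (p = (1 + #\{null >= obs\}) / (1 + n_perm)) so p is never 0.
#'
#' @param mapsA,mapsB lists of per-subject 3D maps (or 4D arrays,
#'   subject last), aligned across subjects.
#' @param n_perm number of permutations (default 5000).
#' @param cdt_p cluster-defining threshold as a p-value (0.005 for the dog
#'   preset, 0.001 for the human preset).
#' @param alpha cluster-level FWE threshold.
#' @param seed integer seed.
#' @param mask optional logical 3D analysis mask (default: voxels finite in
#'   all subjects).
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param affine optional 4x4 affine for peak mm coordinates.
#' @return Object of class `cluster_result`.
#' @export
permutation_paired_test <- function(mapsA, mapsB, n_perm = 5000,
                                    cdt_p = 0.005, alpha = 0.05,
                                    seed = 20230627, mask = NULL,
                                    connectivity = 18, affine = NULL) {
  sa <- stack_maps(mapsA, mask)
  sb <- stack_maps(mapsB, sa$mask)
  if (!all(dim(sa$M) == dim(sb$M))) stopf("mapsA and mapsB are not aligned")
  D <- sa$M - sb$M
  perm_cluster_engine(D, sa$dim, sa$idx, n_perm, cdt_p, alpha, seed,
                      connectivity, affine)
}

#' Permutation-based one-sample t-test with cluster-level FWE correction
#'
#' As [permutation_paired_test()] with the comparison maps identically zero
#' (the second-level "all conditions > implicit baseline" localizer test).
#'
#' @inheritParams permutation_paired_test
#' @param maps list of per-subject 3D maps or a 4D array.
#' @return Object of class `cluster_result`.
#' @export
permutation_onesample_test <- function(maps, n_perm = 5000, cdt_p = 0.005,
                                       alpha = 0.05, seed = 20230627,
                                       mask = NULL, connectivity = 18,
                                       affine = NULL) {
  st <- stack_maps(maps, mask)
  perm_cluster_engine(st$M, st$dim, st$idx, n_perm, cdt_p, alpha, seed,
                      connectivity, affine)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster_result: CDT p=%g (t>%.3f, df=%d), %s%d permutations, alpha=%g\n",
    x$cdt$p, x$cdt$t_threshold, x$cdt$df,
    if (x$exhaustive) "exhaustive " else "", x$n_perm, x$alpha))
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters[, c("cluster", "extent", "peak_t", "p_corrected",
                            "significant")], row.names = FALSE)
  invisible(x)
}

#' Write a cluster table as TSV
#'
#' @param result a `cluster_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cluster_table <- function(result, path) {
  utils::write.table(result$clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Minimum significant cluster extent from a max-extent null sample
#'
#' The smallest extent k whose exceedance probability under the null sample
#' P(max extent >= k) is at most alpha.
#'
#' @param null_max_extents numeric vector of null maximum extents.
#' @param alpha FWE level in (0, 1].
#' @return Integer extent threshold.
#' @export
cluster_extent_threshold <- function(null_max_extents, alpha = 0.05) {
  if (!length(null_max_extents)) stopf("empty null sample")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stopf("`alpha` must be in (0, 1]")
  for (k in seq_len(max(null_max_extents) + 1L)) {
    if (mean(null_max_extents >= k) <= alpha) return(k)
  }
  max(null_max_extents) + 1L
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone and capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (NaN forbidden).
#' @return Adjusted q-values in the input order.
#' @export
fdr_bh <- function(pvalues) {
  if (any(is.na(pvalues))) stopf("NaN/NA p-values are not allowed")
  if (any(pvalues < 0 | pvalues > 1)) stopf("p-values must be in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
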