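#' One-way repeated-measures ANOVA with planned pairwise comparisons
#'
#' Classical repeated-measures F with subject as blocking factor (fitted with
#' `stats::aov` and an Error(subject) stratum), plus planned pairwise paired
#' t-tests whose p-values are returned raw — collect the family across fROIs
#' answering one question and adjust with [fdr_bh()].
#'
#' @param values numeric subject x condition matrix (complete; >= 2 subjects
#'   and >= 2 conditions). Column names are the condition labels.
#' @return List with `F`, `df1`, `df2`, `p`, and `pairwise` (data.frame a, b,
#'   t, df, p, mean_diff).
#' @export
rm_anova_oneway <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stopf("missing cell in subject x condition table")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stopf("need >= 2 subjects and >= 2 conditions")
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(k))
  dat <- data.frame(y = as.vector(values),
                    condition = factor(rep(colnames(values), each = n),
                                       levels = colnames(values)),
                    subject = factor(rep(seq_len(n), k)))
  fit <- aov(y ~ condition + Error(subject), data = dat)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["condition", "F value"]
  p <- tab["condition", "Pr(>F)"]
  ## identical columns leave only round-off in the condition stratum
  if (tab["condition", "Sum Sq"] <= 1e-20 * (sum(values^2) + 1)) {
    Fv <- 0; p <- 1
  }
  if (!is.finite(Fv)) Fv <- 0
  if (!is.finite(p)) p <- 1
  prs <- combn(colnames(values), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    d <- values[, a] - values[, b]
    if (sd(d) < .Machine$double.eps^0.5 * max(abs(d), 1)) {
      tt <- list(statistic = 0, parameter = n - 1L,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- t.test(d)
    data.frame(a = a, b = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_diff = mean(d), stringsAsFactors = FALSE)
  }))
  list(F = unname(Fv), df1 = tab["condition", "Df"],
       df2 = tab["Residuals", "Df"], p = unname(p), pairwise = pairwise)
}

#' 2 x 2 within-subjects ANOVA (species x image category)
#'
#' Fully within-subject 2 x 2 design with one observation per cell: each
#' effect (main effect of species, main effect of category, interaction) is
#' tested with df = (1, n - 1). Columns must be named
#' `<species>_<category>` over two species and two category levels, e.g. the
#' four animate conditions conspecific/heterospecific x face/body.
#'
#' @param values numeric subject x 4 matrix (complete).
#' @param species_levels,category_levels the two factor levels encoded in the
#'   column names.
#' @return Data frame with effect, F, df1, df2, p, plus attribute `pairwise`
#'   (all 6 paired comparisons, raw p — adjust the family with [fdr_bh()]).
#' @export
rm_anova_2x2 <- function(values,
                         species_levels = c("conspecific", "heterospecific"),
                         category_levels = c("face", "body")) {
  values <- as.matrix(values)
  if (ncol(values) != 4L) stopf("`values` must have 4 columns (2 x 2 cells)")
  if (any(!is.finite(values))) stopf("missing cell in 2 x 2 table")
  n <- nrow(values)
  if (n < 2L) stopf("need >= 2 subjects")
  want <- as.vector(outer(species_levels, category_levels,
                          function(s, c) paste(s, c, sep = "_")))
  if (!all(want %in% colnames(values)))
    stopf("columns must be named %s", paste(want, collapse = ", "))
  v <- values[, want]
  ## contrast scores: each 2x2 within-subject effect is a paired t on a
  ## linear combination of the four cells
  scores <- list(
    species = (v[, 1] + v[, 3] - v[, 2] - v[, 4]) / 2,
    category = (v[, 1] + v[, 2] - v[, 3] - v[, 4]) / 2,
    `species:category` = (v[, 1] - v[, 2] - v[, 3] + v[, 4]) / 2
  )
  eff <- do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    if (sd(s) < .Machine$double.eps^0.5 * max(abs(s), 1)) {
      Fv <- 0; p <- 1
    } else {
      tt <- t.test(s)
      Fv <- unname(tt$statistic)^2
      p <- tt$p.value
    }
    data.frame(effect = nm, F = Fv, df1 = 1L, df2 = n - 1L, p = p,
               stringsAsFactors = FALSE)
  }))
  prs <- combn(colnames(v), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    d <- v[, prs[1, i]] - v[, prs[2, i]]
    if (sd(d) < .Machine$double.eps^0.5 * max(abs(d), 1)) {
      tt <- list(statistic = 0, parameter = n - 1L,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- t.test(d)
    data.frame(a = prs[1, i], b = prs[2, i], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_diff = mean(d), stringsAsFactors = FALSE)
  }))
  attr(eff, "pairwise") <- pairwise
  eff
}

#' Subsample resampling of a group analysis
#'
#' Repeatedly draws `n_sub` subjects without replacement from a larger
#' cohort's subject x condition table, reruns the ANOVA, and records the
#' outcome distribution (the n = 15 human subsample control analysis, 1000
#' iterations by default).
#'
#' @param subject_values numeric subject x condition matrix.
#' @param n_sub subsample size.
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param analysis_fn function(matrix) -> list with elements `F` and `p`
#'   (default [rm_anova_oneway()]).
#' @param alpha significance level used for the `significant` column.
#' @return Data frame with iter, F, p, significant; attribute
#'   `significant_fraction`.
#' @export
resample_subsamples <- function(subject_values, n_sub = 15, n_iter = 1000,
                                seed = 20230627,
                                analysis_fn = rm_anova_oneway,
                                alpha = 0.05) {
  subject_values <- as.matrix(subject_values)
  n <- nrow(subject_values)
  n_sub <- check_count(n_sub, "n_sub", min = 2L)
  if (n_sub > n) stopf("n_sub (%d) exceeds available subjects (%d)", n_sub, n)
  set.seed(substream_seed(seed, "resample"))
  res <- do.call(rbind, lapply(seq_len(n_iter), function(i) {
    take <- if (n_sub == n) seq_len(n) else sample(n, n_sub)
    a <- analysis_fn(subject_values[take, , drop = FALSE])
    data.frame(iter = i, F = a$F, p = a$p, significant = a$p < alpha)
  }))
  attr(res, "significant_fraction") <- mean(res$significant)
  res
}
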