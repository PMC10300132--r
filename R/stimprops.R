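#' Low-level visual properties of one image
#'
#' Converts the image from RGB to HSV and measures: hue and saturation as the
#' mean over all pixels of the respective component (achromatic pixels carry
#' hue 0 and are included); contrast as the population standard deviation of
#' the value/brightness component; and spatial extent as the percentage of
#' pixels that differ from the uniform background colour.
#'
#' @param image H x W x 3 array, values in \[0, 1\] or \[0, 255\].
#' @param background background RGB triple on the same scale as the image.
#' @param background_tol per-channel tolerance for the background match,
#'   in intensity levels of a 0-255 scale (use 0 for exact synthetic images).
#' @return Data frame (one row): hue, saturation, contrast, spatial_extent.
#' @export
compute_image_properties <- function(image,
                                     background = c(128, 128, 128) / 255,
                                     background_tol = 2) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stopf("`image` must be a 3-channel H x W x 3 array (convert grayscale/alpha first)")
  maxval <- if (max(image) > 1) 255 else 1
  px <- rbind(as.vector(image[, , 1]),
              as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  hsv <- rgb2hsv(px, maxColorValue = maxval)
  tol <- background_tol / 255 * maxval
  bg <- rep(background, length.out = 3L)
  is_bg <- abs(px[1, ] - bg[1]) <= tol &
           abs(px[2, ] - bg[2]) <= tol &
           abs(px[3, ] - bg[3]) <= tol
  v <- hsv["v", ] * maxval          # value on the input intensity scale
  data.frame(hue = mean(hsv["h", ]),
             saturation = mean(hsv["s", ]),
             contrast = sqrt(mean((v - mean(v))^2)),
             spatial_extent = 100 * mean(!is_bg))
}

#' Property table for a whole stimulus set
#'
#' @param stimulus_set a [generate_stimulus_set()] object.
#' @param background_tol see [compute_image_properties()].
#' @return Data frame with image_id, condition, species, category and the
#'   four property measures.
#' @export
stimulus_property_table <- function(stimulus_set, background_tol = 0) {
  props <- do.call(rbind, lapply(stimulus_set$info$image_id, function(id)
    compute_image_properties(stimulus_set$images[[id]],
                             background = stimulus_set$background,
                             background_tol = background_tol)))
  cbind(stimulus_set$info[, c("image_id", "condition", "species", "category")],
        props)
}

#' Write a property table as TSV
#'
#' @param table from [stimulus_property_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_property_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pooled-variance two-sample t test
#'
#' Student's two-sample t with pooled variance and df = n_a + n_b - 2 (the
#' form behind the stimulus spatial-extent comparisons, e.g. 60 faces vs 60
#' bodies giving df = 118). Degenerate zero-variance input yields t = 0 /
#' p = 1 when the means agree and signed infinity otherwise.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  if (sp2 <= .Machine$double.eps * max(abs(c(a, b)), 1)^2) {
    delta <- mean(a) - mean(b)
    if (abs(delta) < .Machine$double.eps^0.5)
      return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: t is infinite")
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Category and species ANOVAs on stimulus properties
#'
#' For each property, runs (i) a one-way ANOVA over image category (faces,
#' bodies, inanimate objects; species pooled, scrambled excluded) and (ii) a
#' two-way species (dog, human) x category (face, body) ANOVA with
#' interaction. The designs are balanced, so classical sequential sums of
#' squares coincide with type-II.
#'
#' @param records data frame with columns condition, species, category and
#'   the property columns.
#' @param properties property column names to analyse.
#' @return Named list (by property) of lists with `oneway` and `twoway`
#'   data frames (effect, df1, df2, F, p).
#' @export
property_anovas <- function(records,
                            properties = c("hue", "saturation", "contrast",
                                           "spatial_extent")) {
  stopifnot(all(c("category", "species") %in% names(records)))
  one <- records[records$category %in% c("face", "body", "object"), ]
  two <- records[records$category %in% c("face", "body") &
                   records$species %in% c("dog", "human"), ]
  miss <- setdiff(c("face", "body", "object"), unique(one$category))
  if (length(miss))
    stopf("empty category cell: %s", paste(miss, collapse = ", "))
  if (nrow(two) == 0 ||
      length(unique(two$species)) < 2L || length(unique(two$category)) < 2L ||
      any(table(two$species, two$category) == 0))
    stopf("empty species x category cell")

  out <- lapply(properties, function(p) {
    ## effects whose sum of squares is pure floating-point round-off
    ## (constant input, exactly additive cells) are reported as F = 0, p = 1
    clean <- function(a, rows, df2_row) {
      ss_total <- sum(a[, "Sum Sq"])
      scale <- max(ss_total, .Machine$double.eps)
      Fv <- a[rows, "F value"]
      pv <- a[rows, "Pr(>F)"]
      degen <- a[rows, "Sum Sq"] <= 1e-10 * scale
      Fv[degen] <- 0; pv[degen] <- 1
      bad <- !is.finite(Fv)
      Fv[bad] <- 0; pv[bad] <- 1
      data.frame(effect = trimws(rownames(a)[rows]),
                 df1 = a[rows, "Df"], df2 = a[df2_row, "Df"],
                 F = Fv, p = pv, row.names = NULL)
    }
    d1 <- data.frame(y = one[[p]], category = factor(one$category))
    a1 <- summary(aov(y ~ category, data = d1))[[1]]
    oneway <- clean(a1, 1L, nrow(a1))
    d2 <- data.frame(y = two[[p]], species = factor(two$species),
                     category = factor(two$category))
    a2 <- summary(aov(y ~ species * category, data = d2))[[1]]
    twoway <- clean(a2, 1:3, 4L)
    list(oneway = oneway, twoway = twoway)
  })
  names(out) <- properties
  out
}
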