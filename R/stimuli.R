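#' Generate a synthetic stimulus set
#'
#' Builds the full image set for the six-condition block design: coloured
#' shapes on a uniform mid-grey background (RGB 128,128,128), so low-level
#' properties are exactly controllable. Faces are drawn as near-round ellipses
#' covering about 58% of the frame and bodies as elongated ellipses covering
#' about 29%, mirroring the face/body spatial-extent asymmetry of natural
#' cut-out stimuli; objects are rectangles, half matched in extent to faces
#' and half to bodies. Scrambled entries are grid-scrambled copies of a subset
#' drawn equally from the five non-scrambled conditions.
#'
#' @param n_per_condition images per condition (default 30, i.e. 180 total).
#' @param seed integer seed.
#' @param size image side length in pixels.
#' @param scramble_grid grid subdivision used for scrambling (default 8x8).
#' @return An object of class `stimulus_set`: list with `info` (data.frame
#'   image_id, condition, species, category, source_id) and `images` (named
#'   list of size x size x 3 arrays in \[0, 1\]).
#' @export
generate_stimulus_set <- function(n_per_condition = 30, seed = 20230627,
                                  size = 64, scramble_grid = 8) {
  n_per_condition <- check_count(n_per_condition, "n_per_condition")
  set.seed(substream_seed(seed, "stimuli"))
  conds <- study_conditions()
  plain <- setdiff(conds, "scrambled")

  images <- list()
  info <- list()
  for (cond in plain) {
    cat_ <- condition_category(cond)
    spec_ <- condition_species(cond)
    ## per-condition hue bands keep species distinguishable in colour space
    hue0 <- switch(cond, dog_face = 0.08, dog_body = 0.10,
                   human_face = 0.55, human_body = 0.60, object = 0.30)
    for (i in seq_len(n_per_condition)) {
      id <- sprintf("%s_%02d", cond, i)
      extent <- if (cat_ == "face") 0.58
        else if (cat_ == "body") 0.29
        else if (i <= ceiling(n_per_condition / 2)) 0.58 else 0.29
      extent <- extent * runif(1, 0.96, 1.04)
      hue <- (hue0 + runif(1, -0.03, 0.03)) %% 1
      shape <- if (cat_ == "object") "rect" else "ellipse"
      elong <- if (cat_ == "body") runif(1, 2.2, 2.8) else runif(1, 1.0, 1.3)
      images[[id]] <- draw_stimulus(size, extent, hue,
                                    saturation = runif(1, 0.6, 0.9),
                                    value = runif(1, 0.55, 0.8),
                                    shape = shape, elongation = elong)
      info[[id]] <- data.frame(image_id = id, condition = cond,
                               species = spec_, category = cat_,
                               source_id = NA_character_,
                               stringsAsFactors = FALSE)
    }
  }

  ## scrambled: equal draw from the 5 plain conditions (remainder, if any,
  ## spread over the first conditions in canonical order)
  n_each <- rep(n_per_condition %/% 5L, 5L)
  rem <- n_per_condition %% 5L
  if (rem > 0L) n_each[seq_len(rem)] <- n_each[seq_len(rem)] + 1L
  k <- 0L
  for (ci in seq_along(plain)) {
    pool <- sprintf("%s_%02d", plain[ci], seq_len(n_per_condition))
    src <- sample(pool, n_each[ci])
    for (s in src) {
      k <- k + 1L
      id <- sprintf("scrambled_%02d", k)
      images[[id]] <- scramble_image(images[[s]], n_grid = scramble_grid,
                                     seed = substream_seed(seed, id))
      info[[id]] <- data.frame(image_id = id, condition = "scrambled",
                               species = "none", category = "scrambled",
                               source_id = s, stringsAsFactors = FALSE)
    }
  }

  info <- do.call(rbind, info)
  rownames(info) <- NULL
  structure(list(info = info, images = images,
                 background = c(128, 128, 128) / 255,
                 n_per_condition = n_per_condition),
            class = "stimulus_set")
}

## Render one stimulus: a filled ellipse or rectangle of the requested
## fractional area, centred, on mid-grey.
draw_stimulus <- function(size, extent, hue, saturation, value,
                          shape = c("ellipse", "rect"), elongation = 1) {
  shape <- match.arg(shape)
  bg <- 128 / 255
  img <- array(bg, dim = c(size, size, 3))
  cx <- (size + 1) / 2
  x <- matrix(seq_len(size) - cx, size, size)
  y <- t(x)
  if (shape == "ellipse") {
    ## area = pi a b, b = a / elongation
    a <- sqrt(extent * size^2 * elongation / pi)
    b <- a / elongation
    inside <- (x / b)^2 + (y / a)^2 <= 1
  } else {
    w <- sqrt(extent * size^2 / elongation)
    h <- w * elongation
    inside <- abs(x) <= w / 2 & abs(y) <= h / 2
  }
  rgb <- col2rgb(hsv(hue, saturation, value)) / 255
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

#' Grid-scramble an image
#'
#' Partitions the image into an `n_grid` x `n_grid` grid of tiles and permutes
#' the tiles. Image dimensions must be divisible by `n_grid`.
#'
#' @param image H x W x 3 array.
#' @param n_grid grid subdivision per side.
#' @param seed integer seed for the tile permutation.
#' @return Scrambled image of the same shape.
#' @export
scramble_image <- function(image, n_grid = 8, seed = 1L) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stopf("`image` must be H x W x 3")
  if (d[1L] %% n_grid != 0L || d[2L] %% n_grid != 0L)
    stopf("image dimensions must be divisible by n_grid")
  th <- d[1L] %/% n_grid
  tw <- d[2L] %/% n_grid
  set.seed(seed)
  perm <- sample(n_grid^2)
  out <- image
  for (t_new in seq_len(n_grid^2)) {
    t_old <- perm[t_new]
    ro <- ((t_old - 1L) %% n_grid) * th
    co <- ((t_old - 1L) %/% n_grid) * tw
    rn <- ((t_new - 1L) %% n_grid) * th
    cn <- ((t_new - 1L) %/% n_grid) * tw
    out[rn + seq_len(th), cn + seq_len(tw), ] <-
      image[ro + seq_len(th), co + seq_len(tw), ]
  }
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus_set: %d images (%d per condition), %dx%d px\n",
              nrow(x$info), x$n_per_condition,
              dim(x$images[[1]])[1], dim(x$images[[1]])[2]))
  print(table(x$info$condition))
  invisible(x)
}

#' Write stimulus images as PNG files
#'
#' @param stimulus_set a [generate_stimulus_set()] object.
#' @param dir output directory (created if needed).
#' @return Data frame mapping image_id to file path, invisibly.
#' @export
write_stimulus_pngs <- function(stimulus_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stimulus_set$images), function(id) {
    p <- file.path(dir, paste0(id, ".png"))
    png::writePNG(stimulus_set$images[[id]], p)
    p
  }, character(1))
  invisible(data.frame(image_id = names(paths), file = unname(paths),
                       stringsAsFactors = FALSE))
}
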