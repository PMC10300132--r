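#' Study conditions
#'
#' The six stimulus conditions of the face/body/object block design, in
#' canonical order. Faces and bodies exist for both species; `object` is the
#' inanimate control and `scrambled` the grid-scrambled low-level control.
#'
#' @return Character vector of the six condition labels.
#' @export
study_conditions <- function() {
  c("dog_face", "dog_body", "human_face", "human_body", "object", "scrambled")
}

#' Species and category of a condition label
#'
#' @param condition character vector of condition labels.
#' @return `condition_species()`: "dog", "human" or "none";
#'   `condition_category()`: "face", "body", "object" or "scrambled".
#' @export
condition_species <- function(condition) {
  out <- rep("none", length(condition))
  out[grepl("^dog_", condition)] <- "dog"
  out[grepl("^human_", condition)] <- "human"
  out
}

#' @rdname condition_species
#' @export
condition_category <- function(condition) {
  out <- condition
  out[grepl("_face$", condition)] <- "face"
  out[grepl("_body$", condition)] <- "body"
  out
}

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps a master seed plus a stream name to an integer
#' seed. All stage-level randomness in the pipeline flows through named
#' substreams of the config seed, so replays are exact and changing one
#' stage's draws does not shift another's.
#'
#' @param seed master integer seed.
#' @param name stream name.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647L)
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

## linear index <-> ijk coordinates for a 3D grid
ijk_to_index <- function(ijk, dim) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  as.integer(ijk[, 1L] + dim[1L] * (ijk[, 2L] - 1L) +
             dim[1L] * dim[2L] * (ijk[, 3L] - 1L))
}

index_to_ijk <- function(idx, dim) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% dim[1L]
  j <- (idx0 %/% dim[1L]) %% dim[2L]
  k <- idx0 %/% (dim[1L] * dim[2L])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

## Default RAS-like affine: voxel sizes on the diagonal, origin at grid centre
## so that world x < 0 is the left hemisphere.
default_affine <- function(dim, voxel_mm) {
  voxel_mm <- rep(voxel_mm, length.out = 3L)
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * (dim + 1) / 2
  aff
}

## world mm coordinates of voxel centres (ijk 1-based)
ijk_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3L)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Write a 3D/4D volume as NIfTI
#'
#' Thin wrapper around \pkg{RNifti} that attaches the grid affine.
#'
#' @param data numeric 3D or 4D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array with its affine
#'
#' @param path NIfTI file path.
#' @return list with `data` (array) and `affine` (4x4 matrix).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = unclass(RNifti::xform(img)))
}
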