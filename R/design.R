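#' Randomize block order without immediate repeats
#'
#' Draws a random ordering of `blocks_per_condition` blocks of each condition
#' such that the same condition never occurs twice in a row, by seeded
#' rejection sampling. A no-adjacent-repeat arrangement exists iff the largest
#' multiplicity is at most `ceiling(total / 2)`.
#'
#' @param conditions character vector of condition labels.
#' @param blocks_per_condition blocks per condition (default 3).
#' @param seed integer seed.
#' @param max_tries rejection-sampling bound before giving up.
#' @return Character vector of length `length(conditions) * blocks_per_condition`.
#' @export
randomize_block_order <- function(conditions = study_conditions(),
                                  blocks_per_condition = 3,
                                  seed = 20230627, max_tries = 10000) {
  blocks_per_condition <- check_count(blocks_per_condition, "blocks_per_condition")
  if (anyDuplicated(conditions)) stopf("`conditions` must be unique labels")
  total <- length(conditions) * blocks_per_condition
  if (blocks_per_condition > ceiling(total / 2))
    stopf("no repeat-free arrangement exists for %d x %d blocks",
          length(conditions), blocks_per_condition)
  set.seed(substream_seed(seed, "block_order"))
  pool <- rep(conditions, each = blocks_per_condition)
  for (try in seq_len(max_tries)) {
    ord <- sample(pool)
    if (total == 1L || !any(ord[-1L] == ord[-total])) return(ord)
  }
  stopf("failed to draw a repeat-free block order in %d tries", max_tries)
}

#' Build one run's block design
#'
#' Lays out 12-s stimulus blocks separated by jittered visual baselines, with
#' a leading baseline before the first block and one baseline after every
#' block. Each block consumes `images_per_block` unused images of its
#' condition from the available pool, so across runs every image is presented
#' exactly once. Onsets are kept at sub-TR precision; the run length in scans
#' is the total design duration rounded up to whole TRs.
#'
#' @param order condition sequence, e.g. from [randomize_block_order()].
#' @param stimulus_set a [generate_stimulus_set()] object.
#' @param TR repetition time in seconds.
#' @param jitter_range baseline duration range in seconds (uniform).
#' @param seed integer seed (jitters and image composition).
#' @param available_ids image ids still unused; default all images.
#' @param block_duration block length in seconds.
#' @param images_per_block images shown per block.
#' @return An object of class `run_design`: list with `blocks` (data.frame
#'   onset, duration, condition), `block_images` (list of image-id vectors),
#'   `baselines` (data.frame onset, duration), `TR`, `n_scans`.
#' @export
build_run_design <- function(order, stimulus_set, TR = 1,
                             jitter_range = c(3, 7), seed = 20230627,
                             available_ids = NULL, block_duration = 12,
                             images_per_block = 5) {
  if (length(order) < 1L) stopf("`order` must contain at least one block")
  if (length(jitter_range) != 2L || jitter_range[1] > jitter_range[2] ||
      jitter_range[1] < 0)
    stopf("`jitter_range` must be a non-decreasing pair of non-negative seconds")
  info <- stimulus_set$info
  available_ids <- available_ids %||% info$image_id
  set.seed(substream_seed(seed, "run_design"))

  n_blocks <- length(order)
  jit <- runif(n_blocks + 1L, jitter_range[1], jitter_range[2])
  block_images <- vector("list", n_blocks)
  onsets <- numeric(n_blocks)
  t <- jit[1L]                      # leading baseline
  baselines <- data.frame(onset = 0, duration = jit[1L])
  for (b in seq_len(n_blocks)) {
    cond <- order[b]
    pool <- intersect(info$image_id[info$condition == cond], available_ids)
    if (length(pool) < images_per_block)
      stopf("not enough unused `%s` images: need %d, have %d",
            cond, images_per_block, length(pool))
    ids <- if (length(pool) == images_per_block) sample(pool) else
      sample(pool, images_per_block)
    block_images[[b]] <- ids
    available_ids <- setdiff(available_ids, ids)
    onsets[b] <- t
    t <- t + block_duration
    baselines <- rbind(baselines, data.frame(onset = t, duration = jit[b + 1L]))
    t <- t + jit[b + 1L]
  }
  structure(list(
    blocks = data.frame(onset = onsets, duration = block_duration,
                        condition = order, stringsAsFactors = FALSE),
    block_images = block_images,
    baselines = baselines,
    TR = TR,
    n_scans = as.integer(ceiling(t / TR)),
    remaining_ids = available_ids
  ), class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("run_design: %d blocks (%g s), %d baselines, TR %g s, %d scans\n",
              nrow(x$blocks), x$blocks$duration[1], nrow(x$baselines),
              x$TR, x$n_scans))
  invisible(x)
}

#' Build all run designs for one subject
#'
#' Randomizes a repeat-free block order per run and partitions the stimulus
#' set across runs so that every image is presented exactly once in the
#' session.
#'
#' @param stimulus_set a [generate_stimulus_set()] object.
#' @param n_runs number of runs (default 2).
#' @param blocks_per_condition blocks per condition per run (default 3).
#' @inheritParams build_run_design
#' @return List of `run_design` objects.
#' @export
make_subject_designs <- function(stimulus_set, n_runs = 2,
                                 blocks_per_condition = 3, TR = 1,
                                 jitter_range = c(3, 7), seed = 20230627,
                                 images_per_block = 5) {
  available <- stimulus_set$info$image_id
  designs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ord <- randomize_block_order(study_conditions(), blocks_per_condition,
                                 seed = substream_seed(seed, paste0("order", r)))
    designs[[r]] <- build_run_design(ord, stimulus_set, TR = TR,
                                     jitter_range = jitter_range,
                                     seed = substream_seed(seed, paste0("run", r)),
                                     available_ids = available,
                                     images_per_block = images_per_block)
    available <- designs[[r]]$remaining_ids
  }
  designs
}

#' Write / read a run design as a BIDS-events-like TSV
#'
#' Columns: onset, duration, trial_type. Baseline periods are implicit (not
#' written).
#'
#' @param design a `run_design`.
#' @param path TSV path.
#' @return `write_events_tsv()`: the path, invisibly. `read_events_tsv()`:
#'   a data.frame with onset, duration, trial_type.
#' @export
write_events_tsv <- function(design, path) {
  ev <- data.frame(onset = design$blocks$onset,
                   duration = design$blocks$duration,
                   trial_type = design$blocks$condition)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
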