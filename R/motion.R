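#' Simulate a realignment-parameter trace
#'
#' Produces a per-scan 6-column motion trace (3 translations in mm, 3
#' rotations in rad): smooth low-amplitude random wander (cumulative-sum
#' noise, lightly smoothed) plus optional displacement spikes at given scans.
#' Spikes are applied to the x-translation as a sustained step of the given
#' magnitude (the head settles in a new position), so each spike produces
#' exactly one framewise-displacement exceedance, at the spike scan, of at
#' least the magnitude.
#'
#' @param n_scans number of scans.
#' @param spike_times scan indices (2..n_scans) receiving spikes.
#' @param spike_magnitudes spike sizes in mm (recycled against `spike_times`).
#' @param wander_sd standard deviation of the per-scan wander increments
#'   (mm for translations; rad for rotations uses `wander_sd / 50`).
#' @param seed integer seed.
#' @return n_scans x 6 matrix with columns tx, ty, tz (mm), rx, ry, rz (rad).
#' @export
simulate_motion_trace <- function(n_scans, spike_times = integer(0),
                                  spike_magnitudes = numeric(0),
                                  wander_sd = 0.02, seed = 20230627) {
  n_scans <- check_count(n_scans, "n_scans", min = 2L)
  if (length(spike_times) &&
      (any(spike_times < 2L) || any(spike_times > n_scans)))
    stopf("spike times must lie in 2..n_scans")
  if (length(spike_times))
    spike_magnitudes <- rep(spike_magnitudes, length.out = length(spike_times))
  set.seed(substream_seed(seed, "motion"))
  tr_sd <- rep(wander_sd, 3)
  rot_sd <- rep(wander_sd / 50, 3)
  m <- matrix(0, n_scans, 6)
  for (j in 1:6) {
    sdj <- if (j <= 3) tr_sd[j] else rot_sd[j - 3]
    inc <- rnorm(n_scans, sd = sdj)
    x <- cumsum(inc)
    if (n_scans >= 5) {
      x <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
      x[1L] <- x[2L]                  # endpoints: nearest smoothed value
      x[n_scans] <- x[n_scans - 1L]
    }
    m[, j] <- as.numeric(x)
  }
  for (s in seq_along(spike_times)) {
    span <- spike_times[s]:n_scans
    m[span, 1] <- m[span, 1] + spike_magnitudes[s]
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Framewise displacement
#'
#' Scan-to-scan head motion summarised per scan: the sum of absolute
#' translation differences plus the rotation differences converted to arc
#' length on a sphere of radius `rotation_radius`, accounting for both
#' translational and rotational displacements. The first scan has FD 0.
#'
#' @param motion n_scans x 6 matrix (tx, ty, tz in mm; rx, ry, rz in rad).
#' @param rotation_radius head radius in mm (50 is typical for adult humans;
#'   a smaller radius suits the smaller dog head).
#' @return Numeric vector of FD values (mm), length n_scans.
#' @export
compute_fd <- function(motion, rotation_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("`motion` must have 6 columns")
  if (nrow(motion) < 2L) stopf("FD needs at least 2 scans")
  if (any(!is.finite(motion))) stopf("`motion` contains non-finite values")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Scans to scrub by framewise displacement
#'
#' @param fd per-scan FD series from [compute_fd()].
#' @param threshold FD threshold in mm (default 0.5).
#' @return Integer vector of scan indices with FD above threshold, with the
#'   removed fraction as attribute `removed_fraction`.
#' @export
scrub_indices <- function(fd, threshold = 0.5) {
  if (!is.finite(threshold) || threshold <= 0) stopf("`threshold` must be > 0")
  idx <- which(fd > threshold)
  attr(idx, "removed_fraction") <- length(idx) / length(fd)
  idx
}

#' Write / read a motion trace as whitespace-separated text
#'
#' @param motion n_scans x 6 matrix.
#' @param path file path.
#' @return the path / the matrix.
#' @export
write_motion_txt <- function(motion, path) {
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_txt
#' @export
read_motion_txt <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}
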