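# Low-discrepancy generation of failure conditions.

# Direction-number parameters (primitive polynomial degree, coefficient bits,
# initial m values) for the first Sobol dimensions, standard Joe-Kuo table.
# Dimension 1 is the van der Corput sequence in base 2.
.sobol_params <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L))
)

.sobol_bits <- 30L

# Direction numbers v[j] (scaled to .sobol_bits bits) for one dimension.
sobol_directions <- function(dim) {
  B <- .sobol_bits
  if (dim == 1L) return(bitwShiftL(1L, B - seq_len(B)))
  p <- .sobol_params[[dim - 1L]]
  s <- p$s; a <- p$a
  m <- integer(B)
  m[seq_len(s)] <- p$m
  if (B > s) {
    for (j in (s + 1L):B) {
      acc <- bitwXor(m[j - s], bitwShiftL(m[j - s], s))
      if (s > 1L) for (k in seq_len(s - 1L)) {
        ak <- bitwAnd(bitwShiftR(a, s - 1L - k), 1L)
        if (ak == 1L) acc <- bitwXor(acc, bitwShiftL(m[j - k], k))
      }
      m[j] <- acc
    }
  }
  bitwShiftL(m, B - seq_len(B))
}

#' Unscrambled Sobol sequence
#'
#' Gray-code Sobol points in the unit hypercube, starting from the zero point.
#' Deterministic: the same `(n, skip)` always yields the same points.
#'
#' @param n Number of points.
#' @param dim Number of dimensions (1 to 7).
#' @param skip Number of initial points to skip (default 0).
#' @return An `n x dim` matrix of points in `[0, 1)`.
#' @export
sobol_points <- function(n, dim = 4L, skip = 0L) {
  if (n <= 0) stop("`n` must be > 0")
  if (dim < 1L || dim > length(.sobol_params) + 1L)
    stop("`dim` out of supported range")
  V <- vapply(seq_len(dim), sobol_directions, integer(.sobol_bits))
  x <- integer(dim)
  out <- matrix(NA_real_, n, dim)
  total <- skip + n
  for (i in seq_len(total)) {
    if (i > skip) out[i - skip, ] <- x / 2^.sobol_bits
    # rightmost zero bit of (i - 1), 1-based
    c0 <- 1L
    v <- i - 1L
    while (bitwAnd(v, 1L) == 1L) { v <- bitwShiftR(v, 1L); c0 <- c0 + 1L }
    x <- bitwXor(x, V[c0, ])
  }
  out
}

#' Generate non-repeated failure conditions with a Sobol design
#'
#' Draws `n` failure conditions from a 4-dimensional Sobol sequence: the first
#' two dimensions are mapped linearly onto the criticality and onset ranges,
#' the third is quantised into equal quartiles to pick an automation
#' trajectory, and the fourth is thresholded at `understeer_fraction` to set
#' the drift direction.
#'
#' @param n Number of conditions.
#' @param tlc_range Range of TLC_F in seconds (default 2.95 to 19.51).
#' @param onset_range Range of failure onsets in seconds (default 5 to 9).
#' @param n_trajectories Size of the automation-trajectory pool (default 4).
#' @param understeer_fraction Probability mass assigned to understeer drift
#'   (default 0.7).
#' @param skip Sobol skip (default 0); the same `(n, skip)` is deterministic.
#' @param geom Road geometry used when solving yaw-rate offsets.
#' @param solve_offsets If `TRUE` (default), solve the yaw-rate offset that
#'   realises each condition's TLC_F from the road centreline via
#'   [solve_offset_for_tlc()]. Set `FALSE` to skip this (the statistical
#'   models only use TLC_F).
#' @return A data frame with columns `condition_id`, `tlc_f_s`, `onset_s`,
#'   `yaw_offset_degps`, `direction`, `trajectory_id`, `repeated_flag`.
#' @export
sobol_conditions <- function(n, tlc_range = c(2.95, 19.51),
                             onset_range = c(5, 9), n_trajectories = 4L,
                             understeer_fraction = 0.7, skip = 0L,
                             geom = road_geometry(), solve_offsets = TRUE) {
  if (n <= 0) stop("`n` must be > 0")
  if (diff(tlc_range) < 0 || diff(onset_range) < 0) stop("invalid range")
  u <- sobol_points(n, dim = 4L, skip = skip)
  tlc_f <- tlc_range[1] + u[, 1] * diff(tlc_range)
  onset <- onset_range[1] + u[, 2] * diff(onset_range)
  traj <- pmin(floor(u[, 3] * n_trajectories) + 1L, n_trajectories)
  dir <- ifelse(u[, 4] < understeer_fraction, "understeer", "oversteer")
  off <- rep(NA_real_, n)
  if (solve_offsets) {
    for (i in seq_len(n))
      off[i] <- solve_offset_for_tlc(tlc_f[i], geom, onset = onset[i],
                                     direction = dir[i])
  }
  data.frame(condition_id = seq_len(n), tlc_f_s = tlc_f, onset_s = onset,
             yaw_offset_degps = off, direction = dir,
             trajectory_id = as.integer(traj), repeated_flag = FALSE)
}

#' Full failure-condition table for the takeover study
#'
#' The study design combines four Repeated failure conditions (fixed
#' criticalities at a fixed onset, presented several times each) with a pool
#' of Non-Repeated conditions spanning a wider criticality range, generated by
#' [sobol_conditions()]. The default Repeated criticalities are
#' 2.23, 4.68, 7.12 and 9.55 s at a 6 s onset, with yaw-rate offsets
#' 5.73, 1.20, 0.52 and 0.30 deg/s; these are design inputs tied to the
#' pre-recorded automation trajectories, not recomputed quantities.
#'
#' @param n_nonrepeated Number of Non-Repeated conditions (default 24).
#' @param repeated_tlc_f Criticalities of the Repeated conditions in seconds.
#' @param repeated_onset Onset of the Repeated conditions in seconds.
#' @param repeated_offsets Yaw-rate offsets of the Repeated conditions, deg/s.
#' @param ... Passed to [sobol_conditions()].
#' @return A data frame as in [sobol_conditions()], Repeated conditions first
#'   (`repeated_flag = TRUE`), 28 rows with the defaults.
#' @export
failure_conditions <- function(n_nonrepeated = 24L,
                               repeated_tlc_f = c(2.23, 4.68, 7.12, 9.55),
                               repeated_onset = 6,
                               repeated_offsets = c(5.73, 1.20, 0.52, 0.30),
                               ...) {
  rep_df <- data.frame(condition_id = seq_along(repeated_tlc_f),
                       tlc_f_s = repeated_tlc_f,
                       onset_s = repeated_onset,
                       yaw_offset_degps = repeated_offsets,
                       direction = "understeer",
                       trajectory_id = seq_along(repeated_tlc_f),
                       repeated_flag = TRUE)
  non <- sobol_conditions(n_nonrepeated, ...)
  non$condition_id <- non$condition_id + nrow(rep_df)
  rbind(rep_df, non)
}
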