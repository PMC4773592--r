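#' Saccade-detector parameters
#'
#' Constants of the velocity-based detector: Savitzky-Golay differentiation
#' window and order, the iterative data-driven peak-velocity threshold, and
#' event clean-up rules.  Defaults suit 300-Hz recordings: a 7-sample
#' (~23 ms) cubic filter, which tracks the saccadic velocity peak to a
#' fraction of a percent where a quadratic one attenuates it by several
#' percent; threshold iteration `PT <- mean + 6 SD` of
#' sub-threshold velocities to 1 deg/s tolerance, onset/offset walk at
#' `mean + 3 SD` of fixation-window noise, events under 10 ms discarded and
#' events closer than 20 ms merged.
#'
#' @param sg_window Filter window length in samples (odd, > `sg_order`).
#' @param sg_order Polynomial order of the filter.
#' @param pt_init_deg_s Initial peak-velocity threshold (deg/s).
#' @param pt_multiplier SD multiplier of the threshold update.
#' @param onset_multiplier SD multiplier of the onset/offset threshold.
#' @param pt_tol_deg_s Convergence tolerance of the threshold iteration.
#' @param min_duration_ms Minimum saccade duration.
#' @param merge_gap_ms Events separated by less than this are merged.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(sg_window = 7, sg_order = 3,
                            pt_init_deg_s = 100, pt_multiplier = 6,
                            onset_multiplier = 3, pt_tol_deg_s = 1,
                            min_duration_ms = 10, merge_gap_ms = 20) {
  stopifnot_param(sg_window %% 2 == 1 && sg_window > sg_order,
                  "sg_window must be odd and greater than sg_order")
  stopifnot_param(pt_multiplier > 0 && onset_multiplier > 0,
                  "threshold multipliers must be > 0")
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 pt_init_deg_s = pt_init_deg_s,
                 pt_multiplier = pt_multiplier,
                 onset_multiplier = onset_multiplier,
                 pt_tol_deg_s = pt_tol_deg_s,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms),
            class = "detector_params")
}

#' Savitzky-Golay velocity estimate of a gaze trace
#'
#' First-derivative Savitzky-Golay filter of the horizontal position channel,
#' scaled to deg/s.  Interior samples use the symmetric least-squares
#' differentiation kernel; the first and last half-window samples use the
#' corresponding one-sided (asymmetric) fits, so the output has the same
#' length as the input.  Exact for polynomials up to the filter order.
#'
#' @param samples Tibble with `t_ms` and `x_deg` (uniformly sampled), or a
#'   `trial_recording`.
#' @param params A [detector_params()] object.
#' @return Numeric vector of velocities (deg/s), aligned with the samples.
#' @export
compute_velocity <- function(samples, params = detector_params()) {
  if (inherits(samples, "trial_recording")) samples <- samples$samples
  n <- nrow(samples)
  if (n < params$sg_window)
    abort_ocusimon(sprintf("need at least sg_window = %d samples, got %d",
                           params$sg_window, n), "ocusimon_input_error")
  dt_s <- stats::median(diff(samples$t_ms)) / 1000
  as.numeric(signal::sgolayfilt(samples$x_deg, p = params$sg_order,
                                n = params$sg_window, m = 1, ts = dt_s))
}

#' Iterative data-driven peak-velocity threshold
#'
#' Starting from `pt_init_deg_s`, repeatedly re-estimates the threshold as
#' `mean + pt_multiplier * SD` of the velocities whose magnitude lies below
#' the current threshold, until successive thresholds differ by less than
#' `pt_tol_deg_s` (or 100 iterations).  Saccade samples are thereby excluded
#' from the noise estimate without any fixed cutoff; the fixed point is
#' insensitive to the starting value for any reasonable trace.
#'
#' @param velocity Numeric velocity series (deg/s).
#' @param params A [detector_params()] object.
#' @return The converged threshold (deg/s).
#' @export
adaptive_peak_threshold <- function(velocity, params = detector_params()) {
  if (!length(velocity))
    abort_ocusimon("empty velocity series", "ocusimon_input_error")
  pt <- params$pt_init_deg_s
  sub <- velocity[abs(velocity) < pt]
  if (!length(sub))
    abort_ocusimon("all velocity samples exceed the initial threshold",
                   "ocusimon_degenerate_error")
  for (i in seq_len(100)) {
    m <- mean(sub)
    s <- if (length(sub) > 1) sd(sub) else 0
    pt_new <- m + params$pt_multiplier * s
    sub_new <- velocity[abs(velocity) < pt_new]
    if (abs(pt_new - pt) < params$pt_tol_deg_s || !length(sub_new)) {
      pt <- pt_new
      break
    }
    pt <- pt_new
    sub <- sub_new
  }
  pt
}

#' Detect horizontal saccades in a gaze recording
#'
#' Candidate events are maximal runs of samples whose speed reaches the
#' adaptive peak-velocity threshold; runs closer than `merge_gap_ms` are
#' merged.  Each event is then extended: the onset walks backward from the
#' run to the first sample whose speed falls below
#' `noise mean + onset_multiplier * noise SD` (noise statistics taken from
#' the pre-target fixation window of the same trial, floored at 5% of the
#' event's peak speed so that near-noiseless traces do not degenerate), and
#' the offset walks forward symmetrically; the reported onset/offset are the
#' bracketing sub-threshold samples.  Events shorter than `min_duration_ms`
#' are discarded.  Only the horizontal channel is analysed.
#'
#' @param recording A `trial_recording` (or a tibble of samples with `t_ms`,
#'   `x_deg`).
#' @param params A [detector_params()] object.
#' @return A tibble of saccades in time order: `onset_ms`, `offset_ms`,
#'   `amplitude_deg`, `peak_velocity_deg_s`, `direction` (`"left"` /
#'   `"right"`).
#' @export
detect_saccades <- function(recording, params = detector_params()) {
  samples <- if (inherits(recording, "trial_recording")) recording$samples
             else recording
  v <- compute_velocity(samples, params)
  speed <- abs(v)
  t <- samples$t_ms
  empty <- tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                  amplitude_deg = numeric(0),
                  peak_velocity_deg_s = numeric(0),
                  direction = character(0))

  pt <- tryCatch(adaptive_peak_threshold(v, params),
                 ocusimon_degenerate_error = function(e) NA_real_)
  if (is.na(pt)) return(empty)
  above <- speed >= pt & speed > 0
  if (!any(above)) return(empty)

  # fixation-window noise statistics for the onset/offset threshold
  fix <- t < 0 & speed < pt
  noise <- speed[fix]
  if (length(noise) < 2) noise <- speed[speed < pt]
  on_thr <- mean(noise) + params$onset_multiplier * sd(noise)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  # merge runs separated by less than merge_gap_ms
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (t[runs$start[k]] - t[last$end] < params$merge_gap_ms)
        keep[[length(keep)]]$end <- runs$end[k]
      else keep[[length(keep) + 1L]] <- runs[k, ]
    }
    runs <- do.call(rbind, keep)
  }

  out <- lapply(seq_len(nrow(runs)), function(k) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    # floor the walk threshold at 5% of the run's peak speed so the
    # filter's sub-threshold smear does not drag onsets outward on
    # near-noiseless recordings
    thr <- max(on_thr, 0.05 * max(speed[i0:i1]), 1e-9)
    # trim run edges that sit below the walk threshold (possible when the
    # adaptive peak threshold converged lower than the floor)
    while (i0 < i1 && speed[i0] <= thr) i0 <- i0 + 1L
    while (i1 > i0 && speed[i1] <= thr) i1 <- i1 - 1L
    while (i0 > 1 && speed[i0 - 1] > thr) i0 <- i0 - 1L
    while (i1 < length(speed) && speed[i1 + 1] > thr) i1 <- i1 + 1L
    # onset/offset are the bracketing sub-threshold samples
    i0 <- max(i0 - 1L, 1L)
    i1 <- min(i1 + 1L, length(speed))
    if (t[i1] - t[i0] < params$min_duration_ms) return(NULL)
    disp <- samples$x_deg[i1] - samples$x_deg[i0]
    tibble(onset_ms = t[i0], offset_ms = t[i1],
           amplitude_deg = abs(disp),
           peak_velocity_deg_s = max(speed[i0:i1]),
           direction = if (disp >= 0) "right" else "left")
  })
  out <- bind_rows(out)
  if (!nrow(out)) return(empty)
  # extension can make adjacent events touch; keep the first of any overlap
  out <- out[!duplicated(out$onset_ms), ]
  arrange(out, .data$onset_ms)
}
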