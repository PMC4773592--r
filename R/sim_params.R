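#' Parameters of the dual-route conflict accumulator and trace renderer
#'
#' Bundles every tunable constant of the trial simulator: the accumulator that
#' produces decision times and response sides, the non-decision (oculomotor
#' preparation) time, between-participant variability, and the geometry and
#' noise of the rendered gaze trace.
#'
#' The accumulator follows the dual-route account of conflict tasks: a
#' controlled route with constant drift `mu_c` toward the instructed response,
#' and an automatic route contributing a transient pulse of activation
#' `a(t) = A * (t/tau) * exp(1 - t/tau)` toward the stimulus location (peaking
#' at `t = tau` with value `A`).  Evidence starts at a Beta-distributed
#' per-trial point `x0` and diffuses with standard deviation `sigma` per
#' square-root millisecond until it reaches `+b` (correct) or `-b` (error).
#' Reaction time is the crossing time plus a non-decision time, interpreted as
#' ending at saccade onset.
#'
#' Defaults were calibrated by coarse grid search so that a simulated session
#' of healthy adults reproduces the usual oculomotor Simon-task summaries:
#' mean saccade latency around 330 ms, a congruence effect of roughly 20-30 ms
#' that shrinks as latency grows, an overall accuracy difference of a few
#' percentage points, and fast errors concentrated in the earliest latency
#' septile of the incongruent condition.
#'
#' @param mu_c Controlled drift rate (evidence/ms, toward the correct bound).
#' @param A Peak automatic activation (evidence units, toward the target
#'   location).
#' @param tau Time to peak of the automatic pulse (ms).
#' @param b Decision bound (evidence units; symmetric at `+b`/`-b`).
#' @param sigma Diffusion noise SD per sqrt(ms).
#' @param t0_mean,t0_sd Mean and trial-to-trial SD of the non-decision time
#'   (ms).  Draws are floored at `t0_floor`.
#' @param sd_mu_participant,sd_t0_participant Between-participant SDs of
#'   `mu_c` and `t0_mean`.
#' @param x0_shape Shape of the symmetric Beta distribution of the relative
#'   starting point.
#' @param x0_range Half-range of the starting point as a fraction of `b`.
#' @param cap_ms Per-trial simulation cap; trials that have not crossed a
#'   bound by then are returned as no-response.
#' @param t0_floor Lower bound for drawn non-decision times (ms).
#' @param eccentricity_deg Target eccentricity of the rendered saccade
#'   (degrees; right positive).
#' @param sample_rate_hz Sampling rate of the rendered gaze trace.
#' @param trace_noise_deg SD of Gaussian positional noise added to every
#'   rendered sample (degrees).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params()
#' p$mu_c
#' @export
sim_params <- function(mu_c = 0.50,
                       A = 30,
                       tau = 21.5,
                       b = 75,
                       sigma = 4,
                       t0_mean = 200,
                       t0_sd = 35,
                       sd_mu_participant = 0.03,
                       sd_t0_participant = 25,
                       x0_shape = 3,
                       x0_range = 0.6,
                       cap_ms = 1500,
                       t0_floor = 50,
                       eccentricity_deg = 12,
                       sample_rate_hz = 300,
                       trace_noise_deg = 0.05) {
  p <- list(mu_c = mu_c, A = A, tau = tau, b = b, sigma = sigma,
            t0_mean = t0_mean, t0_sd = t0_sd,
            sd_mu_participant = sd_mu_participant,
            sd_t0_participant = sd_t0_participant,
            x0_shape = x0_shape, x0_range = x0_range,
            cap_ms = cap_ms, t0_floor = t0_floor,
            eccentricity_deg = eccentricity_deg,
            sample_rate_hz = sample_rate_hz,
            trace_noise_deg = trace_noise_deg)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x), logical(1))]
  if (length(bad))
    abort_ocusimon(paste0("non-finite or non-scalar parameter: ",
                          paste(bad, collapse = ", ")),
                   "ocusimon_input_error")
  stopifnot_param(p$b > 0, "b must be > 0")
  stopifnot_param(p$sigma >= 0, "sigma must be >= 0")
  stopifnot_param(p$tau > 0, "tau must be > 0")
  stopifnot_param(p$sample_rate_hz > 0, "sample_rate_hz must be > 0")
  stopifnot_param(p$t0_sd >= 0 && p$sd_mu_participant >= 0 &&
                    p$sd_t0_participant >= 0 && p$trace_noise_deg >= 0,
                  "all SDs must be >= 0")
  stopifnot_param(p$x0_shape > 0 && p$x0_range >= 0 && p$x0_range < 1,
                  "x0_shape must be > 0 and x0_range in [0, 1)")
  structure(p, class = "sim_params")
}

stopifnot_param <- function(ok, msg) {
  if (!isTRUE(ok)) abort_ocusimon(msg, "ocusimon_input_error")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  accumulator: mu_c=%g A=%g tau=%g b=%g sigma=%g x0~Beta(%g)*%g*b\n",
              x$mu_c, x$A, x$tau, x$b, x$sigma, x$x0_shape, x$x0_range))
  cat(sprintf("  non-decision: %g +- %g ms (floor %g); between-participant sd_mu=%g sd_t0=%g\n",
              x$t0_mean, x$t0_sd, x$t0_floor,
              x$sd_mu_participant, x$sd_t0_participant))
  cat(sprintf("  rendering: %g deg at %g Hz, trace noise %g deg, cap %g ms\n",
              x$eccentricity_deg, x$sample_rate_hz, x$trace_noise_deg,
              x$cap_ms))
  invisible(x)
}
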