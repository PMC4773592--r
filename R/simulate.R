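#' Simulate decisions from the dual-route conflict accumulator
#'
#' Runs the accumulator for `n` trials of one congruence condition.  Evidence
#' starts at a Beta-distributed point, accumulates controlled drift toward
#' the correct bound plus a transient automatic pulse toward the stimulus
#' location (helping on congruent trials, opposing on incongruent ones), and
#' diffuses with Gaussian noise in 1-ms Euler steps.  A positive crossing is
#' the correct response; trials still undecided at `params$cap_ms` come back
#' as no-response.
#'
#' Randomness is taken from R's global RNG, so results are reproducible with
#' [set.seed()].
#'
#' @param params A [sim_params()] object.
#' @param congruence `"congruent"` or `"incongruent"`.
#' @param n Number of trials to simulate.
#' @param participant_effects Optional list with elements `mu_offset` and
#'   `t0_offset` (both default 0), the participant's deviations from the
#'   population `mu_c` and `t0_mean`.
#'
#' @return A tibble with one row per trial: `decision_ms` (bound-crossing
#'   time; `NA` for no-response), `t0_ms` (non-decision time), `rt_ms`
#'   (latency = decision + non-decision), `correct` (logical; `NA` for
#'   no-response) and `responded`.
#' @examples
#' set.seed(1)
#' simulate_decision(sim_params(), "incongruent", n = 5)
#' @export
simulate_decision <- function(params, congruence = c("congruent", "incongruent"),
                              n = 1,
                              participant_effects = list(mu_offset = 0,
                                                         t0_offset = 0)) {
  stopifnot(inherits(params, "sim_params"))
  congruence <- match.arg(congruence)
  mu_off <- participant_effects$mu_offset %||% 0
  t0_off <- participant_effects$t0_offset %||% 0
  if (!all(is.finite(c(mu_off, t0_off, n))) || n < 1)
    abort_ocusimon("participant effects and n must be finite, n >= 1",
                   "ocusimon_input_error")
  s <- if (congruence == "congruent") 1 else -1
  x0 <- (2 * rbeta(n, params$x0_shape, params$x0_shape) - 1) *
    params$x0_range * params$b
  res <- simulate_decisions_cpp(rep(params$mu_c + mu_off, n), rep(s, n), x0,
                                params$A, params$tau, params$b, params$sigma,
                                params$cap_ms)
  t0 <- pmax(params$t0_mean + t0_off + rnorm(n, 0, params$t0_sd),
             params$t0_floor)
  decision <- as.numeric(res$decision_ms)
  tibble(decision_ms = decision,
         t0_ms = t0,
         rt_ms = decision + t0,
         correct = ifelse(is.na(decision), NA, res$sign > 0),
         responded = !is.na(decision))
}

# analytic minimum-jerk position profile on [0, 1]
min_jerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

# main-sequence approximation of saccade duration
saccade_duration_ms <- function(amplitude_deg) 2.2 * abs(amplitude_deg) + 21

#' Render a simulated trial as a 300-Hz gaze trace
#'
#' Turns a decision (latency plus response side) into a horizontal
#' gaze-sample recording: fixation at 0 deg with Gaussian positional noise,
#' then a saccade to +/- `eccentricity_deg` starting exactly at the decision
#' latency (non-decision time is taken to end at saccade onset, so latency is
#' saccade latency), following a minimum-jerk position profile whose duration
#' comes from the main-sequence rule `2.2 * amplitude + 21` ms, then fixation
#' at the landing position.  Samples run from fixation onset
#' (`-fixation_ms`) to target offset; the target onset defines t = 0 and
#' rightward is positive.
#'
#' @param decision One-row tibble as returned by [simulate_decision()].
#' @param design One-row design tibble as returned by [generate_design()].
#' @param params A [sim_params()] object.
#'
#' @return An object of class `trial_recording`: a list with `design` (the
#'   input row), `samples` (tibble `t_ms`, `x_deg`, `y_deg`), `events`
#'   (tibble `label`, `t_ms` with fixation onset, target onset, target
#'   offset) and `ground_truth` (list with the true onset time, response
#'   side, onset sample index, and whether a saccade was rendered).
#' @examples
#' des <- generate_design(1, 1, 4, seed = 1)
#' set.seed(2)
#' dec <- simulate_decision(sim_params(), des$congruence[1], n = 1)
#' rec <- render_trial_recording(dec, des[1, ], sim_params())
#' range(rec$samples$t_ms)
#' @export
render_trial_recording <- function(decision, design, params) {
  stopifnot(inherits(params, "sim_params"), nrow(decision) == 1,
            nrow(design) == 1)
  dt <- 1000 / params$sample_rate_hz
  t <- seq(-design$fixation_ms, design$target_ms, by = dt)
  n <- length(t)
  x <- rnorm(n, 0, params$trace_noise_deg)
  y <- rnorm(n, 0, params$trace_noise_deg)

  gt <- list(responded = isTRUE(decision$responded),
             rt_ms = decision$rt_ms,
             decision_ms = decision$decision_ms,
             response_side = NA_character_,
             onset_index = NA_integer_,
             rendered = FALSE)

  if (isTRUE(decision$responded)) {
    correct_side <- mapped_response_side(design$target_color, design$mapping)
    side <- if (isTRUE(decision$correct)) correct_side else
      setdiff(c("left", "right"), correct_side)
    landing <- if (side == "right") params$eccentricity_deg else
      -params$eccentricity_deg
    onset <- decision$rt_ms
    dur <- saccade_duration_ms(params$eccentricity_deg)
    if (onset + dur <= design$target_ms) {
      u <- (t - onset) / dur
      moving <- u > 0 & u < 1
      x[moving] <- x[moving] + landing * min_jerk(u[moving])
      x[u >= 1] <- x[u >= 1] + landing
      gt$response_side <- side
      gt$onset_index <- which(t >= onset)[1]
      gt$rendered <- TRUE
    }
  }

  structure(list(
    design = design,
    samples = tibble(t_ms = t, x_deg = x, y_deg = y),
    events = tibble(label = c("fixation_onset", "target_onset",
                              "target_offset"),
                    t_ms = c(-design$fixation_ms, 0, design$target_ms)),
    ground_truth = gt), class = "trial_recording")
}

#' Simulate a full multi-participant session
#'
#' Composes [generate_design()], [simulate_decision()] and (optionally)
#' [render_trial_recording()] for a whole study.  Participant-level random
#' effects on drift and non-decision time are drawn once per participant;
#' every participant gets an independent, deterministic RNG substream derived
#' from the master seed, so the output is fully reproducible.
#'
#' @param n_participants Number of participants.
#' @param params A [sim_params()] object.
#' @param n_blocks,trials_per_block Session structure (defaults 5 x 60).
#' @param seed Master seed.
#' @param render If `TRUE` (default) each trial is also rendered as a gaze
#'   trace; with `FALSE` only the ground-truth outcome table is produced,
#'   which is much faster for distribution-level studies.
#' @param mapping_assignment Passed to [generate_design()].
#'
#' @return A list of class `session` with `designs` (tibble),
#'   `ground_truth` (tibble: one row per trial with congruence, true latency,
#'   true side, correctness), `recordings` (list of `trial_recording`, or
#'   `NULL` when `render = FALSE`), and `provenance` (seed, parameters,
#'   package version).
#' @examples
#' s <- simulate_session(1, sim_params(), n_blocks = 1, trials_per_block = 8,
#'                       seed = 7)
#' nrow(s$ground_truth)
#' @export
simulate_session <- function(n_participants, params = sim_params(),
                             n_blocks = 5, trials_per_block = 60, seed = 1,
                             render = TRUE,
                             mapping_assignment = "alternate") {
  stopifnot(inherits(params, "sim_params"))
  designs <- generate_design(n_participants, n_blocks, trials_per_block,
                             mapping_assignment, seed = seed)
  pp_seeds <- derive_seeds(seed + 1L, n_participants)
  ids <- unique(designs$participant_id)

  out <- vector("list", n_participants)
  recs <- if (render) vector("list", n_participants) else NULL
  for (i in seq_len(n_participants)) {
    dpp <- designs[designs$participant_id == ids[i], ]
    out_i <- with_local_seed(pp_seeds[i], {
      eff <- list(mu_offset = rnorm(1, 0, params$sd_mu_participant),
                  t0_offset = rnorm(1, 0, params$sd_t0_participant))
      # all decisions are drawn (batched per condition) before any
      # rendering, so the ground-truth table does not depend on whether
      # traces are rendered
      dec <- vector("list", nrow(dpp))
      for (cond in c("congruent", "incongruent")) {
        idx <- which(dpp$congruence == cond)
        if (!length(idx)) next
        batch <- simulate_decision(params, cond, n = length(idx), eff)
        for (j in seq_along(idx)) dec[[idx[j]]] <- batch[j, ]
      }
      rec <- if (render)
        lapply(seq_len(nrow(dpp)), function(j)
          render_trial_recording(dec[[j]], dpp[j, ], params))
      list(dec = bind_rows(dec), rec = rec)
    })
    out[[i]] <- bind_rows(dpp, .id = NULL) %>%
      mutate(decision_ms = out_i$dec$decision_ms,
             t0_ms = out_i$dec$t0_ms,
             rt_ms = out_i$dec$rt_ms,
             correct = out_i$dec$correct,
             responded = out_i$dec$responded,
             response_side = dplyr::case_when(
               !responded ~ NA_character_,
               correct ~ .data$mapped_side,
               TRUE ~ ifelse(.data$mapped_side == "left", "right", "left")))
    if (render) recs[[i]] <- out_i$rec
  }

  structure(list(
    designs = designs,
    ground_truth = bind_rows(out),
    recordings = if (render) do.call(c, recs) else NULL,
    provenance = list(seed = seed,
                      params = unclass(params),
                      package_version = as.character(packageVersion("ocusimon")),
                      created = "ocusimon::simulate_session")),
    class = "session")
}
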