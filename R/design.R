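#' Generate a balanced Simon-task session design
#'
#' Builds the planned trial list for one or more participants: within every
#' block each of the four (target colour) x (target side) combinations occurs
#' equally often in pseudo-random order, so the session is balanced overall.
#' Colour-to-direction mapping alternates across participants (half respond
#' left to blue, half left to yellow).  A trial is congruent when the side
#' instructed by the target's colour coincides with the side it appears on.
#'
#' Fixation duration is drawn per trial from 875, 1000, 1125 or 1250 ms
#' (125-ms steps); the target stays on for 1000 ms and the inter-trial
#' interval is 1250 ms.
#'
#' @param n_participants Number of participants.
#' @param n_blocks Blocks per session (default 5).
#' @param trials_per_block Trials per block (default 60; must be divisible by
#'   4 so the colour x side combinations balance).
#' @param mapping_assignment `"alternate"` (default) assigns blue->left to
#'   odd-numbered participants and yellow->left to even-numbered ones;
#'   `"blue_left"` or `"yellow_left"` force one mapping for everyone.
#' @param seed Integer seed; the full design sequence is reproducible from it.
#'
#' @return A tibble with one row per planned trial: `participant_id`, `block`,
#'   `trial`, `target_color`, `target_side`, `mapping`, `congruence`,
#'   `fixation_ms`, `target_ms`, `iti_ms`.
#' @examples
#' d <- generate_design(1, 5, 60, seed = 1)
#' nrow(d)                       # 300
#' table(d$target_color, d$target_side)
#' @export
generate_design <- function(n_participants, n_blocks = 5,
                            trials_per_block = 60,
                            mapping_assignment = c("alternate", "blue_left",
                                                   "yellow_left"),
                            seed = 1) {
  mapping_assignment <- match.arg(mapping_assignment)
  stopifnot_param(is.numeric(n_participants) && n_participants >= 1,
                  "n_participants must be >= 1")
  stopifnot_param(is.numeric(n_blocks) && n_blocks >= 1,
                  "n_blocks must be >= 1")
  if (trials_per_block %% 4 != 0)
    abort_ocusimon("trials_per_block must be divisible by 4 to balance the colour x side combinations",
                   "ocusimon_balance_error")

  combos <- expand.grid(target_color = c("blue", "yellow"),
                        target_side  = c("left", "right"),
                        stringsAsFactors = FALSE)
  fix_steps <- seq(875, 1250, by = 125)
  pp_seeds <- derive_seeds(seed, n_participants)

  one_participant <- function(i) {
    mapping <- switch(mapping_assignment,
                      alternate   = if (i %% 2 == 1) "blue_left" else "yellow_left",
                      blue_left   = "blue_left",
                      yellow_left = "yellow_left")
    left_color <- if (mapping == "blue_left") "blue" else "yellow"
    with_local_seed(pp_seeds[i], {
      blocks <- lapply(seq_len(n_blocks), function(bl) {
        idx <- sample(rep(seq_len(4), trials_per_block / 4))
        tibble(
          participant_id = sprintf("P%02d", i),
          block = bl,
          trial = seq_len(trials_per_block),
          target_color = combos$target_color[idx],
          target_side  = combos$target_side[idx],
          mapping = mapping,
          fixation_ms = sample(fix_steps, trials_per_block, replace = TRUE),
          target_ms = 1000,
          iti_ms = 1250)
      })
      bind_rows(blocks)
    }) %>%
      mutate(mapped_side = ifelse(.data$target_color == left_color,
                                  "left", "right"),
             congruence = ifelse(.data$mapped_side == .data$target_side,
                                 "congruent", "incongruent"))
  }

  bind_rows(lapply(seq_len(n_participants), one_participant)) %>%
    dplyr::select("participant_id", "block", "trial", "target_color",
                  "target_side", "mapping", "mapped_side", "congruence",
                  "fixation_ms", "target_ms", "iti_ms")
}

# side instructed by the colour under a given mapping
mapped_response_side <- function(target_color, mapping) {
  left_color <- ifelse(mapping == "blue_left", "blue", "yellow")
  ifelse(target_color == left_color, "left", "right")
}
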