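#' Extract the per-trial response from detected saccades
#'
#' The participant's response is the very first eye movement after target
#' onset, whether directed toward or away from the target.  Saccades with an
#' amplitude below `amplitude_threshold_deg` (micro-movements around
#' fixation) are skipped rather than voiding the trial.  The response is
#' correct when its direction matches the side instructed by the target's
#' colour under the participant's mapping.
#'
#' @param recording A `trial_recording` (its `design` supplies colour,
#'   mapping, congruence).
#' @param saccades Tibble from [detect_saccades()], time-ordered.
#' @param amplitude_threshold_deg Minimum amplitude for a saccade to count as
#'   a response (default 2 deg).
#' @return A one-row tibble (pre-exclusion): `participant_id`, `block`,
#'   `trial`, `congruence`, `rt_ms`, `response_side` (`"left"`, `"right"` or
#'   `NA`), `correct`, `responded`, `exclusion_reason` (`"none"`,
#'   `"no_response"` or `"amplitude_lt_2deg_only"`), `excluded`.
#' @export
extract_response <- function(recording, saccades,
                             amplitude_threshold_deg = 2) {
  design <- recording$design
  post <- saccades[saccades$onset_ms >= 0, , drop = FALSE]
  qual <- post[post$amplitude_deg >= amplitude_threshold_deg, , drop = FALSE]

  if (nrow(qual)) {
    first <- qual[1, ]
    side <- first$direction
    correct_side <- mapped_response_side(design$target_color, design$mapping)
    res <- tibble(rt_ms = first$onset_ms, response_side = side,
                  correct = side == correct_side, responded = TRUE,
                  exclusion_reason = "none")
  } else {
    reason <- if (nrow(post)) "amplitude_lt_2deg_only" else "no_response"
    res <- tibble(rt_ms = NA_real_, response_side = NA_character_,
                  correct = NA, responded = FALSE, exclusion_reason = reason)
  }
  tibble(participant_id = design$participant_id, block = design$block,
         trial = design$trial, congruence = design$congruence) %>%
    dplyr::bind_cols(res) %>%
    mutate(excluded = .data$exclusion_reason != "none")
}

#' Apply the latency and outlier exclusion rules
#'
#' Two passes over the trial results.  Pass 1 excludes trials with no
#' response, anticipatory latencies below `lo_ms` (strict `<`) and latencies
#' above `hi_ms` (strict `>`, the target duration); latencies exactly at a
#' bound are kept.  Pass 2 computes, per participant over the trials that
#' survive pass 1 (conditions pooled), the mean and SD of latency and
#' excludes trials more than `sd_mult` SDs from the mean — a single pass,
#' not iterated.
#'
#' @param results Tibble of trial results from [extract_response()] (or the
#'   ground-truth equivalent); must carry `participant_id`, `rt_ms`,
#'   `responded`, `exclusion_reason`.
#' @param lo_ms,hi_ms Latency bounds (defaults 100 and 1000 ms).
#' @param sd_mult SD multiplier of the outlier rule (default 3).
#' @return A list with `results` (input annotated with final `excluded` and
#'   `exclusion_reason`) and `summary` (an `exclusion_summary`: `n_total`,
#'   per-reason counts, `n_excluded`, `fraction_excluded`).
#' @export
apply_exclusions <- function(results, lo_ms = 100, hi_ms = 1000,
                             sd_mult = 3) {
  reasons <- c("none", "no_response", "amplitude_lt_2deg_only",
               "latency_lt_100", "latency_gt_1000", "outlier_3sd")
  if (!nrow(results)) {
    summary <- list(n_total = 0L,
                    n_excluded_by_reason = setNames(integer(5), reasons[-1]),
                    n_excluded = 0L, fraction_excluded = NaN)
    return(list(results = results,
                summary = structure(summary, class = "exclusion_summary")))
  }
  res <- results
  pre <- res$exclusion_reason %||% rep("none", nrow(res))
  reason <- ifelse(pre != "none", pre,
                   ifelse(!res$responded | is.na(res$rt_ms), "no_response",
                          ifelse(res$rt_ms < lo_ms, "latency_lt_100",
                                 ifelse(res$rt_ms > hi_ms, "latency_gt_1000",
                                        "none"))))

  # pass 2: per-participant 3-SD rule on surviving trials, pooled over
  # congruence, single pass
  surv <- reason == "none"
  for (pp in unique(res$participant_id)) {
    i <- surv & res$participant_id == pp
    if (sum(i) >= 2) {
      m <- mean(res$rt_ms[i]); s <- sd(res$rt_ms[i])
      out <- i & abs(res$rt_ms - m) > sd_mult * s
      reason[out] <- "outlier_3sd"
    }
  }

  res$exclusion_reason <- reason
  res$excluded <- reason != "none"
  counts <- vapply(reasons[-1], function(r) sum(reason == r), integer(1))
  summary <- structure(list(
    n_total = nrow(res),
    n_excluded_by_reason = counts,
    n_excluded = sum(res$excluded),
    fraction_excluded = sum(res$excluded) / nrow(res)),
    class = "exclusion_summary")
  list(results = res, summary = summary)
}

#' @export
print.exclusion_summary <- function(x, ...) {
  cat(sprintf("<exclusion_summary> %d of %d trials excluded (%.2f%%)\n",
              x$n_excluded, x$n_total, 100 * x$fraction_excluded))
  nz <- x$n_excluded_by_reason[x$n_excluded_by_reason > 0]
  for (r in names(nz)) cat(sprintf("  %-24s %d\n", r, nz[[r]]))
  invisible(x)
}
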