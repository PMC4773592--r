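#' Assign rank-ordered observations to equal-count bins (septiles)
#'
#' Stable rank binning: values are ordered (ties keep input order) and cut
#' into `n_bins` contiguous groups whose sizes differ by at most one, the
#' larger groups going to the earliest bins (largest-remainder-first).  Bin
#' assignments are returned in the original input order.
#'
#' @param rts Numeric vector (latencies, ms); non-empty.
#' @param n_bins Number of bins (default 7).
#' @return Integer vector of bin indices, same length and order as `rts`.
#' @examples
#' bin_septiles(c(300, 100, 200), n_bins = 3)
#' @export
bin_septiles <- function(rts, n_bins = 7) {
  n <- length(rts)
  if (!n) abort_ocusimon("rts must be non-empty", "ocusimon_input_error")
  stopifnot_param(n_bins >= 1, "n_bins must be >= 1")
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n %% n_bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes == 0))
    warning("fewer observations than bins; some bins are empty")
  bins <- integer(n)
  bins[order(rts)] <- rep(seq_len(n_bins), sizes)  # order() is stable
  bins
}

#' Conditional accuracy functions over latency septiles
#'
#' For each participant and congruence condition, all included trials
#' (correct and error) are rank-binned into `n_bins` latency septiles via
#' [bin_septiles()]; each bin contributes its mean latency and proportion
#' correct.  The aggregate is the unweighted mean of the per-participant bin
#' values (vincentized averaging), with the between-participant SE.
#'
#' @param results Trial results with exclusions applied; error trials are
#'   retained.
#' @param n_bins Number of bins (default 7).
#' @return A list with `per_participant` (tibble: `participant_id`,
#'   `congruence`, `bin`, `mean_rt_ms`, `accuracy`, `n_trials`) and
#'   `aggregate` (tibble: `congruence`, `bin`, `mean_rt_ms`, `accuracy`,
#'   `se_accuracy`, `n_participants`).
#' @export
compute_caf <- function(results, n_bins = 7) {
  inc <- filter(results, !.data$excluded, .data$responded)
  if (!nrow(inc))
    abort_ocusimon("no included trials", "ocusimon_input_error")
  per <- inc %>%
    group_by(.data$participant_id, .data$congruence) %>%
    mutate(bin = bin_septiles(.data$rt_ms, n_bins)) %>%
    group_by(.data$participant_id, .data$congruence, .data$bin) %>%
    summarise(mean_rt_ms = mean(.data$rt_ms),
              accuracy = mean(.data$correct),
              n_trials = dplyr::n(), .groups = "drop")
  agg <- per %>%
    group_by(.data$congruence, .data$bin) %>%
    summarise(mean_rt_ms = mean(.data$mean_rt_ms),
              se_accuracy = sd(.data$accuracy) / sqrt(dplyr::n()),
              accuracy = mean(.data$accuracy),
              n_participants = dplyr::n(), .groups = "drop") %>%
    dplyr::relocate("accuracy", .before = "se_accuracy")
  list(per_participant = per, aggregate = agg)
}

#' Delta plots: the congruence effect as a function of latency
#'
#' Correct included trials only.  Within each participant, latencies are
#' septile-binned separately for the congruent and the incongruent
#' condition; the k-th delta pairs the k-th incongruent bin mean with the
#' k-th congruent bin mean (`delta = incongruent - congruent`), plotted at
#' the midpoint of the two means.  The aggregate is the unweighted mean over
#' participants per bin.  Participants lacking correct trials in either
#' condition of some bin are omitted from the aggregate with a warning.
#'
#' @param results Trial results with exclusions applied.
#' @param n_bins Number of bins (default 7).
#' @return A list with `per_participant` (tibble: `participant_id`, `bin`,
#'   `mean_rt_congruent_ms`, `mean_rt_incongruent_ms`, `delta_ms`,
#'   `bin_rt_ms`) and `aggregate` (tibble: `bin`, `delta_ms`, `se_delta`,
#'   `bin_rt_ms`, `n_participants`).
#' @export
compute_delta <- function(results, n_bins = 7) {
  ok <- filter(results, !.data$excluded, .data$responded, .data$correct)
  if (!nrow(ok))
    abort_ocusimon("no correct included trials", "ocusimon_input_error")
  per_cond <- ok %>%
    group_by(.data$participant_id, .data$congruence) %>%
    mutate(bin = bin_septiles(.data$rt_ms, n_bins)) %>%
    group_by(.data$participant_id, .data$congruence, .data$bin) %>%
    summarise(mean_rt_ms = mean(.data$rt_ms), .groups = "drop")
  wide <- tidyr::pivot_wider(per_cond, names_from = "congruence",
                             values_from = "mean_rt_ms")
  for (col in c("congruent", "incongruent"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  incomplete <- unique(wide$participant_id[
    is.na(wide$congruent) | is.na(wide$incongruent)])
  n_pairs <- table(wide$participant_id)
  incomplete <- union(incomplete,
                      names(n_pairs)[n_pairs < n_bins])
  if (length(incomplete)) {
    warning(sprintf("omitting %d participant(s) without correct trials in every bin of both conditions: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")))
    wide <- wide[!wide$participant_id %in% incomplete, ]
  }
  per <- wide %>%
    mutate(mean_rt_congruent_ms = .data$congruent,
           mean_rt_incongruent_ms = .data$incongruent,
           delta_ms = .data$incongruent - .data$congruent,
           bin_rt_ms = (.data$congruent + .data$incongruent) / 2) %>%
    dplyr::select("participant_id", "bin", "mean_rt_congruent_ms",
                  "mean_rt_incongruent_ms", "delta_ms", "bin_rt_ms")
  agg <- per %>%
    group_by(.data$bin) %>%
    summarise(se_delta = sd(.data$delta_ms) / sqrt(dplyr::n()),
              delta_ms = mean(.data$delta_ms),
              bin_rt_ms = mean(.data$bin_rt_ms),
              n_participants = dplyr::n(), .groups = "drop") %>%
    dplyr::relocate("delta_ms", .before = "se_delta")
  list(per_participant = per, aggregate = agg)
}
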