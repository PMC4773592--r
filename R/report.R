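#' Mean latency and accuracy per congruence condition
#'
#' Per-participant means first (latency over correct included trials,
#' accuracy over all included trials), then the across-participant mean and
#' standard error — the error-bar convention of group-level congruence
#' figures.
#'
#' @param trials Trial results with exclusions applied.
#' @return A tibble: `congruence`, `mean_rt_ms`, `se_rt_ms`, `accuracy`,
#'   `se_accuracy`, `n_participants`.
#' @export
summarize_congruence <- function(trials) {
  inc <- filter(trials, !.data$excluded, .data$responded)
  per <- inc %>%
    group_by(.data$participant_id, .data$congruence) %>%
    summarise(rt = mean(.data$rt_ms[.data$correct]),
              acc = mean(.data$correct), .groups = "drop")
  per %>%
    group_by(.data$congruence) %>%
    summarise(mean_rt_ms = mean(.data$rt),
              se_rt_ms = sd(.data$rt) / sqrt(dplyr::n()),
              accuracy = mean(.data$acc),
              se_accuracy = sd(.data$acc) / sqrt(dplyr::n()),
              n_participants = dplyr::n(), .groups = "drop")
}

default_config <- function() {
  list(seed = NULL,
       n_participants = 43,
       n_blocks = 5,
       trials_per_block = 60,
       sim = unclass(sim_params()),
       detector = unclass(detector_params()),
       exclusions = list(lo_ms = 100, hi_ms = 1000, sd_mult = 3),
       n_bins = 7,
       render = TRUE,
       figures = TRUE)
}

validate_config <- function(config) {
  base <- default_config()
  config <- utils::modifyList(base, config)
  if (is.null(config$seed) || !is.finite(config$seed))
    abort_ocusimon("config must provide an integer seed",
                   "ocusimon_config_error")
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    abort_ocusimon(paste0("unknown config field(s): ",
                          paste(unknown, collapse = ", ")),
                   "ocusimon_config_error")
  config$sim <- do.call(sim_params, config$sim)
  config$detector <- do.call(detector_params, config$detector)
  config
}

log_stage <- function(log_path, stage, ...) {
  entry <- c(list(stage = stage, elapsed_s = NULL), list(...))
  entry <- entry[!vapply(entry, is.null, logical(1))]
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE)
}

#' Run the whole analysis pipeline from one configuration
#'
#' Orchestrates simulate -> detect -> extract -> exclude -> distributional
#' statistics -> mixed-model inference as a single reproducible run: every
#' table behind a figure is written as CSV, inference results as JSON, and a
#' JSON-lines log records per-stage timing and counts.  Re-running with the
#' same config reproduces all numeric outputs.  With `render = TRUE` the
#' response is extracted from rendered gaze traces through the saccade
#' detector; with `render = FALSE` the simulated outcomes are analysed
#' directly (fast, for distribution-level studies).
#'
#' @param config A named list (or path to a YAML file) overriding
#'   `default_config()`: `seed` (required), `n_participants`, `n_blocks`,
#'   `trials_per_block`, `sim` (see [sim_params()]), `detector` (see
#'   [detector_params()]), `exclusions`, `n_bins`, `render`, `figures`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the trial table, exclusion summary,
#'   congruence summary, CAF, delta, model fits and post hoc contrasts.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ocusimon_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  cfg_out <- config
  cfg_out$sim <- unclass(cfg_out$sim)
  cfg_out$detector <- unclass(cfg_out$detector)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  if (config$n_participants < 5)
    warning("fewer than 5 participants: mixed-model estimates will be unstable")

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      abort_ocusimon(paste0("stage '", name, "' failed: ",
                            conditionMessage(e)),
                     "ocusimon_pipeline_error"))
    log_stage(log_path, name,
              elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  session <- stage("simulate",
                   simulate_session(config$n_participants, config$sim,
                                    config$n_blocks, config$trials_per_block,
                                    seed = config$seed,
                                    render = config$render))

  trials <- stage("extract", {
    if (config$render) {
      rows <- lapply(session$recordings, function(rec)
        extract_response(rec, detect_saccades(rec, config$detector)))
      bind_rows(rows)
    } else {
      gt <- session$ground_truth
      tibble(participant_id = gt$participant_id, block = gt$block,
             trial = gt$trial, congruence = gt$congruence,
             rt_ms = gt$rt_ms, response_side = gt$response_side,
             correct = gt$correct, responded = gt$responded,
             exclusion_reason = ifelse(gt$responded, "none", "no_response"),
             excluded = !gt$responded)
    }
  })

  excl <- stage("exclusions",
                apply_exclusions(trials, config$exclusions$lo_ms,
                                 config$exclusions$hi_ms,
                                 config$exclusions$sd_mult))
  trials <- excl$results
  write.csv(trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_total = excl$summary$n_total,
         n_excluded = excl$summary$n_excluded,
         fraction_excluded = excl$summary$fraction_excluded,
         by_reason = as.list(excl$summary$n_excluded_by_reason)),
    file.path(out_dir, "exclusions.json"), auto_unbox = TRUE, digits = NA)

  congr <- stage("summarize", summarize_congruence(trials))
  caf <- stage("caf", compute_caf(trials, config$n_bins))
  delta <- stage("delta", compute_delta(trials, config$n_bins))
  write.csv(congr, file.path(out_dir, "congruence_summary.csv"),
            row.names = FALSE)
  write.csv(caf$aggregate, file.path(out_dir, "caf.csv"), row.names = FALSE)
  write.csv(delta$aggregate, file.path(out_dir, "delta.csv"),
            row.names = FALSE)

  inference <- stage("inference", {
    # a degenerate model on a small or error-free simulated cohort (for
    # instance complete separation) downgrades that fit to NULL with a
    # warning instead of aborting the whole run
    try_fit <- function(label, expr)
      tryCatch(expr, error = function(e) {
        warning(sprintf("%s model skipped: %s", label, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    rt_fit <- try_fit("latency", fit_rt_lmm(trials))
    acc_fit <- try_fit("accuracy", fit_acc_glmm(trials))
    caf_fit <- try_fit("CAF", fit_caf_glmm(trials, config$n_bins))
    posthoc <- if (!is.null(caf_fit))
      try_fit("post hoc", posthoc_congruence_by_bin(caf_fit))
    delta_fit <- try_fit("delta", fit_delta_lmm(delta$per_participant))
    list(rt = rt_fit, accuracy = acc_fit, caf = caf_fit, posthoc = posthoc,
         delta = delta_fit)
  })
  jsonlite::write_json(serialize_inference(inference),
                       file.path(out_dir, "inference.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(config$figures))
    stage("figures", try(write_figures(congr, caf$aggregate, delta$aggregate,
                                       out_dir), silent = TRUE))

  log_stage(log_path, "done", n_trials = nrow(trials),
            n_excluded = excl$summary$n_excluded)
  invisible(list(trials = trials, exclusions = excl$summary,
                 congruence = congr, caf = caf, delta = delta,
                 inference = inference, out_dir = out_dir))
}

serialize_model_fit <- function(m) {
  list(formula = m$formula,
       fixed_effects = as.list(as.data.frame(m$fixed_effects)),
       random_intercept_sd = m$random_intercept_sd,
       test = m$test[!vapply(m$test, is.null, logical(1))],
       n_obs = m$n_obs, singular = m$singular)
}

serialize_inference <- function(inf) {
  out <- lapply(inf[c("rt", "accuracy", "caf", "delta")], function(m)
    if (is.null(m)) NULL else serialize_model_fit(m))
  if (!is.null(inf$caf))
    out$caf$tests_all <- lapply(inf$caf$tests_all, function(t)
      t[!vapply(t, is.null, logical(1))])
  out$posthoc <- if (is.null(inf$posthoc)) NULL else
    as.list(as.data.frame(inf$posthoc))
  out
}

write_figures <- function(congr, caf_agg, delta_agg, out_dir) {
  gg_save <- function(p, name) {
    for (ext in c("png", "svg"))
      try(suppressMessages(ggplot2::ggsave(
        file.path(out_dir, paste0(name, ".", ext)), p,
        width = 5, height = 4, dpi = 150)), silent = TRUE)
  }
  p1 <- ggplot2::ggplot(congr, ggplot2::aes(.data$congruence,
                                            .data$mean_rt_ms)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rt_ms - .data$se_rt_ms,
                                        ymax = .data$mean_rt_ms + .data$se_rt_ms),
                           width = 0.2) +
    ggplot2::labs(y = "mean latency (ms)", x = NULL)
  gg_save(p1, "congruence_rt")
  p2 <- ggplot2::ggplot(caf_agg, ggplot2::aes(.data$mean_rt_ms,
                                              .data$accuracy,
                                              colour = .data$congruence)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "bin mean latency (ms)", y = "accuracy")
  gg_save(p2, "caf")
  p3 <- ggplot2::ggplot(delta_agg, ggplot2::aes(.data$bin_rt_ms,
                                                .data$delta_ms)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "bin latency (ms)", y = "delta (ms)")
  gg_save(p3, "delta")
  invisible(NULL)
}
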