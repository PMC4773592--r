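#' Write a session to disk as portable CSV plus a YAML manifest
#'
#' Serialises a session (designs, ground truth, recordings) to a directory:
#' `designs.csv`, `ground_truth.csv`, the gaze samples as one long
#' `recordings.csv` with a `trial_id` column (or one file per trial when
#' `per_trial = TRUE`), `events.csv`, and a `manifest.yaml` listing every
#' file with its MD5 checksum plus provenance (seed, package version).  All
#' files are UTF-8 CSV with a header row, `.` decimal separator, times in ms.
#'
#' @param session A `session` object from [simulate_session()], or any list
#'   with compatible `designs`, `ground_truth`, `recordings`, `provenance`.
#' @param directory Output directory (created if missing).
#' @param per_trial Write one `recording_<trial_id>.csv` per trial instead of
#'   one long file.
#'
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, directory, per_trial = FALSE) {
  if (is.null(session$provenance) || !length(session$provenance))
    abort_ocusimon("session provenance must be non-empty on write",
                   "ocusimon_input_error")
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  probe <- file.path(directory, ".write_probe")
  if (!ok || inherits(try(writeLines("", probe), silent = TRUE), "try-error"))
    abort_ocusimon(paste0("cannot write to directory: ", directory),
                   "ocusimon_io_error")
  unlink(probe)

  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(directory, name)
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    files <<- c(files, name)
  }
  wr(session$designs, "designs.csv")
  wr(session$ground_truth, "ground_truth.csv")

  recs <- session$recordings
  if (!is.null(recs)) {
    ids <- vapply(recs, function(r)
      sprintf("%s_b%02d_t%03d", r$design$participant_id, r$design$block,
              r$design$trial), character(1))
    if (per_trial) {
      for (k in seq_along(recs))
        wr(recs[[k]]$samples, paste0("recording_", ids[k], ".csv"))
    } else {
      long <- bind_rows(lapply(seq_along(recs), function(k)
        mutate(recs[[k]]$samples, trial_id = ids[k], .before = 1)))
      wr(long, "recordings.csv")
    }
    events <- bind_rows(lapply(seq_along(recs), function(k)
      mutate(recs[[k]]$events, trial_id = ids[k], .before = 1)))
    wr(events, "events.csv")
    gt <- bind_rows(lapply(recs, function(r)
      tibble(rendered = r$ground_truth$rendered,
             onset_index = r$ground_truth$onset_index %||% NA_integer_,
             response_side = r$ground_truth$response_side %||% NA_character_)))
    gt$trial_id <- ids
    wr(gt, "recording_truth.csv")
  }

  manifest <- list(
    format = "ocusimon-session/1",
    per_trial = per_trial,
    provenance = session$provenance,
    files = lapply(files, function(f)
      list(name = f,
           md5 = unname(tools::md5sum(file.path(directory, f))))))
  mpath <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a session back from a manifest, with strict validation
#'
#' Verifies every file's MD5 checksum against the manifest, required columns,
#' strictly increasing sample times and the presence of the three trial
#' events before returning the session.  Failures raise classed conditions:
#' `ocusimon_integrity_error` (checksum mismatch, naming the file) or
#' `ocusimon_format_error` (missing column, missing event, non-monotone
#' time).
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [write_session()].
#' @return A list of class `session` (recordings are returned as
#'   `trial_recording` objects when sample files are present).
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    abort_ocusimon(paste0("manifest not found: ", manifest_path),
                   "ocusimon_io_error")
  directory <- dirname(manifest_path)
  manifest <- yaml::read_yaml(manifest_path)

  for (f in manifest$files) {
    path <- file.path(directory, f$name)
    if (!file.exists(path))
      abort_ocusimon(paste0("file listed in manifest is missing: ", f$name),
                     "ocusimon_integrity_error")
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, f$md5))
      abort_ocusimon(paste0("checksum mismatch for ", f$name),
                     "ocusimon_integrity_error")
  }
  listed <- vapply(manifest$files, `[[`, character(1), "name")
  rd <- function(name) as_tibble(read.csv(file.path(directory, name),
                                          stringsAsFactors = FALSE))
  need_cols <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      abort_ocusimon(paste0(name, " is missing column(s): ",
                            paste(miss, collapse = ", ")),
                     "ocusimon_format_error")
  }

  designs <- rd("designs.csv")
  need_cols(designs, c("participant_id", "block", "trial", "target_color",
                       "target_side", "mapping", "congruence"), "designs.csv")
  ground_truth <- rd("ground_truth.csv")

  recordings <- NULL
  if ("events.csv" %in% listed) {
    events <- rd("events.csv")
    need_cols(events, c("trial_id", "label", "t_ms"), "events.csv")
    if (isTRUE(manifest$per_trial)) {
      rec_files <- grep("^recording_.*\\.csv$", listed, value = TRUE)
      rec_files <- setdiff(rec_files, "recording_truth.csv")
      ids <- sub("^recording_(.*)\\.csv$", "\\1", rec_files)
      samples_by_id <- lapply(rec_files, rd)
      names(samples_by_id) <- ids
    } else {
      long <- rd("recordings.csv")
      need_cols(long, c("trial_id", "t_ms", "x_deg", "y_deg"),
                "recordings.csv")
      samples_by_id <- split(long[c("t_ms", "x_deg", "y_deg")], long$trial_id)
      ids <- names(samples_by_id)
    }
    design_ids <- sprintf("%s_b%02d_t%03d", designs$participant_id,
                          designs$block, designs$trial)
    recordings <- lapply(ids, function(id) {
      smp <- as_tibble(samples_by_id[[id]])
      need_cols(smp, c("t_ms", "x_deg", "y_deg"), paste0("recording ", id))
      if (any(diff(smp$t_ms) <= 0))
        abort_ocusimon(paste0("non-monotone sample times in recording ", id),
                       "ocusimon_format_error")
      ev <- events[events$trial_id == id, c("label", "t_ms")]
      for (lab in c("fixation_onset", "target_onset", "target_offset"))
        if (sum(ev$label == lab) != 1L)
          abort_ocusimon(paste0("recording ", id, " must carry event '",
                                lab, "' exactly once"),
                         "ocusimon_format_error")
      structure(list(design = designs[match(id, design_ids), ],
                     samples = smp,
                     events = as_tibble(ev),
                     ground_truth = list(rendered = NA)),
                class = "trial_recording")
    })
    names(recordings) <- NULL
  }

  structure(list(designs = designs, ground_truth = ground_truth,
                 recordings = recordings,
                 provenance = manifest$provenance),
            class = "session")
}
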