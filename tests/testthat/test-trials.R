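fake_recording <- function(color = "blue", mapping = "blue_left") {
  left_color <- ifelse(mapping == "blue_left", "blue", "yellow")
  mapped <- ifelse(color == left_color, "left", "right")
  des <- tibble::tibble(participant_id = "P01", block = 1L, trial = 1L,
                        target_color = color, target_side = "right",
                        mapping = mapping,
                        congruence = ifelse(mapped == "right", "congruent",
                                            "incongruent"),
                        fixation_ms = 1000, target_ms = 1000, iti_ms = 1250)
  structure(list(design = des), class = "trial_recording")
}

saccade_row <- function(onset, amp, direction) {
  tibble::tibble(onset_ms = onset, offset_ms = onset + 40,
                 amplitude_deg = amp, peak_velocity_deg_s = 400,
                 direction = direction)
}

test_that("micro-movements are skipped and the first big saccade is the response", {
  rec <- fake_recording("yellow", "blue_left")   # yellow -> right
  sac <- rbind(saccade_row(150, 1, "left"), saccade_row(240, 12, "right"))
  r <- extract_response(rec, sac)
  expect_equal(r$rt_ms, 240)
  expect_identical(r$response_side, "right")
  expect_true(r$correct)
  expect_identical(r$exclusion_reason, "none")
})

test_that("a saccade toward the target on an incongruent trial is an error", {
  # blue -> left under blue_left, target on the right: going right is wrong
  rec <- fake_recording("blue", "blue_left")
  r <- extract_response(rec, saccade_row(300, 12, "right"))
  expect_false(r$correct)
  r2 <- extract_response(rec, saccade_row(300, 12, "left"))
  expect_true(r2$correct)
})

test_that("pre-target and absent saccades yield the right no-response reasons", {
  rec <- fake_recording()
  none <- extract_response(rec, saccade_row(150, 12, "right")[0, ])
  expect_identical(none$exclusion_reason, "no_response")
  expect_false(none$responded)
  only_micro <- extract_response(rec, saccade_row(200, 1.2, "right"))
  expect_identical(only_micro$exclusion_reason, "amplitude_lt_2deg_only")
  pre_target <- extract_response(rec, saccade_row(-80, 12, "right"))
  expect_identical(pre_target$exclusion_reason, "no_response")
})

test_that("latency bounds are strict and boundary latencies are kept", {
  res <- make_results("P01", "congruent",
                      rt_ms = c(90, 100, 500, 1000, 1001), correct = TRUE)
  out <- apply_exclusions(res)$results
  expect_identical(out$exclusion_reason,
                   c("latency_lt_100", "none", "none", "none",
                     "latency_gt_1000"))
})

test_that("the 3-SD outlier rule removes exactly the constructed outlier", {
  # 19 latencies at ~300 and one far out; verify against direct computation
  rts <- c(rep(300, 19) + seq(-9, 9, by = 1), 450)
  stopifnot(abs(450 - mean(rts)) > 3 * sd(rts))
  res <- make_results("P01", "congruent", rt_ms = rts, correct = TRUE)
  out <- apply_exclusions(res)
  expect_equal(sum(out$results$excluded), 1)
  expect_identical(out$results$exclusion_reason[out$results$rt_ms == 450],
                   "outlier_3sd")
  expect_equal(out$summary$n_excluded_by_reason[["outlier_3sd"]], 1)
})

test_that("exclusion bookkeeping conserves counts and is order-stable", {
  res <- random_results(4, 40, seed = 21)
  res$rt_ms[c(3, 50)] <- c(60, 1200)
  out <- apply_exclusions(res)
  s <- out$summary
  expect_equal(s$n_total, nrow(res))
  expect_equal(sum(s$n_excluded_by_reason), s$n_excluded)
  expect_equal(s$fraction_excluded, s$n_excluded / s$n_total)
  expect_equal(s$n_total - s$n_excluded, sum(!out$results$excluded))

  set.seed(1)
  perm <- sample(nrow(res))
  out2 <- apply_exclusions(res[perm, ])
  key <- function(d) d[order(d$participant_id, d$trial), ]$exclusion_reason
  expect_identical(key(out2$results), key(out$results))
})

test_that("empty input yields an empty summary, not an error", {
  out <- apply_exclusions(make_results(character(0), character(0),
                                       numeric(0), logical(0)))
  expect_equal(out$summary$n_total, 0)
  expect_equal(out$summary$n_excluded, 0)
})

test_that("no-response trials coming from the extractor stay excluded", {
  res <- make_results("P01", "congruent", rt_ms = c(NA, 300, 310),
                      correct = c(NA, TRUE, TRUE),
                      responded = c(FALSE, TRUE, TRUE))
  res$exclusion_reason <- c("amplitude_lt_2deg_only", "none", "none")
  res$excluded <- c(TRUE, FALSE, FALSE)
  out <- apply_exclusions(res)$results
  expect_identical(out$exclusion_reason[1], "amplitude_lt_2deg_only")
  expect_true(out$excluded[1])
})
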