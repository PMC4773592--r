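samples_from_x <- function(x, rate = 300) {
  tibble::tibble(t_ms = (seq_along(x) - 1) * 1000 / rate, x_deg = x,
                 y_deg = 0)
}

test_that("velocity of a constant trace is zero and of a ramp is exact", {
  s <- samples_from_x(rep(2.5, 50))
  expect_true(all(abs(compute_velocity(s)) < 1e-9))
  # x = 0.01 deg/ms -> 10 deg/s, exact for polynomials up to the order
  s2 <- samples_from_x(0.01 * (seq_len(50) - 1) * 1000 / 300)
  expect_true(all(abs(compute_velocity(s2) - 10) < 1e-6))
  expect_error(compute_velocity(samples_from_x(c(1, 2, 3))),
               class = "ocusimon_input_error")
})

test_that("the adaptive threshold finds the fixed point of mean + 6 SD", {
  # degenerate: all-zero velocities converge to 0 immediately
  expect_equal(adaptive_peak_threshold(rep(0, 100)), 0)
  # Gaussian noise, SD 5: fixed point ~ 6 * 5 = 30 (nearly no truncation)
  set.seed(1)
  v <- rnorm(10000, 0, 5)
  pt <- adaptive_peak_threshold(v)
  expect_gt(pt, 27); expect_lt(pt, 33)
  # the converged threshold does not depend on the starting value
  mixed <- c(rnorm(2000, 0, 8), runif(60, 200, 400) * sign(runif(60, -1, 1)))
  p80 <- adaptive_peak_threshold(mixed, detector_params(pt_init_deg_s = 80))
  p150 <- adaptive_peak_threshold(mixed, detector_params(pt_init_deg_s = 150))
  expect_lt(abs(p80 - p150), detector_params()$pt_tol_deg_s)
  # all samples above the initial threshold is degenerate input
  expect_error(adaptive_peak_threshold(rep(500, 10)),
               class = "ocusimon_degenerate_error")
})

make_recording <- function(rt, noise = 0, seed = 1, correct = TRUE) {
  des <- generate_design(1, 1, 4, seed = 1)[1, ]
  dec <- tibble::tibble(decision_ms = rt - 150, t0_ms = 150, rt_ms = rt,
                        correct = correct, responded = TRUE)
  set.seed(seed)
  render_trial_recording(dec, des, sim_params(trace_noise_deg = noise))
}

test_that("a rendered noise-free saccade is recovered with onset and amplitude fidelity", {
  for (rt in c(250, 251.3, 347.9)) {
    rec <- make_recording(rt)
    sac <- detect_saccades(rec)
    expect_equal(nrow(sac), 1)
    expect_lte(abs(sac$onset_ms - rt), 1000 / 300 + 1e-9)  # within 1 sample
    expect_lt(abs(sac$amplitude_deg - 12), 0.1)
    expect_identical(sac$direction,
                     ifelse(tail(rec$samples$x_deg, 1) > 0, "right", "left"))
  }
})

test_that("fixation-only noise traces produce no saccades", {
  des <- generate_design(1, 1, 4, seed = 1)[1, ]
  dec <- tibble::tibble(decision_ms = NA_real_, t0_ms = 150, rt_ms = NA_real_,
                        correct = NA, responded = FALSE)
  for (s in 1:20) {
    set.seed(s)
    rec <- render_trial_recording(dec, des, sim_params(trace_noise_deg = 0.1))
    expect_equal(nrow(detect_saccades(rec)), 0)
  }
})

test_that("two well-separated saccades are both detected, in time order", {
  dt <- 1000 / 300
  t <- seq(-500, 1000, by = dt)
  x <- numeric(length(t))
  add_sacc <- function(x, onset, amp) {
    dur <- 2.2 * abs(amp) + 21
    u <- pmin(pmax((t - onset) / dur, 0), 1)
    x + amp * (10 * u^3 - 15 * u^4 + 6 * u^5)
  }
  x <- add_sacc(x, 150, 12)
  x <- add_sacc(x, 650, -12)
  rec <- tibble::tibble(t_ms = t, x_deg = x, y_deg = 0)
  sac <- detect_saccades(rec)
  expect_equal(nrow(sac), 2)
  expect_identical(sac$direction, c("right", "left"))
  expect_true(all(diff(sac$onset_ms) > 0))
})

test_that("detection is deterministic and direction matches displacement", {
  rec <- make_recording(300, noise = 0.08, seed = 9)
  a <- detect_saccades(rec); b <- detect_saccades(rec)
  expect_identical(a, b)
  i0 <- which(rec$samples$t_ms == a$onset_ms[1])
  i1 <- which(rec$samples$t_ms == a$offset_ms[1])
  disp <- rec$samples$x_deg[i1] - rec$samples$x_deg[i0]
  expect_identical(a$direction[1], ifelse(disp >= 0, "right", "left"))
})

test_that("ground-truth saccades are recovered at realistic noise levels", {
  # property over 120 seeded trials at the noise ceiling 0.1 deg
  des <- generate_design(1, 1, 4, seed = 1)[1, ]
  p <- sim_params(trace_noise_deg = 0.1)
  set.seed(42)
  hits <- 0; n_rend <- 0
  for (i in 1:120) {
    dec <- simulate_decision(p, "congruent", 1)
    rec <- render_trial_recording(dec, des, p)
    if (!rec$ground_truth$rendered) next
    n_rend <- n_rend + 1
    sac <- detect_saccades(rec)
    sac <- sac[sac$onset_ms >= 0 & sac$amplitude_deg >= 2, ]
    if (nrow(sac) &&
        abs(sac$onset_ms[1] - rec$ground_truth$rt_ms) <= 2 * 1000 / 300)
      hits <- hits + 1
  }
  expect_gte(hits / n_rend, 0.99)
})
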