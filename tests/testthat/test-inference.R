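# direct Bernoulli generator for accuracy-model tests (no accumulator)
bernoulli_results <- function(n_pp, n_per_cell, p_con, p_inc, seed,
                              re_sd = 0) {
  set.seed(seed)
  rows <- lapply(seq_len(n_pp), function(i) {
    re <- rnorm(1, 0, re_sd)
    inv <- function(eta) 1 / (1 + exp(-eta))
    make_results(sprintf("P%02d", i),
                 rep(c("congruent", "incongruent"), each = n_per_cell),
                 rt_ms = runif(2 * n_per_cell, 200, 800),
                 correct = c(runif(n_per_cell) < inv(qlogis(p_con) + re),
                             runif(n_per_cell) < inv(qlogis(p_inc) + re)))
  })
  dplyr::bind_rows(rows)
}

test_that("with zero between-participant variance the RT model collapses to the raw difference", {
  rt <- c(runif(40, 250, 350), runif(40, 250, 350) + 25)
  res <- dplyr::bind_rows(lapply(1:4, function(i) {
    r <- make_results(sprintf("P%02d", i),
                      rep(c("congruent", "incongruent"), each = 40),
                      rt_ms = rt, correct = TRUE)
    r
  }))
  fit <- fit_rt_lmm(res)
  raw <- mean(res$rt_ms[res$congruence == "incongruent"]) -
    mean(res$rt_ms[res$congruence == "congruent"])
  est <- unname(fit$fixed_effects$estimate[
    fit$fixed_effects$name == "congruenceincongruent"])
  expect_equal(est, raw, tolerance = 1e-8)
  expect_true(fit$singular)
  expect_equal(fit$test$df2,
               fit$n_obs - length(unique(res$participant_id)) - 1)
})

test_that("an injected 25-ms latency shift is recovered within 3 SE", {
  p <- sim_params(A = 0)
  res <- quick_study(12, seed = 31, params = p,
                     n_blocks = 2, trials_per_block = 60)
  res$rt_ms[res$congruence == "incongruent"] <-
    res$rt_ms[res$congruence == "incongruent"] + 25
  fit <- fit_rt_lmm(res)
  i <- fit$fixed_effects$name == "congruenceincongruent"
  est <- fit$fixed_effects$estimate[i]; se <- fit$fixed_effects$se[i]
  expect_lt(abs(est - 25), 3 * se)
})

test_that("a single congruence condition is not estimable", {
  res <- make_results(rep(c("P01", "P02"), each = 30), "congruent",
                      rt_ms = runif(60, 200, 400), correct = TRUE)
  expect_error(fit_rt_lmm(res), class = "ocusimon_input_error")
  expect_error(fit_rt_lmm(res[0, ]), class = "ocusimon_input_error")
})

test_that("the accuracy model is null when both conditions are at 50%", {
  res <- bernoulli_results(10, 60, 0.5, 0.5, seed = 41)
  fit <- fit_acc_glmm(res)
  i <- fit$fixed_effects$name == "congruenceincongruent"
  expect_lt(abs(fit$fixed_effects$estimate[i]), 2 * fit$fixed_effects$se[i])
})

test_that("a true log-odds difference of 1 is recovered within 3 SE", {
  p_con <- plogis(2.2); p_inc <- plogis(1.2)
  res <- bernoulli_results(20, 120, p_con, p_inc, seed = 42, re_sd = 0.4)
  fit <- fit_acc_glmm(res)
  i <- fit$fixed_effects$name == "congruenceincongruent"
  est <- fit$fixed_effects$estimate[i]; se <- fit$fixed_effects$se[i]
  expect_lt(abs(est - (-1)), 3 * se)
})

test_that("perfect accuracy raises a separation error", {
  res <- make_results(rep(c("P01", "P02"), each = 40),
                      rep(c("congruent", "incongruent"), 40),
                      rt_ms = runif(80, 200, 800), correct = TRUE)
  expect_error(fit_acc_glmm(res), class = "ocusimon_separation_error")
})

test_that("the CAF model reports all three omnibus tests and flags empty cells", {
  res <- bernoulli_results(8, 42, 0.95, 0.8, seed = 43, re_sd = 0.3)
  fit <- fit_caf_glmm(res, n_bins = 3)
  expect_setequal(names(fit$tests_all), c("congruence", "bin",
                                          "congruence:bin"))
  expect_true(all(sapply(fit$tests_all, function(t) t$p_value >= 0 &&
                           t$p_value <= 1)))
  # too few trials for 7 bins in a condition -> an empty cell is reported
  small <- make_results(rep(c("P01", "P02"), each = 8),
                        rep(c("congruent", "incongruent"), 8),
                        rt_ms = runif(16, 200, 800),
                        correct = rep(c(TRUE, FALSE), 8))
  expect_error(suppressWarnings(fit_caf_glmm(small, n_bins = 7)), "empty")
})

test_that("the omnibus interaction statistic ignores how bins are labelled", {
  res <- bernoulli_results(8, 42, 0.95, 0.8, seed = 44, re_sd = 0.3)
  res <- ocusimon:::attach_bins(
    dplyr::filter(res, !excluded, responded), 3)
  fit1 <- lme4::glmer(correct ~ congruence * factor(bin) +
                        (1 | participant_id),
                      data = res, family = binomial)
  perm <- c(2, 3, 1)
  res$bin_perm <- perm[res$bin]
  fit2 <- lme4::glmer(correct ~ congruence * factor(bin_perm) +
                        (1 | participant_id),
                      data = res, family = binomial)
  c1 <- car::Anova(fit1)["congruence:factor(bin)", "Chisq"]
  c2 <- car::Anova(fit2)["congruence:factor(bin_perm)", "Chisq"]
  expect_equal(c1, c2, tolerance = 1e-3)
})

test_that("post hoc congruence-by-bin contrasts are adjusted upward", {
  res <- bernoulli_results(10, 70, 0.95, 0.75, seed = 45, re_sd = 0.3)
  fit <- fit_caf_glmm(res, n_bins = 7)
  ph <- posthoc_congruence_by_bin(fit)
  expect_equal(nrow(ph), 7)
  expect_true(all(ph$p_adjusted >= ph$p_value - 1e-12))
  expect_true(all(ph$p_adjusted <= 1))
  # repeated calls agree despite the randomized joint-normal quadrature
  ph2 <- posthoc_congruence_by_bin(fit)
  expect_equal(ph$p_adjusted, ph2$p_adjusted)
})

test_that("the delta model reproduces raw cell means under balanced data and needs 2 bins", {
  res <- random_results(6, 70, seed = 46)
  d <- compute_delta(res)
  fit <- fit_delta_lmm(d$per_participant)
  # saturated categorical fixed effect: fitted cell means = raw bin means
  co <- fit$fixed_effects$estimate
  fitted_means <- co[1] + c(0, co[2:7])
  raw_means <- tapply(d$per_participant$delta_ms, d$per_participant$bin,
                      mean)
  expect_equal(unname(fitted_means), as.vector(raw_means), tolerance = 1e-6)
  expect_equal(fit$test$df1, 6)
  expect_equal(fit$test$df2, nrow(d$per_participant) - 6 - 6)
  one_bin <- d$per_participant[d$per_participant$bin == 1, ]
  expect_error(fit_delta_lmm(one_bin), class = "ocusimon_input_error")
})

test_that("estimates are invariant to trial order and participant relabeling", {
  res <- quick_study(6, seed = 47, n_blocks = 1, trials_per_block = 60)
  fit <- fit_rt_lmm(res)
  set.seed(1); perm <- sample(nrow(res))
  fit_p <- fit_rt_lmm(res[perm, ])
  expect_equal(fit$fixed_effects$estimate, fit_p$fixed_effects$estimate,
               tolerance = 1e-6)
  relab <- res
  relab$participant_id <- paste0("Z", relab$participant_id)
  fit_r <- fit_rt_lmm(relab)
  expect_equal(fit$fixed_effects$estimate, fit_r$fixed_effects$estimate,
               tolerance = 1e-6)
})
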