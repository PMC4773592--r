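# shared fixtures and independent brute-force oracles

# minimal trial-result table built directly (bypasses the simulator) for
# distributional and inference tests
make_results <- function(participant_id, congruence, rt_ms, correct,
                         excluded = FALSE, responded = TRUE) {
  n <- max(length(participant_id), length(congruence), length(rt_ms),
           length(correct))
  tibble::tibble(
    participant_id = rep_len(participant_id, n),
    block = 1L, trial = seq_len(n),
    congruence = rep_len(congruence, n),
    rt_ms = rep_len(rt_ms, n),
    response_side = "right",
    correct = rep_len(correct, n),
    responded = rep_len(responded, n),
    exclusion_reason = ifelse(rep_len(excluded, n), "outlier_3sd", "none"),
    excluded = rep_len(excluded, n))
}

# random result table: n trials per participant x condition
random_results <- function(n_pp, n_per_cell, seed) {
  set.seed(seed)
  grid <- expand.grid(participant_id = sprintf("P%02d", seq_len(n_pp)),
                      congruence = c("congruent", "incongruent"),
                      i = seq_len(n_per_cell), stringsAsFactors = FALSE)
  make_results(grid$participant_id, grid$congruence,
               rt_ms = round(runif(nrow(grid), 150, 900), 3),
               correct = runif(nrow(grid)) < 0.85)
}

# brute-force septile assignment: full sort + slice
oracle_bins <- function(rts, n_bins = 7) {
  n <- length(rts)
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[1:r] <- sizes[1:r] + 1
  lab <- rep(seq_len(n_bins), sizes)
  ord <- sort.list(rts, method = "radix")   # stable
  out <- integer(n)
  for (k in seq_len(n)) out[ord[k]] <- lab[k]
  out
}

# brute-force CAF aggregate via plain loops
oracle_caf <- function(results, n_bins = 7) {
  d <- results[!results$excluded & results$responded, ]
  rows <- list()
  for (pp in unique(d$participant_id)) for (cg in unique(d$congruence)) {
    s <- d[d$participant_id == pp & d$congruence == cg, ]
    if (!nrow(s)) next
    b <- oracle_bins(s$rt_ms, n_bins)
    for (k in sort(unique(b)))
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = pp, congruence = cg, bin = k,
        mean_rt_ms = mean(s$rt_ms[b == k]),
        accuracy = mean(s$correct[b == k]),
        n_trials = sum(b == k))
  }
  per <- do.call(rbind, rows)
  agg <- aggregate(cbind(mean_rt_ms, accuracy) ~ congruence + bin, per, mean)
  list(per_participant = per[order(per$participant_id, per$congruence,
                                   per$bin), ],
       aggregate = agg[order(agg$congruence, agg$bin), ])
}

# brute-force delta aggregate
oracle_delta <- function(results, n_bins = 7) {
  d <- results[!results$excluded & results$responded & results$correct, ]
  rows <- list()
  for (pp in unique(d$participant_id)) {
    means <- list()
    for (cg in c("congruent", "incongruent")) {
      s <- d[d$participant_id == pp & d$congruence == cg, ]
      b <- oracle_bins(s$rt_ms, n_bins)
      means[[cg]] <- sapply(seq_len(n_bins), function(k)
        if (any(b == k)) mean(s$rt_ms[b == k]) else NA_real_)
    }
    if (any(is.na(means$congruent)) || any(is.na(means$incongruent))) next
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = pp, bin = seq_len(n_bins),
      delta_ms = means$incongruent - means$congruent)
  }
  per <- do.call(rbind, rows)
  aggregate(delta_ms ~ bin, per, mean)
}

# brute-force per-congruence summary (participant means first)
oracle_congruence_summary <- function(results) {
  d <- results[!results$excluded & results$responded, ]
  rows <- list()
  for (pp in unique(d$participant_id)) for (cg in unique(d$congruence)) {
    s <- d[d$participant_id == pp & d$congruence == cg, ]
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = pp, congruence = cg,
      rt = mean(s$rt_ms[s$correct]), acc = mean(s$correct))
  }
  per <- do.call(rbind, rows)
  out <- aggregate(cbind(rt, acc) ~ congruence, per, mean)
  out[order(out$congruence), ]
}

# quick decision-level session: outcomes only, exclusions applied
quick_study <- function(n_pp, seed, params = sim_params(),
                        n_blocks = 5, trials_per_block = 60) {
  s <- simulate_session(n_pp, params, n_blocks, trials_per_block,
                        seed = seed, render = FALSE)
  gt <- s$ground_truth
  trials <- tibble::tibble(
    participant_id = gt$participant_id, block = gt$block, trial = gt$trial,
    congruence = gt$congruence, rt_ms = gt$rt_ms,
    response_side = gt$response_side, correct = gt$correct,
    responded = gt$responded,
    exclusion_reason = ifelse(gt$responded, "none", "no_response"),
    excluded = !gt$responded)
  apply_exclusions(trials)$results
}

# binary accuracy data from an explicit logistic mixed model: random
# participant intercepts (sd re_sd) and a fixed congruence shift in log-odds
bernoulli_glmm_data <- function(n_pp, n_per_cell, eta0, eta_shift, re_sd,
                                seed) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_pp), function(i) {
    re <- rnorm(1, 0, re_sd)
    p_con <- stats::plogis(eta0 + re)
    p_inc <- stats::plogis(eta0 + eta_shift + re)
    make_results(sprintf("P%02d", i),
                 rep(c("congruent", "incongruent"), each = n_per_cell),
                 rt_ms = runif(2 * n_per_cell, 200, 800),
                 correct = c(runif(n_per_cell) < p_con,
                             runif(n_per_cell) < p_inc))
  }))
}
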