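#' @importFrom lme4 lmer glmer glmerControl lmerControl isSingular fixef
#'   VarCorr ngrps
NULL

model_fit <- function(formula, fit, test, n_obs, singular = FALSE) {
  fe <- summary(fit)$coefficients
  structure(list(
    formula = formula,
    fixed_effects = tibble(name = rownames(fe),
                           estimate = fe[, "Estimate"],
                           se = fe[, "Std. Error"]),
    random_intercept_sd =
      sqrt(as.numeric(VarCorr(fit)$participant_id[1, 1])),
    test = test,
    n_obs = n_obs,
    singular = singular,
    model = fit), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>", x$formula, "\n")
  cat(sprintf("  n_obs %d, random intercept SD %.3f%s\n", x$n_obs,
              x$random_intercept_sd,
              if (x$singular) " (singular fit)" else ""))
  print(as.data.frame(x$fixed_effects), row.names = FALSE)
  t <- x$test
  if (!is.null(t$df2))
    cat(sprintf("  %s(%g, %g) = %.3f, p = %.3g\n", t$statistic, t$df1, t$df2,
                t$value, t$p_value))
  else cat(sprintf("  %s = %.3f, p = %.3g\n", t$statistic, t$value,
                   t$p_value))
  invisible(x)
}

# inner-group residual denominator df: N - n_participants - (p - 1)
resid_ddf <- function(n_obs, n_groups, n_coef) n_obs - n_groups - (n_coef - 1)

check_inference_input <- function(d) {
  if (length(unique(d$participant_id)) < 2)
    abort_ocusimon("need at least 2 participants", "ocusimon_input_error")
  if (length(unique(d$congruence)) < 2)
    abort_ocusimon("both congruence conditions are required (congruence not estimable)",
                   "ocusimon_input_error")
}

#' Linear mixed model for saccade latency
#'
#' Fits `rt_ms ~ congruence + (1 | participant_id)` by REML on the correct,
#' included trials: a fixed congruence effect (the ms cost of incongruence)
#' and a participant random intercept.  The congruence test is an F with one
#' numerator df and the inner-group residual denominator df
#' (`N - n_participants - 1`).  A fit with zero between-participant variance
#' proceeds with `singular = TRUE`.
#'
#' @param results Trial results with exclusions applied.
#' @return A `model_fit` list: `fixed_effects` (name, estimate, se),
#'   `random_intercept_sd`, `test` (F statistic, dfs, p), `n_obs`,
#'   `singular`, and the underlying `lmerMod` as `model`.
#' @export
fit_rt_lmm <- function(results) {
  d <- filter(results, !.data$excluded, .data$responded, .data$correct)
  check_inference_input(d)
  d$congruence <- factor(d$congruence, c("congruent", "incongruent"))
  fit <- suppressMessages(lmer(rt_ms ~ congruence + (1 | participant_id),
                               data = d, REML = TRUE,
                               control = lmerControl(calc.derivs = FALSE)))
  Fv <- anova(fit)["congruence", "F value"]
  ddf <- resid_ddf(nrow(d), length(unique(d$participant_id)), 2)
  test <- list(statistic = "F", value = Fv, df1 = 1, df2 = ddf,
               p_value = pf(Fv, 1, ddf, lower.tail = FALSE))
  model_fit("rt_ms ~ congruence + (1 | participant_id)", fit, test, nrow(d),
            isSingular(fit))
}

#' Logistic mixed model for response accuracy
#'
#' Accuracy is binary, so the congruence comparison uses a logistic
#' (logit-link) mixed model, `correct ~ congruence + (1 | participant_id)`,
#' fitted by maximum likelihood with the Laplace approximation.  Error and
#' correct trials of both conditions must be present; complete separation
#' (a condition with all trials correct or all wrong) raises an error.  The
#' congruence effect is reported on the log-odds scale with its Wald z test.
#'
#' @param results Trial results with exclusions applied (errors retained).
#' @return A `model_fit`; `test` holds the Wald z and p for congruence.
#' @export
fit_acc_glmm <- function(results) {
  d <- filter(results, !.data$excluded, .data$responded)
  check_inference_input(d)
  acc <- tapply(d$correct, d$congruence, mean)
  if (any(acc %in% c(0, 1)))
    abort_ocusimon(paste0("complete separation: accuracy is 0 or 1 in condition(s) ",
                          paste(names(acc)[acc %in% c(0, 1)], collapse = ", ")),
                   "ocusimon_separation_error")
  d$congruence <- factor(d$congruence, c("congruent", "incongruent"))
  fit <- glmer(correct ~ congruence + (1 | participant_id), data = d,
               family = stats::binomial,
               control = glmerControl(calc.derivs = FALSE))
  co <- summary(fit)$coefficients["congruenceincongruent", ]
  test <- list(statistic = "z", value = unname(co["z value"]), df1 = NA,
               df2 = NULL, p_value = unname(co["Pr(>|z|)"]))
  model_fit("correct ~ congruence + (1 | participant_id)", fit, test,
            nrow(d), isSingular(fit))
}

# attach per-participant x condition septile bins to trial results
attach_bins <- function(d, n_bins) {
  d %>%
    group_by(.data$participant_id, .data$congruence) %>%
    mutate(bin = bin_septiles(.data$rt_ms, n_bins)) %>%
    ungroup()
}

#' Congruence x bin logistic mixed model for the CAF analysis
#'
#' Adds a categorical latency-septile factor to the accuracy model:
#' `correct ~ congruence * bin + (1 | participant_id)` with logit link,
#' giving a 2 x `n_bins` analysis.  Bins are assigned per participant and
#' condition with [bin_septiles()].  Omnibus Wald chi-square tests for the
#' congruence and bin main effects and their interaction are computed from
#' the fitted coefficients; empty congruence x bin cells raise an error
#' naming the cells.
#'
#' @param results Trial results with exclusions applied (errors retained).
#' @param n_bins Number of latency bins (default 7).
#' @return A `model_fit`; `test` is the interaction chi-square, and
#'   `tests_all` lists the chi-square for each of the three terms.
#' @export
fit_caf_glmm <- function(results, n_bins = 7) {
  d <- filter(results, !.data$excluded, .data$responded)
  check_inference_input(d)
  d <- attach_bins(d, n_bins)
  cells <- table(d$congruence, factor(d$bin, levels = seq_len(n_bins)))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    abort_ocusimon(paste0("empty congruence x bin cell(s): ",
                          paste(sprintf("(%s, bin %s)",
                                        rownames(cells)[empty[, 1]],
                                        colnames(cells)[empty[, 2]]),
                                collapse = ", ")),
                   "ocusimon_input_error")
  }
  d$congruence <- factor(d$congruence, c("congruent", "incongruent"))
  d$bin <- factor(d$bin)
  fit <- glmer(correct ~ congruence * bin + (1 | participant_id), data = d,
               family = stats::binomial,
               control = glmerControl(calc.derivs = FALSE))
  aov <- car::Anova(fit, type = "II")
  tests_all <- lapply(rownames(aov), function(term)
    list(term = term, statistic = "chisq",
         value = aov[term, "Chisq"], df1 = aov[term, "Df"], df2 = NULL,
         p_value = aov[term, "Pr(>Chisq)"]))
  names(tests_all) <- rownames(aov)
  mf <- model_fit("correct ~ congruence * bin + (1 | participant_id)", fit,
                  tests_all[["congruence:bin"]], nrow(d), isSingular(fit))
  mf$tests_all <- tests_all
  mf$n_bins <- n_bins
  mf
}

#' Post hoc congruence contrasts within each latency bin
#'
#' From a fitted CAF model, tests the congruence effect (incongruent minus
#' congruent, log-odds scale) separately within each bin: one z test per
#' bin, adjusted for multiplicity over the family by the single-step
#' max-|z| method (the joint-normal adjustment multcomp implements).  If the
#' joint computation fails, Holm-Bonferroni is used as the deterministic
#' fallback; the method used is recorded.  The joint-normal quantile is
#' evaluated under a fixed internal seed so repeated calls agree.
#'
#' @param fit A `model_fit` from [fit_caf_glmm()].
#' @return A tibble of contrasts: `label`, `estimate`, `se`, `z_value`,
#'   `p_value`, `p_adjusted`, `method`.
#' @export
posthoc_congruence_by_bin <- function(fit) {
  stopifnot(inherits(fit, "model_fit"), !is.null(fit$n_bins))
  model <- fit$model
  cf <- names(fixef(model))
  n_bins <- fit$n_bins
  K <- matrix(0, n_bins, length(cf), dimnames = list(
    sprintf("congruence | bin %d", seq_len(n_bins)), cf))
  K[, "congruenceincongruent"] <- 1
  for (k in 2:n_bins) {
    term <- sprintf("congruenceincongruent:bin%d", k)
    K[k, term] <- 1
  }
  est <- drop(K %*% fixef(model))
  V <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(K %*% V %*% t(K)))
  z <- est / se
  p_raw <- 2 * pnorm(-abs(z))

  adj <- tryCatch({
    g <- multcomp::glht(model, linfct = K)
    s <- with_local_seed(20200301,
                         summary(g, test = multcomp::adjusted("single-step")))
    list(p = as.numeric(s$test$pvalues), method = "single-step max-|z|")
  }, error = function(e)
    list(p = p.adjust(p_raw, "holm"), method = "holm"))
  # adjustment must never fall below the raw p (guards numerical slack in
  # the multivariate-normal integration)
  p_adj <- pmin(1, pmax(adj$p, p_raw))

  tibble(label = rownames(K), estimate = est, se = se, z_value = z,
         p_value = p_raw, p_adjusted = p_adj, method = adj$method)
}

#' Linear mixed model for delta values across bins
#'
#' Fits `delta_ms ~ bin + (1 | participant_id)` (bin categorical) to the
#' per-participant delta rows, testing whether the congruence effect changes
#' across the latency distribution.  The omnibus bin test is an F with
#' `n_bins - 1` numerator df and inner-group residual denominator df.
#'
#' @param delta_rows `per_participant` tibble from [compute_delta()].
#' @return A `model_fit`.
#' @export
fit_delta_lmm <- function(delta_rows) {
  d <- delta_rows
  if (length(unique(d$bin)) < 2)
    abort_ocusimon("need at least 2 bins", "ocusimon_input_error")
  d$bin <- factor(d$bin)
  fit <- suppressMessages(lmer(delta_ms ~ bin + (1 | participant_id),
                               data = d, REML = TRUE,
                               control = lmerControl(calc.derivs = FALSE)))
  Fv <- anova(fit)["bin", "F value"]
  df1 <- length(levels(d$bin)) - 1
  ddf <- resid_ddf(nrow(d), length(unique(d$participant_id)), df1 + 1)
  test <- list(statistic = "F", value = Fv, df1 = df1, df2 = ddf,
               p_value = pf(Fv, df1, ddf, lower.tail = FALSE))
  model_fit("delta_ms ~ bin + (1 | participant_id)", fit, test, nrow(d),
            isSingular(fit))
}
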