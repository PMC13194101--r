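# Inferential stage: Mann-Whitney comparisons on participant means, per-stage
# mixed-effects models on trial-level data, and Kaplan-Meier analysis of
# censored latencies.

#' Mann-Whitney comparison of participant-level means
#'
#' Two-sided Mann-Whitney U test of HC vs aMCI participant-level means for
#' one variable at one level (global or a stage). Missing values are dropped.
#' The p-value uses exact enumeration for small tie-free samples and the
#' tie-corrected normal approximation otherwise (stats::wilcox.test
#' behaviour); the reported z is the tie-corrected normal approximation.
#'
#' @param summaries participant summary data.frame with a `group` column
#' @param variable one of path_length, latency, path_distance_ratio,
#'   quadrant_crossings, time_in_target_quadrant, target_total
#' @param level "global", "s1", "s2" or "s3"
#' @return one-row data.frame: variable, level, U, z, p_value, group
#'   means/SEs and ns
#' @export
mann_whitney_by_group <- function(summaries, variable, level = "global") {
  col <- paste0(variable, "_", level)
  if (!col %in% names(summaries)) stop("no such summary column: ", col)
  x <- summaries[[col]][summaries$group == "aMCI"]
  y <- summaries[[col]][summaries$group == "HC"]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty group for ", col)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                            correct = FALSE))
  n1 <- length(x)
  n2 <- length(y)
  # tie-corrected normal approximation for the reported z
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (u - n1 * n2 / 2) / sqrt(sig2) else 0
  data.frame(variable = variable, level = level,
             U = unname(wt$statistic), z = z, p_value = wt$p.value,
             mean_amci = mean(x), se_amci = stats::sd(x) / sqrt(n1),
             mean_hc = mean(y), se_hc = stats::sd(y) / sqrt(n2),
             n_amci = n1, n_hc = n2)
}

#' Mann-Whitney tests for all variables and levels
#'
#' @param summaries participant summary data.frame with a `group` column
#' @param variables variables to test
#' @param levels_ levels to test
#' @return data.frame, one row per variable x level
#' @export
mann_whitney_table <- function(summaries,
                               variables = c("path_length", "latency",
                                             "path_distance_ratio",
                                             "quadrant_crossings",
                                             "time_in_target_quadrant",
                                             "target_total"),
                               levels_ = c("global", "s1", "s2", "s3")) {
  rows <- list()
  for (v in variables) {
    for (lv in levels_) {
      rows[[length(rows) + 1L]] <- mann_whitney_by_group(summaries, v, lv)
    }
  }
  do.call(rbind, rows)
}

#' log(x + 1) transform
#'
#' Natural-log transform applied to skewed navigation outcomes before linear
#' mixed modelling.
#'
#' @param values non-negative numeric vector
#' @return `log(values + 1)`, elementwise
#' @export
transform_log1 <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be >= 0")
  log1p(values)
}

#' Per-stage mixed-effects model
#'
#' Fits the trial-level model for one outcome within one stage: fixed effects
#' group (HC reference), trial (categorical, reference trial 1) and their
#' interaction, with a random intercept per participant. Families: `linear`
#' (REML on log(x+1)-transformed outcome), `poisson` and `logistic` (Laplace
#' ML). Latency is excluded from mixed modelling because of censoring at the
#' trial cap. A logistic fit is skipped with a flag when quasi-separation is
#' detected (a group success rate within 0.025 of 0 or 1).
#'
#' @param metrics per-trial metrics table
#' @param cohort cohort data.frame (for the group labels)
#' @param outcome metric name; for `linear` the log(x+1) transform is applied
#'   internally
#' @param stage stage number
#' @param family "linear", "poisson" or "logistic"
#' @return object of class `vm_mixed_result`: list with coefficient tables
#'   (`group`, `trial`, `interaction`), `ranef_var`, `converged`, `skipped`,
#'   `messages`
#' @export
fit_stage_mixed_model <- function(metrics, cohort, outcome, stage,
                                  family = c("linear", "poisson", "logistic")) {
  family <- match.arg(family)
  if (outcome == "latency")
    stop("latency is excluded from mixed modelling (censored at the cap); use km_logrank()")
  d <- metrics[metrics$stage == stage, ]
  if (!nrow(d)) stop("no data for stage ", stage)
  d <- merge(d, cohort[, c("participant_id", "group")], by = "participant_id")
  d$group <- factor(d$group, levels = c("HC", "aMCI"))
  d$trial_f <- factor(d$trial)
  y <- d[[outcome]]
  res <- list(outcome = outcome, stage = stage, family = family,
              skipped = FALSE, converged = TRUE, messages = character(0))
  class(res) <- "vm_mixed_result"

  if (family == "logistic") {
    rates <- tapply(as.numeric(y), d$group, mean, na.rm = TRUE)
    if (any(rates >= 0.975) || any(rates <= 0.025)) {
      res$skipped <- TRUE
      res$messages <- sprintf(
        "quasi-separation: group success rates %s; model skipped",
        paste(sprintf("%s=%.3f", names(rates), rates), collapse = ", "))
      return(res)
    }
  }
  d$y <- switch(family,
                linear = transform_log1(y),
                poisson = as.integer(round(y)),
                logistic = as.integer(y))
  keep <- !is.na(d$y)
  d <- d[keep, ]

  fml <- y ~ group * trial_f + (1 | participant_id)
  msgs <- character(0)
  fit <- tryCatch(
    withCallingHandlers(
      switch(family,
             linear = lmerTest::lmer(fml, data = d, REML = TRUE),
             poisson = lme4::glmer(fml, data = d, family = stats::poisson()),
             logistic = lme4::glmer(fml, data = d, family = stats::binomial())),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res$converged <- FALSE
    res$skipped <- TRUE
    res$messages <- c(msgs, paste("fit failed:", conditionMessage(fit)))
    return(res)
  }
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages)) msgs <- c(msgs, conv$messages)
  res$converged <- !any(grepl("failed to converge", msgs))
  res$messages <- msgs

  ct <- withCallingHandlers(
    as.data.frame(stats::coef(summary(fit))),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  res$messages <- msgs
  pcol <- grep("^Pr", names(ct), value = TRUE)[1]
  tab <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                    p_value = if (!is.na(pcol)) ct[[pcol]] else NA_real_,
                    row.names = NULL)
  res$group <- tab[tab$term == "groupaMCI", ]
  res$trial <- tab[grepl("^trial_f", tab$term) & !grepl(":", tab$term), ]
  res$interaction <- tab[grepl("^groupaMCI:trial_f", tab$term), ]
  vc <- as.data.frame(lme4::VarCorr(fit))
  res$ranef_var <- vc$vcov[vc$grp == "participant_id"][1]
  res$fit <- fit
  res
}

#' Kaplan-Meier curves and log-rank test for latency
#'
#' Pools all trials of one stage (treated as independent observations, as in
#' the reference analysis) and estimates the per-group cumulative success
#' probability 1 - S(t), where the event is platform arrival and unsuccessful
#' trials are censored at the 60 s cap. The two-sample log-rank test compares
#' the groups; if there are no events the test is flagged undefined.
#'
#' @param metrics per-trial metrics table
#' @param cohort cohort data.frame (for the group labels)
#' @param stage stage number
#' @return object of class `vm_survival_result`: list with `curves`
#'   (stage, group, time, success_prob), `median_latency` per group (NA when
#'   not reached), `chisq`, `p_value`, `test_defined`,
#'   `pooled_trials_note`
#' @export
km_logrank <- function(metrics, cohort, stage) {
  d <- metrics[metrics$stage == stage, ]
  if (!nrow(d)) stop("no data for stage ", stage)
  d <- merge(d, cohort[, c("participant_id", "group")], by = "participant_id")
  if (any(d$latency <= 0 | d$latency > 60 + 1e-9))
    stop("latencies must lie in (0, 60]")
  if (any(d$latency_censored == d$target_reached))
    stop("censor flags inconsistent with target_reached")
  d$group <- factor(d$group, levels = c("HC", "aMCI"))
  sf <- survival::survfit(survival::Surv(latency, target_reached) ~ group,
                          data = d)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(stage = stage,
                       group = sub("^group=", "", strata),
                       time = sf$time,
                       success_prob = 1 - sf$surv)
  med <- summary(sf)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(sf)$table))
  n_events <- sum(d$target_reached)
  if (n_events == 0L) {
    return(structure(list(stage = stage, curves = curves,
                          median_latency = med, chisq = NA_real_,
                          p_value = NA_real_, test_defined = FALSE,
                          pooled_trials_note = pooled_note()),
                     class = "vm_survival_result"))
  }
  sd_ <- survival::survdiff(survival::Surv(latency, target_reached) ~ group,
                            data = d)
  structure(list(stage = stage, curves = curves, median_latency = med,
                 chisq = sd_$chisq,
                 p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
                 test_defined = TRUE,
                 pooled_trials_note = pooled_note()),
            class = "vm_survival_result")
}

pooled_note <- function() {
  paste("trials pooled within stage and treated as independent observations;",
        "no within-participant clustering correction applied")
}
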