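# End-to-end orchestration: simulate -> metrics -> group stats -> composite
# -> classification, with optional CSV reports.

#' Run the full analysis pipeline
#'
#' Simulates a cohort with the given parameters, extracts per-trial metrics
#' and participant summaries, injects the single missing path-distance-ratio
#' value, runs the Mann-Whitney comparisons, optional mixed models, the
#' Kaplan-Meier latency analysis, the Route Efficiency composite with its
#' association and effect-size analyses, and the nested-CV classification.
#' Every stochastic stage is seeded from `seed` through [derive_seed()], so
#' reruns with the same configuration are bit-identical.
#'
#' @param seed master seed
#' @param params a `simulator_params`
#' @param config an `arena_config`
#' @param n_hc,n_amci cohort sizes
#' @param k,reps nested-CV folds and repetitions
#' @param n_boot bootstrap iterations for the AUC CI (0 = skip)
#' @param boot_reps CV repetitions per bootstrap sample
#' @param do_mixed fit the per-stage mixed models (slower)
#' @param missing_value inject the single missing ratio value
#' @param outdir if non-NULL, write report CSVs and a manifest there
#' @param trajectories optionally reuse a previously simulated/loaded
#'   trajectory table (with matching `cohort`); skips simulation
#' @param cohort cohort records when `trajectories` is supplied
#' @param verbose print stage progress
#' @return list with cohort, trajectories, metrics, summaries, group_tests,
#'   survival, mixed (optional), pca, scores, associations, effect, cv,
#'   single_aucs, ci (optional), seed
#' @export
run_pipeline <- function(seed = 1,
                         params = default_simulator_params(),
                         config = arena_config(),
                         n_hc = 20, n_amci = 18,
                         k = 5, reps = 10,
                         n_boot = 0, boot_reps = 2,
                         do_mixed = FALSE,
                         missing_value = TRUE,
                         outdir = NULL,
                         trajectories = NULL, cohort = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf("[vmnav %s] ", format(Sys.time(), "%H:%M:%S")), ...)
  if (is.null(trajectories)) {
    say("simulating cohort (seed ", seed, ")")
    sim <- simulate_cohort(params, config, n_hc, n_amci, seed)
    trajectories <- sim$trajectories
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    if (is.null(cohort)) stop("cohort must accompany precomputed trajectories")
    truth <- NULL
  }
  say("extracting metrics")
  metrics <- compute_metrics(trajectories, config)
  summaries <- summarize_participants(metrics, cohort, config)
  summaries <- inject_missingness(summaries, enabled = missing_value,
                                  seed = derive_seed(seed, 3L))

  say("group comparisons")
  group_tests <- mann_whitney_table(summaries)
  surv <- lapply(seq_len(config$n_stages), function(s)
    km_logrank(metrics, cohort, s))

  mixed <- NULL
  if (do_mixed) {
    say("mixed models")
    plan <- expand.grid(
      outcome = c("path_length", "path_distance_ratio",
                  "time_in_target_quadrant", "quadrant_crossings",
                  "target_reached"),
      stage = seq_len(config$n_stages), stringsAsFactors = FALSE)
    plan$family <- ifelse(plan$outcome == "quadrant_crossings", "poisson",
                          ifelse(plan$outcome == "target_reached",
                                 "logistic", "linear"))
    mixed <- lapply(seq_len(nrow(plan)), function(i)
      fit_stage_mixed_model(metrics, cohort, plan$outcome[i],
                            plan$stage[i], plan$family[i]))
  }

  say("Route Efficiency composite")
  pca <- fit_pca(summaries)
  scores <- orient_and_score(pca, summaries)
  assoc <- associate(scores, cohort)
  eff <- effect_size_and_power(scores)

  say("nested-CV classification")
  cv <- nested_cv_auc(summaries, k = k, reps = reps,
                      seed = derive_seed(seed, 4L))
  sva <- single_variable_aucs(summaries)
  ci <- NULL
  if (n_boot > 0) {
    say("bootstrap CI (", n_boot, " iterations)")
    ci <- bootstrap_auc_ci(summaries, k = k, reps = boot_reps,
                           n_boot = n_boot, seed = derive_seed(seed, 5L))
  }

  out <- list(cohort = cohort, trajectories = trajectories, truth = truth,
              metrics = metrics, summaries = summaries,
              group_tests = group_tests, survival = surv, mixed = mixed,
              pca = pca, scores = scores, associations = assoc,
              effect = eff, cv = cv, single_aucs = sva, ci = ci,
              seed = seed)
  if (!is.null(outdir)) write_reports(out, outdir, config)
  out
}

#' Write pipeline report tables
#'
#' Emits the cohort summary, the per-trial metrics, the participant
#' summaries, the group-comparison table, survival curves, the PCA report,
#' Route Efficiency scores, the CV report and a manifest recording the seed
#' and analysis flags.
#'
#' @param res result list from [run_pipeline()]
#' @param outdir output directory (created if needed)
#' @param config the `arena_config` used
#' @return `outdir`, invisibly
#' @export
write_reports <- function(res, outdir, config = arena_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(outdir, name),
                                           row.names = FALSE)
  w(res$cohort, "cohort.csv")
  w(res$metrics, "trial_metrics.csv")
  w(res$summaries, "participant_summaries.csv")
  w(group_summary(res$summaries), "group_summary.csv")
  w(res$group_tests, "mann_whitney.csv")
  w(do.call(rbind, lapply(res$survival, function(s) s$curves)),
    "survival_curves.csv")
  pca_df <- data.frame(variable = res$pca$variables,
                       loading_pc1 = res$pca$loadings[, 1])
  w(pca_df, "pca_loadings.csv")
  w(data.frame(component = seq_along(res$pca$eigenvalues),
               eigenvalue = res$pca$eigenvalues,
               var_share = res$pca$var_share), "pca_eigenvalues.csv")
  w(res$scores, "route_efficiency.csv")
  w(res$single_aucs, "single_variable_aucs.csv")
  cvdf <- data.frame(rep = rep(seq_len(nrow(res$cv$fold_aucs)),
                               ncol(res$cv$fold_aucs)),
                     fold = rep(seq_len(ncol(res$cv$fold_aucs)),
                                each = nrow(res$cv$fold_aucs)),
                     auc = as.numeric(res$cv$fold_aucs))
  w(cvdf, "cv_fold_aucs.csv")
  manifest <- c(
    sprintf("seed: %d", res$seed),
    sprintf("n_hc: %d", sum(res$cohort$group == "HC")),
    sprintf("n_amci: %d", sum(res$cohort$group == "aMCI")),
    sprintf("cv: k=%d reps=%d aggregate=%s", res$cv$k, res$cv$reps,
            res$cv$aggregate),
    sprintf("mean_auc: %.4f", res$cv$auc),
    sprintf("cohens_d: %.4f", res$effect$d),
    sprintf("pc1_var_share: %.4f", res$pca$var_share[1]),
    sprintf("n_complete: %d", res$pca$n_complete),
    "survival_note: trials pooled within stage, no clustering correction",
    sprintf("vmnav_version: %s",
            as.character(utils::packageVersion("vmnav"))))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
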