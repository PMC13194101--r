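#!/usr/bin/env Rscript
# Discrimination of aMCI vs HC: nested 5-fold cross-validation (10
# repetitions) with fold-internal standardization, PCA and logistic scoring,
# a bootstrap 95% CI for the mean AUC, and single-variable reference AUCs.
#
# Usage: Rscript analysis/05_classification.R [seed] [n_boot]

library(vmnav)
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(args[1])
if (is.na(seed)) seed <- 1L
n_boot <- as.integer(args[2])
if (is.na(n_boot)) n_boot <- 1000L

summ <- utils::read.csv("results/participant_summaries.csv")

cv <- nested_cv_auc(summ, k = 5, reps = 10, seed = derive_seed(seed, 4L))
cat(sprintf("nested-CV AUC (mean of %d fold AUCs): %.3f\n",
            length(cv$fold_aucs), cv$auc))
utils::write.csv(data.frame(rep = rep(seq_len(nrow(cv$fold_aucs)), 5),
                            fold = rep(1:5, each = nrow(cv$fold_aucs)),
                            auc = as.numeric(cv$fold_aucs)),
                 "results/cv_fold_aucs.csv", row.names = FALSE)

ci <- bootstrap_auc_ci(summ, k = 5, reps = 2, n_boot = n_boot,
                       seed = derive_seed(seed, 5L), method = "participant")
cat(sprintf("bootstrap 95%% CI (%s resampling, %d iterations): %.2f-%.2f\n",
            ci$method, n_boot, ci$low, ci$high))

sva <- single_variable_aucs(summ)
utils::write.csv(sva, "results/single_variable_aucs.csv", row.names = FALSE)
cat("\nsingle-variable AUCs:\n")
print(sva, row.names = FALSE, digits = 3)
cat(sprintf("range: %.2f-%.2f\n", min(sva$auc, na.rm = TRUE),
            max(sva$auc, na.rm = TRUE)))

writeLines(c(sprintf("seed: %d", seed),
             sprintf("cv_auc: %.4f", cv$auc),
             sprintf("ci: %.4f %.4f", ci$low, ci$high),
             "cv: k=5 reps=10 stratified fold-internal PCA",
             sprintf("bootstrap: participant resampling, %d iterations, 2 reps per sample",
                     n_boot)),
           "results/classification_manifest.txt")
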