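#!/usr/bin/env Rscript
# Construct the Route Efficiency composite (inverted PC1 of the five
# standardized global navigation metrics, complete cases) and run the
# association, adjustment and effect-size analyses against the cognitive
# scores.
#
# Usage: Rscript analysis/04_route_efficiency.R

library(vmnav)
cohort <- read_cohort("results/cohort.csv")
summ <- utils::read.csv("results/participant_summaries.csv")

pca <- fit_pca(summ)
cat(sprintf("complete cases: n = %d\n", pca$n_complete))
cat(sprintf("PC1: eigenvalue %.2f, %.1f%% of variance; only component above the Kaiser criterion: %s\n",
            pca$eigenvalues[1], 100 * pca$var_share[1], pca$kaiser_only_pc1))
utils::write.csv(data.frame(variable = pca$variables,
                            loading_pc1 = pca$loadings[, 1]),
                 "results/pca_loadings.csv", row.names = FALSE)
utils::write.csv(data.frame(component = seq_along(pca$eigenvalues),
                            eigenvalue = pca$eigenvalues,
                            var_share = pca$var_share),
                 "results/pca_eigenvalues.csv", row.names = FALSE)

scores <- orient_and_score(pca, summ)
utils::write.csv(scores, "results/route_efficiency.csv", row.names = FALSE)

eff <- effect_size_and_power(scores)
cat(sprintf("Route Efficiency: HC %.2f +- %.2f, aMCI %.2f +- %.2f\n",
            eff$mean_hc, eff$se_hc, eff$mean_amci, eff$se_amci))
cat(sprintf("Cohen's d = %.2f, post-hoc power = %.3f (%s)\n",
            eff$d, eff$power, eff$power_method))

mw <- mann_whitney_by_group(cbind(scores,
                                  route_efficiency_global = scores$route_efficiency),
                            "route_efficiency", "global")
cat(sprintf("group difference: U = %.0f, z = %.2f, p = %.2g\n",
            mw$U, mw$z, mw$p_value))

assoc <- associate(scores, cohort)
utils::write.csv(assoc$spearman, "results/spearman.csv", row.names = FALSE)
utils::write.csv(assoc$partial, "results/partial_correlations.csv",
                 row.names = FALSE)
cat("\nSpearman correlations with cognitive scores:\n")
print(assoc$spearman, row.names = FALSE, digits = 3)
cat("\npartial correlations controlling for group:\n")
print(assoc$partial, row.names = FALSE, digits = 3)
cat(sprintf("\nadjusted group effect (group + sex + age + education): beta = %.2f, p = %.3g\n",
            assoc$adjusted_group$beta, assoc$adjusted_group$p_value))
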