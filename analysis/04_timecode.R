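#!/usr/bin/env Rscript
## Population time decoding: PCA trajectory of hourly activity, the
## cohort-polling predictor across cohort sizes, feature-space views,
## and per-neuron contribution coefficients.

suppressMessages(library(scnca))
ds <- readRDS("results/cache/ds_main.rds")

pc <- pca_trajectory(ds)
write.csv(data.frame(hour = ds$hour_labels, pc1 = pc$points[, 1],
                     pc2 = pc$points[, 2]),
          "results/04_pca_trajectory.csv", row.names = FALSE)
cat("PC1+PC2 explain", round(100 * sum(pc$explained[1:2])), "% variance;",
    "circularity score", round(pc$circularity, 2), "\n")

curve <- accuracy_curve(ds, sizes = c(1, 100, 450), trials = 500,
                        seeds = 0:2, epochs = 25, patience = 8)
write.csv(curve$table, "results/04_accuracy_curve.csv", row.names = FALSE)
print(curve$summary)
cat("one-sided trend p (accuracy grows with cohort size):",
    signif(curve$trend_p, 3), "\n")

pools <- partition_neurons(ds, seed = 0)
pred <- train_time_predictor(ds, pools, 450, epochs = 25, patience = 8,
                             seed = 0)
fs <- embed_feature_space(pred, ds, pools$test, size = 450,
                          n_cohorts = 240, seed = 0)
fs1 <- embed_feature_space(pred, ds, pools$test, size = 1,
                           n_cohorts = 240, seed = 0)
cat("feature-space silhouette by hour: cohort 450 =",
    round(fs$silhouette, 2), "vs cohort 1 =", round(fs1$silhouette, 2), "\n")
write.csv(data.frame(hour = fs$hour, x = fs$coords[, 1],
                     y = fs$coords[, 2]),
          "results/04_feature_tsne.csv", row.names = FALSE)

# contribution coefficients on a neuron subsample (2-channel network)
sub <- ds
keep <- sort(sample(dim(ds$fluorescence)[1], 300))
sub$fluorescence <- ds$fluorescence[keep, , , drop = FALSE]
sub$truth$f0 <- ds$truth$f0[keep]
att <- contribution_coefficients(sub, M = 64, seed = 0)
cat("attribution completeness gaps <=",
    signif(max(att$completeness_gaps), 2),
    "; 24-h averaged contribution 5-95% spread:",
    round(att$spread, 3), "\n")
write.csv(data.frame(neuron = keep, time_avg = att$time_avg),
          "results/04_contribution.csv", row.names = FALSE)
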