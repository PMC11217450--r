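#!/usr/bin/env Rscript
## Dynamical states and circadian modes: train the graph-convolutional
## state classifier on labeled archetype manifolds, classify every
## neuron-session, and assign 12-h high/low activity modes.

suppressMessages(library(scnca))
ds <- readRDS("results/cache/ds_main.rds")

set.seed(2)
mans <- list(); labs <- integer(0)
for (cls in 1:6) for (r in 1:25) {
  mans[[length(mans) + 1]] <- embed_manifold(
    archetype_trace(cls, dim(ds$fluorescence)[3], ds$config$frame_rate))
  labs <- c(labs, cls)
}
aug <- augment_labeled_manifolds(mans, labs)
cat("training set:", length(aug$manifolds), "manifolds (25% original)\n")
clf <- train_state_classifier(aug$manifolds, aug$labels, epochs = 160,
                              seed = 0)

# classify a manageable subsample of the population
sub <- ds
keep <- sort(sample(dim(ds$fluorescence)[1], 400))
sub$fluorescence <- ds$fluorescence[keep, , , drop = FALSE]
sub$truth$f0 <- ds$truth$f0[keep]
cl <- classify_states(sub, clf)
write.csv(as.data.frame(cl$fractions), "results/03_state_fractions.csv",
          row.names = FALSE)
cat("population state fractions (hour 1):",
    round(cl$fractions[1, ], 3), "\n")
cat("dominant state overall:",
    names(which.max(colSums(cl$fractions))), "\n")

modes <- assign_modes(sub)
write.csv(modes, "results/03_modes.csv", row.names = FALSE)
cat("neurons with significant H/L split:",
    mean(modes$p_value < 0.05), "\n")
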