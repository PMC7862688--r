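#!/usr/bin/env Rscript
# Accuracy as a function of training-set size (4, 10, 20, 39 subjects),
# contrasting subject-wise training (only the drawn subjects' records) with
# record-wise training (test subjects' other records included in the
# training pool). Draws are group-balanced and nested across sizes within
# each repeat.

library(reachcv)

ds <- read_features("results/features.csv")
lc <- run_learning_curve(ds, sizes = c(4, 10, 20, 39), repeats = 10,
                         spec = model_spec_reduced(), seed = 42)
m <- aggregate(accuracy ~ size + scheme, lc, mean)
print(m)
utils::write.csv(lc, "results/learning_curve.csv", row.names = FALSE)
cat("Per-draw accuracies written to results/learning_curve.csv\n")
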