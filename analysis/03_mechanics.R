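#!/usr/bin/env Rscript
# Stage 3 — jaw lever mechanics.
#
# Computes masseter (MAM) and temporalis (MAT) mechanical advantage at the
# jaw tip and at the first lower molar from the moment-arm table, and joins
# MA with PC1 (jaw length) for the plot-ready coordinate files.

library(jawmorph)

arms <- utils::read.csv("results/data/arms.csv")
taxa <- read_taxon_table("results/data/taxa.csv")
ma <- ma_table(arms)

training <- taxa$taxon_id[taxa$role == "training"]
diet <- taxa$diet_class[match(ma$taxon_id, taxa$taxon_id)]
cat("training-class means of MAM/MAT at the jaw tip:\n")
print(aggregate(cbind(MAM_tip, MAT_tip) ~ diet,
                data = cbind(ma, diet = diet)[ma$taxon_id %in% training, ],
                FUN = function(x) round(mean(x), 3)))

scores <- rbind(utils::read.csv("results/training_scores.csv")[, c("taxon_id", "PC1")],
                utils::read.csv("results/fossil_scores.csv")[, c("taxon_id", "PC1")])
ma_pc1 <- merge(ma, scores, by = "taxon_id")
utils::write.csv(ma, "results/mechanical_advantage.csv", row.names = FALSE)
utils::write.csv(ma_pc1, "results/ma_vs_pc1.csv", row.names = FALSE)
cat(sprintf("wrote MA tables for %d taxa\n", nrow(ma)))
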