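#!/usr/bin/env Rscript
# Stage 2 — superimposition and morphospace.
#
# Reads the stage-1 files back, runs the joint generalized Procrustes
# analysis with sliding semi-landmarks over all 115 jaws, fits the PCA
# morphospace on the extant training subset, projects the fossils into it,
# and reports convex-hull occupancy of the fossil jaws on (PC1, PC2).
# PC1 is oriented so herbivores (short jaws) score negative.

library(jawmorph)

configs <- read_tps("results/data/jaws.tps",
                    curves = read_slider_descriptor("results/data/jaws.tps.sliders"))
taxa <- read_taxon_table("results/data/taxa.csv")

aligned <- gpa(configs, slide = TRUE)
cat(sprintf("GPA: %d iterations, %d sliding sweeps, final change %.2g\n",
            aligned$iterations_used, length(aligned$criterion_trace),
            aligned$final_change))

training <- taxa$taxon_id[taxa$role == "training"]
fossil <- taxa$taxon_id[taxa$role == "predict"]
msp <- fit_pca(aligned$coords[, , match(training, aligned$taxon_ids)],
               ids = training)
diet <- taxa$diet_class[match(training, taxa$taxon_id)]
if (mean(msp$scores[diet == "herbivore", "PC1"]) > 0) {
  msp$loadings[, 1] <- -msp$loadings[, 1]
  msp$scores[, 1] <- -msp$scores[, 1]
  cat("PC1 flipped so herbivores score negative\n")
}
fossil_scores <- project_shapes(
  msp, aligned$coords[, , match(fossil, aligned$taxon_ids)], ids = fossil)

cat(sprintf("PC1 %.1f%%, PC2 %.1f%%, PCs 1-7 cumulative %.1f%% of variance\n",
            100 * msp$variance_fractions[1], 100 * msp$variance_fractions[2],
            100 * sum(msp$variance_fractions[1:7])))

occ <- hull_occupancy(msp$scores[, 1:2], diet, fossil_scores[, 1:2])
cat("fossils inside extant diet hulls (PC1-PC2):\n")
print(colSums(occ, na.rm = TRUE))

utils::write.csv(data.frame(taxon_id = training, diet_class = diet,
                            msp$scores),
                 "results/training_scores.csv", row.names = FALSE)
utils::write.csv(data.frame(taxon_id = fossil, fossil_scores),
                 "results/fossil_scores.csv", row.names = FALSE)
utils::write.csv(data.frame(PC = seq_along(msp$eigenvalues),
                            eigenvalue = msp$eigenvalues,
                            variance_fraction = msp$variance_fractions),
                 "results/eigenvalues.csv", row.names = FALSE)
utils::write.csv(data.frame(taxon_id = fossil, occ),
                 "results/fossil_hull_occupancy.csv", row.names = FALSE)
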