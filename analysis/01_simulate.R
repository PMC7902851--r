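#!/usr/bin/env Rscript
# Stage 1 — build the study dataset.
#
# Generates the ground-truthed synthetic analogue of the study sample:
# 70 extant training taxa in four diet classes (8 herbivores, 16 carnivores,
# 13 insectivores, 33 omnivores) and 45 fossil taxa of hidden diet, each
# with a 64-landmark jaw configuration (6 fixed + 58 sliding), moment arms,
# and a shared phylogeny with fossil first-appearance dates. Everything is
# written to results/data/ in the interchange formats the pipeline reads
# (TPS + slider sidecar, CSV, Newick), so the later stages exercise the
# same readers a real dataset would.

library(jawmorph)

seed <- 1
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(seed = seed)
ds <- synth_dataset(spec)

write_tps(ds$configs, "results/data/jaws.tps")
utils::write.csv(ds$taxa, "results/data/taxa.csv", row.names = FALSE)
utils::write.csv(ds$arms, "results/data/arms.csv", row.names = FALSE)
ape::write.tree(ds$cladogram, "results/data/cladogram.nwk")
utils::write.csv(data.frame(taxon_id = names(ds$fads), fad = ds$fads),
                 "results/data/ages.csv", row.names = FALSE)
utils::write.csv(ds$ground_truth, "results/data/ground_truth_synthetic.csv",
                 row.names = FALSE)

cat(sprintf("simulated %d taxa (%d training / %d fossil), %d landmarks each\n",
            nrow(ds$taxa), sum(ds$taxa$role == "training"),
            sum(ds$taxa$role == "predict"), nrow(ds$configs[[1]]$coords)))
print(table(ds$taxa$diet_class[ds$taxa$role == "training"]))
cat(sprintf("tree: %d tips, root age %.1f Ma; fossil FADs %.0f-%.0f Ma\n",
            length(ds$fads), ds$tree$root_age,
            min(ds$fads[ds$fads > 0]), max(ds$fads)))
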