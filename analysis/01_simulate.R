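#!/usr/bin/env Rscript
# Step 1: generate the synthetic world.
#
# The generator emulates the data a stage-aware network-medicine repurposing
# analysis consumes: a scale-free PPI-like interactome, a planted 60-gene
# disease module, 30 stage-labelled seed draws (6 early / 5 late / 19
# unspecified, mimicking the 238/183/728 proportions of the real PBC seed
# list), and 50 drug/pathway annotation sets of which 5 are enriched in the
# module. Fixtures are written in the same dialects the real pipeline reads
# (BioGRID-style edge list TSV, seeds CSV, GMT, background TXT).

library(pbcnet)

cfg <- synthetic_config(rng_seed = 42L)
world <- generate_world(cfg)
manifest <- write_fixture_bundle(world, "results/fixtures")

cat("Synthetic world generated (seed 42):\n")
cat(sprintf("  interactome: %d genes, %d interactions\n",
            length(world$net$nodes), igraph::ecount(world$net$graph)))
cat(sprintf("  planted module: %d genes; cohesion %.2f\n",
            length(world$truth$module_genes), cfg$module_cohesion))
cat(sprintf("  seed draws: %d rows over %d unique genes\n",
            nrow(world$seed_rows), length(unique(world$seed_rows$symbol))))
cat(sprintf("  annotation sets: %d (%d planted: %s)\n",
            length(world$collection), length(world$planted_ids),
            paste(world$planted_ids, collapse = ", ")))
cat("Fixture bundle written to results/fixtures:\n")
print(manifest, row.names = FALSE)
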