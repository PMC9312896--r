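#!/usr/bin/env Rscript
# Step 2: seed curation.
#
# Normalizes gene symbols, collapses duplicate rows (stage labels union),
# scores database-sourced genes with the GDA component sum C+M+I+L (clamped
# to [0,1]) and manually curated genes with the stage-maximum rule, which
# guarantees curated genes at least the best database score of their stage
# and hence a major influence on the diffusion step.

library(pbcnet)

raw <- read_seed_csv("results/fixtures/seeds.csv")
seeds <- assign_curated_scores(dedup_seed_table(raw))
write_seed_csv(seeds, "results/seed_table.csv")

cat(sprintf("Curation: %d raw rows -> %d unique seed genes (%d skipped)\n",
            attr(seeds, "n_input"), nrow(seeds), attr(seeds, "n_skipped")))
for (st in c("early", "late", "unspecified")) {
  sub <- stage_seeds(seeds, st)
  cat(sprintf("  %-11s: %2d genes (%d disgenet, %d curated), relevance %.2f-%.2f\n",
              st, nrow(sub), sum(sub$source == "disgenet"),
              sum(sub$source == "curated"),
              min(sub$relevance), max(sub$relevance)))
}
cat("Canonical scored table written to results/seed_table.csv\n")
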