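# pbcnet

Stage-aware network-medicine drug repurposing for primary biliary
cholangitis (PBC), as an R analysis workflow.

PBC gene associations can be labelled by histological stage (early, late,
unspecified). Starting from a stage-labelled, relevance-scored seed gene
list, `pbcnet`:

1. **curates** the seeds — HGNC-style symbol normalization, dedup with
   stage-label union, gene–disease association (GDA) scoring
   `min(1, C + M + I + L)` for database genes and the stage-maximum rule for
   manually curated genes;
2. **diffuses** seed relevance over a protein–protein interaction network to
   the random-walk-with-restart fixed point
   `p = r·p0 + (1 − r)·W·p` (column-stochastic `W = A D⁻¹`, restart
   `r = 0.3`), producing a disease-proximity ranking;
3. **prioritizes** unlabelled genes with bagged positive-unlabelled (PU)
   learning on diffusion/topology features and selects the top-150
   "likely positive" (LP) genes per stage;
4. **tests** both the seed set and the LP set for drug and pathway
   over-representation: one-sided Fisher exact test (hypergeometric upper
   tail) on a protein-coding background, set-size filter 5–2000,
   Benjamini–Hochberg FDR < 0.05 per collection.

A synthetic-data generator (scale-free interactome, planted disease module,
stage-labelled scored seeds, GMT collections with planted signal) supplies
ground-truthed inputs for every step, since the real curated PBC inputs are
not redistributable.

Audience: computational biologists studying network-based disease-gene
prioritization and repurposing pipelines, and anyone needing a desk-scale,
fully testable reimplementation of this analysis pattern.

## Worked example

The numbered scripts under `analysis/` run the whole analysis on the
synthetic world and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # world + fixture bundle
Rscript analysis/02_curate_seeds.R      # canonical scored seed table
Rscript analysis/03_run_pipeline.R      # per-stage diffusion + PU + ORA
Rscript analysis/04_evaluate_recovery.R # comparison with ground truth
```

Step 3 prints, per stage, the chain's cardinalities and the enriched sets
(seed 42):

```
stage early      :  6 seeds (6 in network), 21 diffusion iters, 150 LP genes
  drugs     ORA: 1/25 sets significant from seeds, 3/25 from LP genes
  pathways  ORA: 2/25 sets significant from seeds, 3/25 from LP genes
...
Top enriched sets per stage/query/category:
       stage query_type category set_id  k K_set        p      fdr
       early         LP  pathway SET046 18    45 2.52e-05 5.69e-04
       early         LP  pathway SET032 12    24 4.55e-05 5.69e-04
       early         LP     drug SET011 11    20 3.05e-05 7.63e-04
...
```

Reading one row: of the 150 early-stage LP genes, 18 fall in the 45-member
set `SET046`; drawing 150 genes from the 1000-gene background would overlap
a 45-member set that much with probability `2.5e-05`, which survives BH
correction at FDR `5.7e-04`. The sets flagged significant (SET011, SET032,
SET037, SET039, SET046) are exactly the five sets the generator planted
with module genes. Step 4 quantifies recovery against the ground truth:

```
       stage heat_auroc lp_module_frac planted_detection
       early      0.848          0.213               0.6
        late      0.771          0.160               0.2
 unspecified      0.909          0.220               1.0
```

`heat_auroc` is how well diffusion ranks held-out planted-module genes;
stages with more seeds (unspecified: 19) detect the planted annotation sets
better than seed-poor stages (late: 5) — the same stage asymmetry any real
stage-labelled seed corpus imposes.

The same chain is available programmatically:

```r
library(pbcnet)
world <- generate_world(synthetic_config(rng_seed = 42))
write_fixture_bundle(world, "fixtures")
cfg <- run_config(
  edges = "fixtures/edges.tsv", seeds = "fixtures/seeds.csv",
  background = "fixtures/background.txt",
  collections = c(drugs = "fixtures/drugs.gmt",
                  pathways = "fixtures/pathways.gmt"),
  out_dir = "run", rng_seed = 42)
res <- run_pipeline(cfg)
head(res$report)
```

Real inputs drop in the same way: a BioGRID TAB export via
`read_edge_list(path, column_map = c("Official Symbol Interactor A",
"Official Symbol Interactor B"))`, seeds as CSV
(`symbol, stage, source, C, M, I, L`), collections as GMT, background as a
one-symbol-per-line list.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic world from the given seed, runs the full
per-stage pipeline (curation → diffusion → PU/LP → seed- and LP-ORA) from
the written fixture files, logs per-stage cardinalities, and writes the
JSON report to `--out`.

## Layout

- `R/` — package code: synthetic generators, seed curation, interactome and
  propagation operators, diffusion, PU prioritization, enrichment, pipeline.
- `analysis/` — the numbered narrative drivers shown above.
- `tests/testthat/` — unit, property, and end-to-end acceptance tests
  (exhaustive hypergeometric enumeration, dense linear-solve diffusion
  oracle, BH step-up oracle, planted-module recovery, determinism).
- `vignettes/stage-aware-network-repurposing.Rmd` — the methods vignette:
  model, assumptions, parameter choices, what the synthetic world does and
  does not establish, known limitations.
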