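# Shared fixtures, generated in code and memoised per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# The reference synthetic world at package defaults.
default_world <- function() cached("default_world", generate_world())

# Scored seed table of the default world.
default_seeds <- function() {
  cached("default_seeds",
         assign_curated_scores(dedup_seed_table(default_world()$seed_rows)))
}

# A small world for cheap structural tests.
small_world <- function() {
  cached("small_world", generate_world(synthetic_config(
    n_genes = 300, attachment_m = 2, module_size = 30,
    n_seeds_early = 7, n_seeds_late = 6, n_seeds_us = 10,
    n_annotation_sets = 20, n_planted_sets = 3,
    set_size_range = c(5, 25), rng_seed = 7L
  )))
}

# Fixture bundle of the default world on disk (shared temp dir).
default_bundle_dir <- function() {
  cached("default_bundle_dir", {
    d <- file.path(tempdir(), "pbcnet_default_bundle")
    write_fixture_bundle(default_world(), d)
    d
  })
}

default_run_config <- function(out_dir = tempfile("run_"), ...) {
  d <- default_bundle_dir()
  run_config(edges = file.path(d, "edges.tsv"),
             seeds = file.path(d, "seeds.csv"),
             background = file.path(d, "background.txt"),
             collections = c(drugs = file.path(d, "drugs.gmt"),
                             pathways = file.path(d, "pathways.gmt")),
             out_dir = out_dir, ...)
}

# Tiny deterministic interactome from explicit edges.
toy_net <- function(edges) interactome(matrix(edges, ncol = 2, byrow = TRUE))
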