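# Synthetic world generators: graph growth, module planting, seed sampling,
# annotation collections, fixture round trips.

test_that("config validation names the offending field", {
  err <- expect_error(synthetic_config(module_size = 2000), class = "pbcnet_config_error")
  expect_equal(err$field, "module_size")
  err <- expect_error(synthetic_config(n_genes = 3, attachment_m = 5),
                      class = "pbcnet_config_error")
  expect_equal(err$field, "attachment_m")
  expect_error(synthetic_config(set_size_range = c(10, 5)),
               class = "pbcnet_config_error")
  expect_error(synthetic_config(n_planted_sets = 60, n_annotation_sets = 50),
               class = "pbcnet_config_error")
})

test_that("preferential-attachment growth has the closed-form edge count", {
  # m = 1: a tree
  cfg <- synthetic_config(n_genes = 5, attachment_m = 1, module_size = 2,
                          n_seeds_early = 1, n_seeds_late = 1, n_seeds_us = 1,
                          set_size_range = c(1, 3), rng_seed = 7)
  net <- generate_interactome(cfg)
  expect_length(net$nodes, 5)
  expect_equal(igraph::ecount(net$graph), 4)

  # general closed form: node i adds min(m, i-1) edges
  cfg2 <- synthetic_config(n_genes = 1000, attachment_m = 3)
  net2 <- generate_interactome(cfg2)
  m <- 3; n <- 1000
  expect_equal(igraph::ecount(net2$graph), m * (n - 1) - m * (m - 1) / 2)
  expect_true(igraph::is_connected(net2$graph))

  # heavy tail: max degree well above the median
  deg <- igraph::degree(net2$graph)
  expect_gt(max(deg), 3 * stats::median(deg))
})

test_that("generators are deterministic given the config seed", {
  cfg <- synthetic_config(rng_seed = 11)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(igraph::as_edgelist(w1$net$graph),
                   igraph::as_edgelist(w2$net$graph))
  expect_identical(w1$seed_rows, w2$seed_rows)
  expect_identical(w1$truth, w2$truth)

  # byte-identical fixtures
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_bundle(w1, d1)
  write_fixture_bundle(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted module is connected, right-sized, and cohesion adds internal edges", {
  cfg0 <- synthetic_config(module_cohesion = 0, rng_seed = 5)
  cfg1 <- synthetic_config(module_cohesion = 1, rng_seed = 5)
  net <- generate_interactome(cfg0)
  p0 <- plant_disease_module(net, cfg0)
  p1 <- plant_disease_module(net, cfg1)

  expect_length(p0$module_genes, cfg0$module_size)
  expect_identical(p1$module_genes, p0$module_genes)  # same rng stream for growth
  sub0 <- igraph::induced_subgraph(p0$net$graph, p0$module_genes)
  sub1 <- igraph::induced_subgraph(p1$net$graph, p1$module_genes)
  expect_true(igraph::is_connected(sub0))

  # cohesion = 1 attempts one extra internal edge per module gene
  gained <- igraph::ecount(sub1) - igraph::ecount(sub0)
  expect_gt(gained, 0)
  expect_lte(gained, cfg1$module_size)
  expect_gt(mean(igraph::degree(sub1)), mean(igraph::degree(sub0)))

  # module_size = 1 degenerate case
  cfg_one <- synthetic_config(module_size = 1, n_seeds_early = 1,
                              n_seeds_late = 1, n_seeds_us = 1)
  expect_length(plant_disease_module(net, cfg_one)$module_genes, 1)
})

test_that("module genes are topologically localized", {
  w <- default_world()
  d_all <- igraph::mean_distance(w$net$graph)
  sub_d <- igraph::distances(w$net$graph, v = w$truth$module_genes,
                             to = w$truth$module_genes)
  d_mod <- mean(sub_d[upper.tri(sub_d)])
  expect_lt(d_mod, d_all)
})

test_that("seed sampling respects stage counts, module membership, and score law", {
  w <- small_world()
  rows <- w$seed_rows
  expect_true(all(rows$symbol %in% w$truth$module_genes))
  expect_true(all(rows$stage %in% c("early", "late", "unspecified")))
  expect_equal(as.vector(table(factor(rows$stage,
                                      c("early", "late", "unspecified")))),
               c(7, 6, 10))
  dg <- rows[rows$source == "disgenet", ]
  expect_true(all(dg$score > 0 & dg$score <= 1))
  # components reconstruct the score
  expect_equal(gda_score(dg$C, dg$M, dg$I, dg$L), dg$score, tolerance = 1e-12)

  # zero-count stage yields an empty stage table
  cfg0 <- synthetic_config(n_seeds_early = 0, rng_seed = 3)
  rows0 <- sample_seeds_and_scores(plant_disease_module(generate_interactome(cfg0), cfg0), cfg0)
  expect_false("early" %in% rows0$stage)

  # alpha = beta = 1 gives uniform scores (KS statistic < 0.1 at n = 1000)
  cfgU <- synthetic_config(n_genes = 1200, module_size = 1000,
                           n_seeds_early = 334, n_seeds_late = 333,
                           n_seeds_us = 333, disgenet_frac = 1,
                           score_alpha = 1, score_beta = 1, rng_seed = 9)
  rowsU <- sample_seeds_and_scores(plant_disease_module(generate_interactome(cfgU), cfgU), cfgU)
  ks <- suppressWarnings(stats::ks.test(rowsU$score, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("annotation collections plant module signal as configured", {
  w <- small_world()
  expect_length(w$planted_ids, 3)
  expect_true(all(w$planted_ids %in% names(w$collection)))

  # full overlap with small sets nests planted sets inside the module
  cfg <- synthetic_config(planted_overlap_frac = 1, set_size_range = c(5, 20),
                          rng_seed = 13)
  net <- generate_interactome(cfg)
  pl <- plant_disease_module(net, cfg)
  ann <- generate_annotation_collection(pl$net, pl, cfg)
  for (id in ann$planted_ids) {
    expect_true(all(ann$collection[[id]]$members %in% pl$module_genes))
  }
  cats <- vapply(ann$collection, function(s) s$category, "")
  expect_setequal(unique(cats), c("drug", "pathway"))
})

test_that("fixture bundle round-trips through the pipeline readers", {
  d <- default_bundle_dir()
  w <- default_world()

  net2 <- read_edge_list(file.path(d, "edges.tsv"))
  expect_identical(net2$nodes, w$net$nodes)
  expect_equal(igraph::ecount(net2$graph), igraph::ecount(w$net$graph))

  drugs <- read_gmt(file.path(d, "drugs.gmt"))
  orig_drugs <- Filter(function(s) s$category == "drug", w$collection)
  expect_identical(names(drugs), names(orig_drugs))
  for (id in names(drugs)) {
    expect_setequal(drugs[[id]]$members, orig_drugs[[id]]$members)
    expect_identical(drugs[[id]]$category, "drug")
    expect_identical(drugs[[id]]$name, orig_drugs[[id]]$name)
  }

  # a 5-member set's GMT line has exactly 7 tab-separated fields
  sizes5 <- names(which(vapply(w$collection, function(s) length(s$members), 0L) == 5))
  if (length(sizes5)) {
    gmt_lines <- c(readLines(file.path(d, "drugs.gmt")),
                   readLines(file.path(d, "pathways.gmt")))
    ln <- gmt_lines[startsWith(gmt_lines, paste0(sizes5[1], "\t"))]
    expect_length(strsplit(ln, "\t", fixed = TRUE)[[1]], 7L)
  }

  bg <- read_background(file.path(d, "background.txt"))
  expect_setequal(bg, w$net$nodes)

  manifest <- read.csv(file.path(d, "manifest.csv"))
  expect_equal(manifest$n_rows[manifest$file == "seeds.csv"], nrow(w$seed_rows))
  expect_equal(manifest$n_rows[manifest$file == "edges.tsv"],
               igraph::ecount(w$net$graph))
  expect_equal(manifest$n_rows[manifest$file == "background.txt"],
               length(w$background))
})

test_that("stronger planted signal yields better downstream recovery", {
  # monotonicity in expectation: weak vs strong cohesion/overlap worlds,
  # 20 replicate seeds each, compared on diffusion+PU module recovery AUROC
  rec_quality <- function(cohesion, overlap, seed) {
    cfg <- synthetic_config(n_genes = 400, attachment_m = 2, module_size = 40,
                            module_cohesion = cohesion,
                            planted_overlap_frac = overlap,
                            n_seeds_early = 4, n_seeds_late = 4, n_seeds_us = 8,
                            n_annotation_sets = 10, n_planted_sets = 2,
                            set_size_range = c(5, 20), rng_seed = seed)
    w <- generate_world(cfg)
    seeds <- assign_curated_scores(dedup_seed_table(w$seed_rows))
    h <- propagate(build_operator(w$net), make_seed_vector(seeds, w$net))
    f <- extract_features(w$net, h, seeds$symbol)
    s <- pu_bag_scores(f, seeds$symbol, apu_config(n_bags = 30, rng_seed = seed))
    held <- setdiff(w$truth$module_genes, seeds$symbol)
    lab <- names(s) %in% held
    K <- length(held)
    lp <- select_lp(s, seeds$symbol, K)
    c(auroc = auroc(as.numeric(s), lab),
      precision = mean(lp$symbol %in% held))
  }
  seeds <- 1:20
  weak <- vapply(seeds, function(s) rec_quality(0.1, 0.2, s),
                 c(auroc = 0, precision = 0))
  strong <- vapply(seeds, function(s) rec_quality(0.9, 0.9, s),
                   c(auroc = 0, precision = 0))
  expect_gte(mean(strong["auroc", ]), mean(weak["auroc", ]))
  expect_gte(mean(strong["precision", ]), mean(weak["precision", ]))
})
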