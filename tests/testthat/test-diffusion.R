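# Random walk with restart: initialization, fixed point, ranking, and the
# locality/mass-conservation properties that make the heat scores usable
# as disease-proximity evidence.

make_scored_seeds <- function(symbols, relevance) {
  out <- data.frame(symbol = symbols, source = "disgenet",
                    relevance = relevance, stringsAsFactors = FALSE)
  out$stages <- rep(list("unspecified"), length(symbols))
  structure(out, class = c("pbcnet_seeds", "data.frame"))
}

test_that("seed vector is relevance-weighted and normalized", {
  net <- toy_net(c("A", "B", "B", "C"))
  p0 <- make_seed_vector(make_scored_seeds("B", 0.4), net)
  expect_equal(unname(p0[["B"]]), 1.0)

  p0 <- make_seed_vector(make_scored_seeds(c("A", "C"), c(0.2, 0.6)), net)
  expect_equal(unname(p0[c("A", "C")]), c(0.25, 0.75), ignore_attr = TRUE)
  expect_equal(sum(p0), 1)

  p0 <- make_seed_vector(make_scored_seeds(c("A", "B", "C"), c(0.5, 0.5, 0.5)), net)
  expect_equal(unname(p0), rep(1 / 3, 3), ignore_attr = TRUE)

  # out-of-network seeds are dropped but counted; all-out is an error
  p0 <- make_seed_vector(make_scored_seeds(c("A", "ZZZ"), c(0.5, 0.9)), net)
  expect_equal(attr(p0, "n_dropped"), 1)
  expect_equal(unname(p0[["A"]]), 1.0)
  expect_error(make_seed_vector(make_scored_seeds("ZZZ", 1), net),
               class = "pbcnet_validation_error")
})

test_that("restart = 1 returns the seed vector unchanged", {
  net <- small_world()$net
  W <- build_operator(net)
  p0 <- make_seed_vector(make_scored_seeds(net$nodes[1:5], rep(1, 5)), net)
  h <- propagate(W, p0, diffusion_config(restart = 1))
  expect_equal(as.numeric(h), as.numeric(p0), tolerance = 1e-12)
})

test_that("two-node path has the closed-form fixed point (2/3, 1/3)", {
  net <- toy_net(c("A", "B"))
  W <- build_operator(net)
  p0 <- make_seed_vector(make_scored_seeds("A", 1), net)
  h <- propagate(W, p0, diffusion_config(restart = 0.5))
  expect_equal(unname(h[["A"]]), 2 / 3, tolerance = 1e-7)
  expect_equal(unname(h[["B"]]), 1 / 3, tolerance = 1e-7)
})

test_that("iterative fixed point matches the dense linear solve", {
  # oracle: p = restart * solve(I - (1-restart) W) p0
  for (seed in c(3, 17)) {
    set.seed(seed)
    g <- igraph::sample_gnp(10, 0.4)
    while (!igraph::is_connected(g)) g <- igraph::sample_gnp(10, 0.4)
    igraph::V(g)$name <- sprintf("N%02d", 1:10)
    net <- interactome(igraph::as_edgelist(g))
    W <- build_operator(net)
    cfg <- diffusion_config(restart = 0.3, tol = 1e-10)
    p0 <- make_seed_vector(make_scored_seeds(net$nodes[1:3], c(0.9, 0.5, 0.1)), net)
    h <- propagate(W, p0, cfg)
    direct <- cfg$restart * solve(diag(length(p0)) - (1 - cfg$restart) * as.matrix(W),
                                  as.numeric(p0))
    expect_lt(max(abs(as.numeric(h) - direct)), 10 * cfg$tol)
  }
})

test_that("heat mass is conserved and non-negative at convergence", {
  w <- default_world()
  seeds <- default_seeds()
  h <- propagate(build_operator(w$net), make_seed_vector(seeds, w$net))
  expect_lt(abs(sum(h) - 1), 1e-9)
  expect_true(all(as.numeric(h) >= 0))
})

test_that("non-convergence raises an error carrying the residual", {
  net <- small_world()$net
  W <- build_operator(net)
  p0 <- make_seed_vector(make_scored_seeds(net$nodes[1], 1), net)
  expect_error(propagate(W, p0, diffusion_config(restart = 0.01, tol = 1e-14,
                                                 max_iter = 2)),
               "did not converge")
})

test_that("proximity ranking sorts by heat with lexicographic tie-break", {
  h <- structure(c(A = 0.2, C = 0.5, B = 0.5, D = 0.1), class = "pbcnet_heat",
                 seed_symbols = character(0))
  r <- proximity_ranking(h, exclude = character(0))
  expect_equal(r$symbol, c("B", "C", "A", "D"))

  expect_equal(nrow(proximity_ranking(h, exclude = c("A", "B", "C", "D"))), 0)

  # star graph: all leaves tie; a 2-hop appendage ranks below every leaf
  net <- toy_net(c("HUB", "L1", "HUB", "L2", "HUB", "L3", "L3", "FAR"))
  W <- build_operator(net)
  p0 <- make_seed_vector(make_scored_seeds("HUB", 1), net)
  h2 <- propagate(W, p0, diffusion_config(restart = 0.3, tol = 1e-12))
  r2 <- proximity_ranking(h2)
  expect_equal(r2$symbol[4], "FAR")
  expect_equal(h2[["L1"]], h2[["L2"]], tolerance = 1e-10)
})

test_that("mean heat decays with distance from the seed set", {
  # locality invariant, averaged over 20 replicate synthetic worlds
  profiles <- sapply(1:20, function(seed) {
    cfg <- synthetic_config(n_genes = 400, attachment_m = 2, module_size = 30,
                            n_seeds_early = 3, n_seeds_late = 3, n_seeds_us = 6,
                            n_annotation_sets = 5, n_planted_sets = 1,
                            set_size_range = c(5, 20), rng_seed = seed)
    w <- generate_world(cfg)
    seeds <- assign_curated_scores(dedup_seed_table(w$seed_rows))
    h <- propagate(build_operator(w$net), make_seed_vector(seeds, w$net))
    dmat <- igraph::distances(w$net$graph,
                              to = intersect(seeds$symbol, w$net$nodes))
    d <- apply(dmat, 1, min)
    vapply(0:3, function(k) mean(as.numeric(h)[d == k]), 0)
  })
  mean_profile <- rowMeans(profiles)
  expect_true(all(diff(mean_profile) <= 0))
})

test_that("raising a seed's relevance cannot lower its own heat", {
  net <- small_world()$net
  W <- build_operator(net)
  sym <- net$nodes[c(2, 40, 90)]
  h_lo <- propagate(W, make_seed_vector(make_scored_seeds(sym, c(0.2, 0.5, 0.5)), net))
  h_hi <- propagate(W, make_seed_vector(make_scored_seeds(sym, c(0.8, 0.5, 0.5)), net))
  expect_gt(h_hi[[sym[1]]], h_lo[[sym[1]]])
})

test_that("heat table CSV records rank and seed status", {
  net <- toy_net(c("A", "B", "B", "C"))
  W <- build_operator(net)
  p0 <- make_seed_vector(make_scored_seeds("B", 1), net)
  h <- propagate(W, p0)
  p <- tempfile(fileext = ".csv")
  write_heat_csv(h, p)
  tab <- read.csv(p)
  expect_equal(names(tab), c("symbol", "heat", "rank", "is_seed"))
  expect_equal(tab$symbol[1], "B")
  expect_true(tab$is_seed[1])
})
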