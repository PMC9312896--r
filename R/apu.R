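# Positive-unlabelled prioritization: the only labels we trust are the seed
# genes (positives). Bagged PU learning (Mordelet-Vert style) repeatedly
# samples provisional negatives from the unlabelled pool, fits a ridge
# logistic classifier on diffusion-derived features, and averages each
# unlabelled gene's out-of-bag positive-class score. The top-K unlabelled
# genes by that score become the "likely positive" (LP) set.

#' APU configuration
#'
#' @param n_bags number of PU bagging rounds (default 100).
#' @param negatives_per_bag provisional negatives drawn per round, as a
#'   multiple of the positive count (default 1.0).
#' @param K size of the likely-positive set (default 150).
#' @param lambda ridge penalty of the bag classifier (default 0.01).
#' @param rng_seed integer seed controlling negative sampling.
#' @return list of class `pbcnet_apu_config`.
#' @export
apu_config <- function(n_bags = 100, negatives_per_bag = 1.0, K = 150,
                       lambda = 0.01, rng_seed = 1L) {
  if (n_bags < 1) stop_config("n_bags must be positive", "n_bags")
  if (negatives_per_bag < 1) {
    stop_config("negatives_per_bag must be >= 1", "negatives_per_bag")
  }
  if (K < 1) stop_config("K must be positive", "K")
  structure(list(n_bags = as.integer(n_bags),
                 negatives_per_bag = negatives_per_bag,
                 K = as.integer(K), lambda = lambda,
                 rng_seed = as.integer(rng_seed)),
            class = "pbcnet_apu_config")
}

#' Topology/diffusion features for every gene
#'
#' Five features per node: converged heat, log(1 + degree), fraction of
#' neighbours that are seeds, mean heat of neighbours, and shortest-path
#' distance to the seed set (capped). Columns are standardized to zero mean
#' and unit variance; constant columns are left at 0.
#'
#' @param net `pbcnet_interactome`.
#' @param heat heat vector from [propagate()].
#' @param seeds character vector of in-network seed symbols.
#' @param dist_cap cap on the seed-distance feature (default 10).
#' @return numeric matrix, one row per node (rownames = symbols).
#' @export
extract_features <- function(net, heat, seeds, dist_cap = 10) {
  g <- net$graph
  nodes <- net$nodes
  seeds <- intersect(seeds, nodes)
  if (!length(seeds)) stop_validation("no in-network seeds for feature extraction")
  h <- as.numeric(heat)[match(nodes, names(heat))]

  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- as.numeric(Matrix::colSums(A))
  is_seed <- as.numeric(nodes %in% seeds)
  seed_nb_frac <- as.numeric(A %*% is_seed) / deg
  mean_nb_heat <- as.numeric(A %*% h) / deg

  d <- suppressWarnings(igraph::distances(g, v = igraph::V(g),
                                          to = which(nodes %in% seeds)))
  seed_dist <- pmin(apply(d, 1, min), dist_cap)

  X <- cbind(heat = h, log_degree = log1p(deg),
             seed_neighbour_frac = seed_nb_frac,
             mean_neighbour_heat = mean_nb_heat,
             seed_distance = seed_dist)
  rownames(X) <- nodes
  # standardize; constant columns stay at 0
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  X <- sweep(X, 2, mu)
  keep <- sdv > 0
  X[, keep] <- sweep(X[, keep, drop = FALSE], 2, sdv[keep], "/")
  X[, !keep] <- 0
  X
}

#' Bagged positive-unlabelled scores
#'
#' For each of `n_bags` rounds, `negatives_per_bag * |P|` unlabelled genes
#' are sampled as provisional negatives, a ridge logistic classifier is fit
#' on positives vs that sample, and every out-of-bag unlabelled gene is
#' scored with its positive-class probability. A gene's PU score is the
#' mean over the rounds in which it was out-of-bag; a gene that was never
#' out-of-bag falls back to its mean in-bag score (counted and logged).
#' Rounds whose fit degenerates to a single class are skipped with a
#' warning.
#'
#' @param features matrix from [extract_features()].
#' @param positives seed symbols (>= 5 required).
#' @param cfg [apu_config()].
#' @return named numeric vector of PU scores in \[0, 1\] over all
#'   unlabelled genes, with attributes `n_bags_used` and `n_never_oob`.
#' @export
pu_bag_scores <- function(features, positives, cfg = apu_config()) {
  nodes <- rownames(features)
  positives <- intersect(positives, nodes)
  if (length(positives) < 5) stop_validation("need at least 5 in-network positives")
  unlab <- setdiff(nodes, positives)
  if (!length(unlab)) stop_validation("unlabelled pool is empty")

  n_neg <- max(1L, round(cfg$negatives_per_bag * length(positives)))
  n_neg <- min(n_neg, length(unlab))
  Xp <- features[positives, , drop = FALSE]

  score_sum <- setNames(numeric(length(unlab)), unlab)
  oob_count <- setNames(integer(length(unlab)), unlab)
  inbag_sum <- setNames(numeric(length(unlab)), unlab)
  inbag_count <- setNames(integer(length(unlab)), unlab)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$rng_seed)

  n_used <- 0L
  for (b in seq_len(cfg$n_bags)) {
    neg <- sample(unlab, n_neg)
    X <- rbind(Xp, features[neg, , drop = FALSE])
    y <- c(rep(1, nrow(Xp)), rep(0, n_neg))
    if (length(unique(y)) < 2) {
      warning(sprintf("PU bag %d skipped: single-class fit", b))
      next
    }
    fit <- tryCatch(
      suppressWarnings(
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = cfg$lambda, standardize = FALSE)),
      error = function(e) NULL
    )
    n_used <- n_used + 1L
    pr <- if (is.null(fit)) {
      # constant/degenerate design: intercept-only model, all genes get the
      # positive-class base rate (preserves exchangeability)
      rep(mean(y), length(unlab))
    } else {
      as.numeric(predict(fit, newx = features[unlab, , drop = FALSE],
                         type = "response"))
    }
    names(pr) <- unlab
    oob <- setdiff(unlab, neg)
    score_sum[oob] <- score_sum[oob] + pr[oob]
    oob_count[oob] <- oob_count[oob] + 1L
    inbag_sum[neg] <- inbag_sum[neg] + pr[neg]
    inbag_count[neg] <- inbag_count[neg] + 1L
  }
  if (n_used == 0L) stop("all PU bags failed to fit")

  scores <- ifelse(oob_count > 0, score_sum / oob_count,
                   inbag_sum / pmax(inbag_count, 1L))
  never_oob <- sum(oob_count == 0L)
  if (never_oob) {
    pbc_log("pu_bag_scores", never_oob = never_oob)
  }
  structure(scores, n_bags_used = n_used, n_never_oob = never_oob)
}

#' Select the likely-positive (LP) gene set
#'
#' Top-K non-seed genes by PU score; ties broken lexicographically. Seeds
#' are excluded even if scored.
#'
#' @param scores named PU scores from [pu_bag_scores()].
#' @param seeds seed symbols to exclude.
#' @param K LP set size (default 150).
#' @return data.frame `symbol`, `pu_score`, `rank`, K rows (or fewer if
#'   the candidate pool is smaller).
#' @export
select_lp <- function(scores, seeds, K = 150) {
  syms <- setdiff(names(scores), seeds)
  s <- as.numeric(scores[syms])
  o <- order(-s, syms)
  k <- min(K, length(syms))
  data.frame(symbol = syms[o][seq_len(k)], pu_score = s[o][seq_len(k)],
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Combine seed and LP genes into the final disease gene set
#'
#' @param seeds scored `pbcnet_seeds` (or character vector of symbols).
#' @param lp LP table from [select_lp()].
#' @return data.frame `symbol`, `provenance` (`"seed"` or `"LP"`),
#'   `relevance` (seed relevance or PU score).
#' @export
combine_seed_lp <- function(seeds, lp) {
  seed_sym <- if (is.data.frame(seeds)) seeds$symbol else as.character(seeds)
  seed_rel <- if (is.data.frame(seeds)) seeds$relevance else rep(NA_real_, length(seed_sym))
  overlap <- intersect(seed_sym, lp$symbol)
  if (length(overlap)) {
    stop_validation(sprintf("LP set overlaps seeds: %s",
                            paste(utils::head(overlap, 3), collapse = ", ")))
  }
  data.frame(
    symbol = c(seed_sym, lp$symbol),
    provenance = c(rep("seed", length(seed_sym)), rep("LP", nrow(lp))),
    relevance = c(seed_rel, lp$pu_score),
    stringsAsFactors = FALSE
  )
}
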