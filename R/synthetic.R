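# Synthetic world generator. Emulates the statistical structure the
# analysis assumes: a scale-free PPI-like interactome, a topologically
# cohesive planted disease module, stage-labelled seed genes with GDA-like
# relevance scores (stage proportions mimic the 238/183/728 early/late/
# unspecified split of the real 1121-gene seed list), and drug/pathway
# annotation collections of which a few are enriched in the module.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Synthetic world configuration
#'
#' Defaults describe the package's reference fixture: a 1000-gene
#' scale-free interactome with a 60-gene planted module and 30 stage seed
#' draws split 6/5/19 (early/late/unspecified, mimicking the real data's
#' 238/183/728 proportions).
#'
#' @param n_genes interactome size.
#' @param attachment_m edges added per node in preferential-attachment
#'   growth.
#' @param module_size planted disease module size.
#' @param module_cohesion probability each module gene gains one extra
#'   module-internal edge, in \[0, 1\].
#' @param n_seeds_early,n_seeds_late,n_seeds_us seed draws per stage (one
#'   gene may be drawn by several stages).
#' @param disgenet_frac fraction of seed rows that are database-sourced
#'   (the rest are "manually curated").
#' @param score_alpha,score_beta Beta parameters for GDA-like scores.
#' @param n_annotation_sets,n_planted_sets collection size and number of
#'   module-enriched sets.
#' @param planted_overlap_frac fraction of a planted set's members drawn
#'   from the module.
#' @param set_size_range inclusive (min, max) set sizes.
#' @param rng_seed integer seed.
#' @return list of class `pbcnet_synth_config`.
#' @export
synthetic_config <- function(n_genes = 1000, attachment_m = 3,
                             module_size = 60, module_cohesion = 0.5,
                             n_seeds_early = 6, n_seeds_late = 5,
                             n_seeds_us = 19, disgenet_frac = 0.8,
                             score_alpha = 2, score_beta = 5,
                             n_annotation_sets = 50, n_planted_sets = 5,
                             planted_overlap_frac = 0.8,
                             set_size_range = c(5, 50), rng_seed = 42L) {
  chk <- function(cond, field, msg) if (!cond) stop_config(msg, field)
  chk(n_genes >= 2, "n_genes", "n_genes must be >= 2")
  chk(attachment_m >= 1, "attachment_m", "attachment_m must be >= 1")
  chk(n_genes >= attachment_m + 1, "attachment_m",
      "n_genes must exceed attachment_m")
  chk(module_size >= 1 && module_size < n_genes, "module_size",
      "module_size must be in [1, n_genes)")
  chk(module_cohesion >= 0 && module_cohesion <= 1, "module_cohesion",
      "module_cohesion must be in [0, 1]")
  for (f in c("n_seeds_early", "n_seeds_late", "n_seeds_us")) {
    v <- get(f)
    chk(v >= 0 && v <= module_size, f,
        sprintf("%s must be in [0, module_size]", f))
  }
  chk(disgenet_frac >= 0 && disgenet_frac <= 1, "disgenet_frac",
      "disgenet_frac must be in [0, 1]")
  chk(score_alpha > 0 && score_beta > 0, "score_alpha",
      "Beta parameters must be positive")
  chk(n_planted_sets <= n_annotation_sets, "n_planted_sets",
      "n_planted_sets must not exceed n_annotation_sets")
  chk(planted_overlap_frac >= 0 && planted_overlap_frac <= 1,
      "planted_overlap_frac", "planted_overlap_frac must be in [0, 1]")
  chk(length(set_size_range) == 2 && set_size_range[1] <= set_size_range[2],
      "set_size_range", "set_size_range must be an ordered pair")
  chk(set_size_range[1] >= 1 && set_size_range[2] <= n_genes,
      "set_size_range", "set_size_range must lie within [1, n_genes]")
  structure(
    list(n_genes = as.integer(n_genes), attachment_m = as.integer(attachment_m),
         module_size = as.integer(module_size), module_cohesion = module_cohesion,
         n_seeds_early = as.integer(n_seeds_early),
         n_seeds_late = as.integer(n_seeds_late),
         n_seeds_us = as.integer(n_seeds_us), disgenet_frac = disgenet_frac,
         score_alpha = score_alpha, score_beta = score_beta,
         n_annotation_sets = as.integer(n_annotation_sets),
         n_planted_sets = as.integer(n_planted_sets),
         planted_overlap_frac = planted_overlap_frac,
         set_size_range = as.integer(set_size_range),
         rng_seed = as.integer(rng_seed)),
    class = "pbcnet_synth_config"
  )
}

#' Generate a scale-free synthetic interactome
#'
#' Preferential-attachment (Barabási–Albert) growth: each new node attaches
#' to `attachment_m` existing nodes with probability proportional to their
#' degree, reproducing the heavy-tailed degree distribution of real PPI
#' networks. Node names are `G000001` ... Connected and simple by
#' construction; edge count is `m*(n-1) - m*(m-1)/2`.
#'
#' @param config [synthetic_config()].
#' @return `pbcnet_interactome`.
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "pbcnet_synth_config"))
  g <- with_seed(config$rng_seed, {
    igraph::sample_pa(config$n_genes, m = config$attachment_m,
                      directed = FALSE, algorithm = "psumtree")
  })
  igraph::V(g)$name <- sprintf("G%06d", seq_len(config$n_genes))
  interactome(igraph::as_edgelist(g))
}

#' Plant a cohesive disease module
#'
#' Grows a connected vertex set of `module_size` genes by seeded random
#' expansion from a random root (at each step a uniformly chosen frontier
#' neighbour joins the module), then, with probability `module_cohesion`
#' per module gene, adds one extra edge from that gene to another module
#' gene (skipping duplicates). The extra internal edges create the
#' topological locality that diffusion-based prioritization assumes
#' disease genes to have.
#'
#' @param net `pbcnet_interactome`.
#' @param config [synthetic_config()].
#' @return list with `net` (interactome including cohesion edges) and
#'   `module_genes` (character).
#' @export
plant_disease_module <- function(net, config) {
  stopifnot(inherits(net, "pbcnet_interactome"),
            inherits(config, "pbcnet_synth_config"))
  if (config$module_size > length(net$nodes)) {
    stop_config("module_size exceeds interactome size", "module_size")
  }
  el <- igraph::as_edgelist(net$graph)
  nbrs <- function(vs) unique(c(el[el[, 1] %in% vs, 2], el[el[, 2] %in% vs, 1]))
  res <- with_seed(config$rng_seed + 1L, {
    module <- sample(net$nodes, 1)
    while (length(module) < config$module_size) {
      frontier <- setdiff(nbrs(module), module)
      if (!length(frontier)) break  # unreachable on a connected graph
      module <- c(module, sample(frontier, 1))
    }
    extra <- list()
    gains <- runif(length(module)) < config$module_cohesion
    existing <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
    for (v in module[gains]) {
      cand <- setdiff(module, c(v, nbrs(v)))
      if (length(cand)) {
        cand <- cand[!(paste(pmin(v, cand), pmax(v, cand), sep = "\r") %in% existing)]
      }
      if (length(cand)) {
        u <- sample(cand, 1)
        extra[[length(extra) + 1L]] <- c(v, u)
        existing <- c(existing, paste(min(v, u), max(v, u), sep = "\r"))
      }
    }
    list(module = module, extra = extra)
  })
  if (length(res$extra)) el <- rbind(el, do.call(rbind, res$extra))
  list(net = interactome(el), module_genes = sort(res$module))
}

#' Sample stage-labelled, scored seed genes from the module
#'
#' Each stage draws its configured number of genes from the module without
#' replacement (a gene may be drawn by several stages, as in the real data
#' where per-stage counts sum past the unique gene total). Database
#' (`disgenet`) rows get a Beta-distributed GDA-like score decomposed into
#' C/M/I/L components; curated rows carry empty components and are scored
#' later by the stage-maximum rule.
#'
#' @param truth output of [plant_disease_module()] (or any list with
#'   `module_genes`).
#' @param config [synthetic_config()].
#' @return raw seed row table (`symbol`, `stage`, `source`, `C`, `M`, `I`,
#'   `L`, `score`) ready for [dedup_seed_table()].
#' @export
sample_seeds_and_scores <- function(truth, config) {
  module <- truth$module_genes
  if (!length(module)) stop_validation("module is empty")
  counts <- c(early = config$n_seeds_early, late = config$n_seeds_late,
              unspecified = config$n_seeds_us)
  with_seed(config$rng_seed + 2L, {
    rows <- lapply(names(counts), function(st) {
      n <- counts[[st]]
      if (!n) return(NULL)
      sym <- sample(module, n)
      data.frame(symbol = sym, stage = st, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    n <- nrow(rows)
    rows$source <- ifelse(runif(n) < config$disgenet_frac, "disgenet", "curated")
    score <- pmax(rbeta(n, config$score_alpha, config$score_beta), 1e-9)
    w <- matrix(runif(4 * n), ncol = 4)
    comp <- score * w / rowSums(w)
    comp[rows$source == "curated", ] <- 0
    rows$C <- comp[, 1]; rows$M <- comp[, 2]
    rows$I <- comp[, 3]; rows$L <- comp[, 4]
    rows$score <- ifelse(rows$source == "disgenet", score, NA_real_)
    rownames(rows) <- NULL
    rows
  })
}

#' Generate drug/pathway annotation collections with planted signal
#'
#' `n_planted_sets` sets draw `planted_overlap_frac` of their members from
#' the disease module and the remainder uniformly from the rest of the
#' interactome; decoy sets draw uniformly from all genes. Categories
#' alternate drug/pathway.
#'
#' @param net `pbcnet_interactome`.
#' @param truth list with `module_genes`.
#' @param config [synthetic_config()].
#' @return list with `collection` (`pbcnet_collection`) and `planted_ids`.
#' @export
generate_annotation_collection <- function(net, truth, config) {
  genes <- net$nodes
  module <- truth$module_genes
  with_seed(config$rng_seed + 3L, {
    n_sets <- config$n_annotation_sets
    ids <- sprintf("SET%03d", seq_len(n_sets))
    planted <- if (config$n_planted_sets)
      sort(sample(ids, config$n_planted_sets)) else character(0)
    category <- rep(c("drug", "pathway"), length.out = n_sets)
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    n_sets, replace = TRUE)
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- sizes[i]
      if (ids[i] %in% planted) {
        n_mod <- min(round(config$planted_overlap_frac * size), length(module))
        mod_part <- sample(module, n_mod)
        rest <- sample(setdiff(genes, mod_part), size - n_mod)
        c(mod_part, rest)
      } else {
        sample(genes, size)
      }
    })
    names(sets) <- ids
    pretty <- ifelse(category == "drug", "Drug", "Pathway")
    coll <- annotation_collection(sets, category = category,
                                  names_ = paste(pretty, seq_len(n_sets)))
    list(collection = coll, planted_ids = planted)
  })
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper running every generator with one config: the
#' interactome (including module-cohesion edges), the ground truth, the raw
#' seed table, the annotation collection, and the background (all
#' interactome genes).
#'
#' @param config [synthetic_config()].
#' @return list of class `pbcnet_world`: `net`, `truth` (module_genes,
#'   seed_assignments, planted_set_ids), `seed_rows`, `collection`,
#'   `planted_ids`, `background`, `config`.
#' @export
generate_world <- function(config = synthetic_config()) {
  net0 <- generate_interactome(config)
  planted <- plant_disease_module(net0, config)
  seed_rows <- sample_seeds_and_scores(planted, config)
  ann <- generate_annotation_collection(planted$net, planted, config)
  assign <- split(seed_rows$stage, seed_rows$symbol)
  truth <- list(module_genes = planted$module_genes,
                seed_assignments = lapply(assign, function(x) sort(unique(x))),
                planted_set_ids = ann$planted_ids)
  structure(list(net = planted$net, truth = truth, seed_rows = seed_rows,
                 collection = ann$collection, planted_ids = ann$planted_ids,
                 background = planted$net$nodes, config = config),
            class = "pbcnet_world")
}

#' Write a synthetic world as plain-text fixtures
#'
#' Emits the file dialects the real pipeline reads: edge list TSV, seeds
#' CSV, one GMT per category, background TXT, a ground-truth JSON sidecar,
#' and a manifest CSV listing every file with its row count.
#'
#' @param world `pbcnet_world` from [generate_world()].
#' @param dir output directory (created if needed).
#' @return manifest data.frame (`file`, `n_rows`), invisibly written as
#'   `manifest.csv`.
#' @export
write_fixture_bundle <- function(world, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create fixture directory: %s", dir))
  paths <- c(edges = file.path(dir, "edges.tsv"),
             seeds = file.path(dir, "seeds.csv"),
             drugs = file.path(dir, "drugs.gmt"),
             pathways = file.path(dir, "pathways.gmt"),
             background = file.path(dir, "background.txt"),
             truth = file.path(dir, "ground_truth.json"))

  write_edge_list(world$net, paths["edges"])
  write.csv(world$seed_rows, paths["seeds"], row.names = FALSE, quote = FALSE)
  cats <- vapply(world$collection, function(s) s$category, "")
  write_gmt(structure(world$collection[cats == "drug"],
                      class = "pbcnet_collection"), paths["drugs"])
  write_gmt(structure(world$collection[cats == "pathway"],
                      class = "pbcnet_collection"), paths["pathways"])
  writeLines(world$background, paths["background"])
  jsonlite::write_json(world$truth, paths["truth"], auto_unbox = FALSE,
                       pretty = TRUE)

  n_rows <- c(igraph::ecount(world$net$graph), nrow(world$seed_rows),
              sum(cats == "drug"), sum(cats == "pathway"),
              length(world$background), length(world$truth$module_genes))
  manifest <- data.frame(file = basename(paths), n_rows = n_rows,
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}
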