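# Per-stage orchestration: curation -> diffusion -> PU prioritization ->
# LP selection -> over-representation analysis of both the seed set and
# the LP set against every annotation collection. Stages (early, late,
# unspecified) run independently with stage-specific seeds and
# stage-derived RNG streams, so editing one stage's inputs cannot perturb
# another stage's outputs.

#' Pipeline run configuration
#'
#' File paths plus the sub-configurations of every step. Unknown arguments
#' are rejected (there is no `...`), and referenced files are checked at
#' construction time.
#'
#' @param edges edge-list TSV path.
#' @param seeds seeds CSV path.
#' @param background background TXT path.
#' @param collections named character vector/list of GMT paths (names are
#'   the collection labels, e.g. `drugs`, `pathways`).
#' @param aliases optional alias TSV path.
#' @param out_dir output directory for tables.
#' @param stages stages to run.
#' @param diffusion [diffusion_config()].
#' @param apu [apu_config()].
#' @param min_ids,max_ids,fdr_cut ORA parameters (defaults 5, 2000, 0.05).
#' @param include_us pool unspecified-stage seeds into early/late runs.
#' @param emit_combined additionally run ORA on the combined seed+LP set.
#' @param rng_seed master seed; each stage uses `rng_seed + stage index`.
#' @param edge_columns column names of the interactor columns in the edge
#'   file.
#' @return list of class `pbcnet_run_config`.
#' @export
run_config <- function(edges, seeds, background, collections,
                       aliases = NULL, out_dir = tempfile("pbcnet_run_"),
                       stages = c("early", "late", "unspecified"),
                       diffusion = diffusion_config(), apu = apu_config(),
                       min_ids = 5, max_ids = 2000, fdr_cut = 0.05,
                       include_us = FALSE, emit_combined = FALSE,
                       rng_seed = 1L,
                       edge_columns = c("symbol_a", "symbol_b")) {
  for (p in c(edges, seeds, background, unlist(collections), aliases)) {
    if (!file.exists(p)) stop_config(sprintf("input file not found: %s", p))
  }
  if (is.null(names(collections)) || any(!nzchar(names(collections)))) {
    stop_config("collections must be named", "collections")
  }
  check_stages(stages)
  structure(list(edges = edges, seeds = seeds, background = background,
                 collections = as.list(collections), aliases = aliases,
                 out_dir = out_dir, stages = stages, diffusion = diffusion,
                 apu = apu, min_ids = min_ids, max_ids = max_ids,
                 fdr_cut = fdr_cut, include_us = include_us,
                 emit_combined = emit_combined,
                 rng_seed = as.integer(rng_seed),
                 edge_columns = edge_columns),
            class = "pbcnet_run_config")
}

# Read every input once; shared across stage runs.
load_inputs <- function(cfg) {
  aliases <- if (!is.null(cfg$aliases)) read_alias_map(cfg$aliases) else NULL
  seeds <- assign_curated_scores(
    dedup_seed_table(read_seed_csv(cfg$seeds), aliases))
  net <- read_edge_list(cfg$edges, cfg$edge_columns)
  list(
    net = net,
    W = build_operator(net, cfg$diffusion$normalization),
    seeds = seeds,
    background = read_background(cfg$background),
    collections = lapply(cfg$collections, read_gmt)
  )
}

#' Run one disease-stage analysis
#'
#' The full chain for one stage: stage seed subset, relevance-weighted
#' diffusion, feature extraction, bagged PU scoring, LP selection, and ORA
#' with the stage's seed genes (seed path) and with the LP genes (LP path)
#' against every collection. A stage with no in-network seeds returns NULL
#' (skipped, with a message).
#'
#' @param stage stage label.
#' @param cfg [run_config()].
#' @param inputs preloaded inputs (internal reuse); loaded from `cfg` if
#'   NULL.
#' @return list of class `pbcnet_stage_run`: `stage`, `seeds`, `heat`,
#'   `lp`, `combined`, `seed_ora`, `lp_ora`, (`combined_ora`), `meta`.
#' @export
run_stage <- function(stage, cfg, inputs = NULL) {
  check_stages(stage)
  if (is.null(inputs)) inputs <- load_inputs(cfg)
  t0 <- proc.time()[["elapsed"]]

  st_seeds <- stage_seeds(inputs$seeds, stage, cfg$include_us)
  in_net <- intersect(st_seeds$symbol, inputs$net$nodes)
  if (!length(in_net)) {
    message(sprintf("stage '%s' skipped: no in-network seeds", stage))
    return(NULL)
  }

  p0 <- make_seed_vector(st_seeds, inputs$net)
  heat <- propagate(inputs$W, p0, cfg$diffusion)
  feats <- extract_features(inputs$net, heat, in_net)

  apu <- cfg$apu
  apu$rng_seed <- cfg$rng_seed + match(stage, STAGES)
  scores <- pu_bag_scores(feats, in_net, apu)
  lp <- select_lp(scores, st_seeds$symbol, apu$K)
  combined <- combine_seed_lp(st_seeds, lp)

  ora_for <- function(query) {
    lapply(inputs$collections, function(coll) {
      run_ora(query, coll, inputs$background,
              min_ids = cfg$min_ids, max_ids = cfg$max_ids,
              fdr_cut = cfg$fdr_cut)
    })
  }
  out <- list(stage = stage, seeds = st_seeds, heat = heat, lp = lp,
              combined = combined,
              seed_ora = ora_for(st_seeds$symbol),
              lp_ora = ora_for(lp$symbol))
  if (cfg$emit_combined) out$combined_ora <- ora_for(combined$symbol)
  out$meta <- list(rng_seed = apu$rng_seed,
                   n_seeds = nrow(st_seeds), n_in_network = length(in_net),
                   diffusion_iterations = attr(heat, "iterations"),
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  class(out) <- "pbcnet_stage_run"
  out
}

#' Run the full per-stage pipeline and write its tables
#'
#' Runs every configured stage, writes per-stage heat, LP, combined-set and
#' ORA CSVs plus a run manifest into `cfg$out_dir`, and returns the stage
#' runs with the summary report. Output files carry no timestamps, so a
#' rerun with the same config and seed is byte-identical.
#'
#' @param cfg [run_config()].
#' @return list of class `pbcnet_run`: `runs` (per stage), `report`
#'   ([assemble_report()]), `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pbcnet_run_config"))
  inputs <- load_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  runs <- list()
  for (stage in cfg$stages) {
    run <- run_stage(stage, cfg, inputs)
    if (is.null(run)) next
    runs[[stage]] <- run
    write_heat_csv(run$heat, file.path(cfg$out_dir, sprintf("%s_heat.csv", stage)))
    write.csv(run$lp, file.path(cfg$out_dir, sprintf("%s_lp.csv", stage)),
              row.names = FALSE, quote = FALSE)
    write.csv(run$combined,
              file.path(cfg$out_dir, sprintf("%s_combined.csv", stage)),
              row.names = FALSE, quote = FALSE)
    for (lbl in names(run$seed_ora)) {
      write_ora_csv(run$seed_ora[[lbl]],
                    file.path(cfg$out_dir, sprintf("%s_seed_ora_%s.csv", stage, lbl)))
      write_ora_csv(run$lp_ora[[lbl]],
                    file.path(cfg$out_dir, sprintf("%s_lp_ora_%s.csv", stage, lbl)))
      if (cfg$emit_combined) {
        write_ora_csv(run$combined_ora[[lbl]],
                      file.path(cfg$out_dir,
                                sprintf("%s_combined_ora_%s.csv", stage, lbl)))
      }
    }
  }
  if (!length(runs)) stop("no stage could be run (no in-network seeds anywhere)")

  report <- assemble_report(runs)
  write.csv(report, file.path(cfg$out_dir, "report.csv"), row.names = FALSE,
            quote = TRUE)
  manifest <- data.frame(file = sort(list.files(cfg$out_dir)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[manifest$file != "run_manifest.csv", , drop = FALSE]
  manifest$n_rows <- vapply(manifest$file, function(f) {
    length(readLines(file.path(cfg$out_dir, f))) - 1L
  }, 0L)
  write.csv(manifest, file.path(cfg$out_dir, "run_manifest.csv"),
            row.names = FALSE, quote = FALSE)

  structure(list(runs = runs, report = report, out_dir = cfg$out_dir),
            class = "pbcnet_run")
}

#' Summary report of the most enriched sets
#'
#' Top-10 enriched sets per (stage, query type, category), ordered by FDR,
#' then p, then set id, in one tidy long-format table.
#'
#' @param runs list of `pbcnet_stage_run` objects (NULLs allowed, skipped).
#' @param top_n rows kept per group (default 10).
#' @return data.frame `stage`, `query_type`, `collection`, `category`,
#'   `set_id`, `name`, `k`, `K_set`, `p`, `fdr`, `significant`.
#' @export
assemble_report <- function(runs, top_n = 10) {
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop_validation("assemble_report needs at least one stage run")
  pieces <- list()
  for (run in runs) {
    families <- list(seed = run$seed_ora, LP = run$lp_ora)
    if (!is.null(run$combined_ora)) families$combined <- run$combined_ora
    for (qt in names(families)) {
      for (lbl in names(families[[qt]])) {
        tab <- families[[qt]][[lbl]]
        if (!nrow(tab)) next
        for (cat in unique(tab$category)) {
          sub <- tab[tab$category == cat, , drop = FALSE]
          sub <- sub[order(sub$fdr, sub$p, sub$set_id), , drop = FALSE]
          sub <- utils::head(sub, top_n)
          pieces[[length(pieces) + 1L]] <- data.frame(
            stage = run$stage, query_type = qt, collection = lbl,
            category = cat, set_id = sub$set_id, name = sub$name,
            k = sub$k, K_set = sub$K_set, p = sub$p, fdr = sub$fdr,
            significant = sub$significant, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(pieces)) {
    return(data.frame(stage = character(0), query_type = character(0),
                      collection = character(0), category = character(0),
                      set_id = character(0), name = character(0),
                      k = integer(0), K_set = integer(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(pieces, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}
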