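# Seed curation: symbol normalization, dedup with stage-label union,
# gene-disease association (GDA) scoring, and the stage-maximum rule that
# gives manually curated genes at least the best database score of their
# stage.

#' Read a two-column alias table
#'
#' Tab-delimited file mapping raw gene symbol tokens to canonical HGNC
#' symbols (columns `alias`, `symbol`, header required). Matching is
#' case-insensitive; canonical symbols always map to themselves.
#'
#' @param path file path.
#' @return named character vector: `names()` are uppercased raw tokens,
#'   values are canonical symbols.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("alias file not found: %s", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("alias", "symbol")
  if (!all(need %in% names(tab))) {
    stop_validation("alias table must have columns 'alias' and 'symbol'")
  }
  alias_map(setNames(tab$symbol, tab$alias))
}

#' Build an alias map from a named vector
#'
#' @param x named character vector (names = raw tokens, values = canonical
#'   symbols) or NULL for the identity map.
#' @return normalized alias map (uppercased keys and values, canonical
#'   symbols self-mapped).
#' @export
alias_map <- function(x = NULL) {
  if (is.null(x) || !length(x)) {
    return(structure(character(0), class = "pbcnet_alias_map"))
  }
  keys <- toupper(trimws(names(x)))
  vals <- toupper(trimws(unname(x)))
  dup <- duplicated(keys)
  if (any(dup & vals[dup] != vals[match(keys[dup], keys)])) {
    stop_validation("alias map is not functional: one token maps to two symbols")
  }
  keys2 <- c(keys, setdiff(vals, keys))     # canonical symbols self-map
  vals2 <- c(vals, setdiff(vals, keys))
  keep <- !duplicated(keys2)
  structure(setNames(vals2[keep], keys2[keep]), class = "pbcnet_alias_map")
}

#' Normalize one or more raw gene symbol tokens
#'
#' Trims, uppercases, and resolves through the alias map; tokens absent from
#' the map are kept uppercased and flagged unmapped rather than dropped, so
#' curation never silently shrinks a seed list.
#'
#' @param raw character vector of raw tokens.
#' @param aliases an [alias_map()]; NULL for pure case/whitespace
#'   normalization.
#' @return data.frame with columns `raw`, `symbol` (canonical), `mapped`
#'   (logical: found in the alias map).
#' @export
normalize_symbol <- function(raw, aliases = NULL) {
  tok <- trimws(as.character(raw))
  if (any(!nzchar(tok))) stop_validation("empty gene symbol token")
  up <- toupper(tok)
  if (is.null(aliases)) aliases <- alias_map()
  hit <- match(up, names(aliases))
  out <- ifelse(is.na(hit), up, unname(aliases[hit]))
  data.frame(raw = tok, symbol = out, mapped = !is.na(hit),
             stringsAsFactors = FALSE)
}

#' GDA relevance score
#'
#' Gene-disease association score as the sum of four evidence components --
#' curated sources (C), non-human model-organism sources (M), GWAS-type
#' sources (I), and text-mining publication support (L) -- clamped to the
#' score's documented range \[0, 1\].
#'
#' @param C,M,I,L non-negative component values (vectorized).
#' @return numeric in \[0, 1\].
#' @export
gda_score <- function(C, M = 0, I = 0, L = 0) {
  comp <- cbind(C, M, I, L)
  if (any(!is.finite(comp)) || any(comp < 0)) {
    stop_validation("GDA components must be finite and non-negative")
  }
  pmin(1, rowSums(comp))
}

#' Deduplicate a raw seed table into canonical seed genes
#'
#' Rows carrying the same canonical symbol collapse to one seed gene whose
#' stage set is the union of the rows' stage labels. If any duplicate row is
#' database-sourced (`disgenet`), the gene is treated as database-sourced and
#' scored by [gda_score()] from its components (maximum across duplicate
#' disgenet rows); otherwise it stays `curated` and is scored later by
#' [assign_curated_scores()]. Malformed rows (bad stage or source, empty
#' symbol) are skipped with a warning, not an error.
#'
#' @param rows data.frame with columns `symbol`, `stage`, `source`, and
#'   optionally `C`, `M`, `I`, `L` (GDA components, used for disgenet rows).
#' @param aliases optional [alias_map()].
#' @return object of class `pbcnet_seeds`: data.frame with columns `symbol`,
#'   `stages` (list of character), `source`, `relevance` (NA for curated
#'   until scored), plus attributes `n_input`, `n_skipped`, `n_unmapped`.
#' @export
dedup_seed_table <- function(rows, aliases = NULL) {
  stopifnot(is.data.frame(rows))
  need <- c("symbol", "stage", "source")
  if (!all(need %in% names(rows))) {
    stop_validation("seed table needs columns symbol, stage, source")
  }
  for (comp in c("C", "M", "I", "L")) {
    if (is.null(rows[[comp]])) rows[[comp]] <- 0
  }
  n_input <- nrow(rows)

  ok_sym <- nzchar(trimws(as.character(rows$symbol)))
  ok_stage <- rows$stage %in% STAGES
  ok_src <- rows$source %in% c("disgenet", "curated")
  ok <- ok_sym & ok_stage & ok_src & !is.na(rows$symbol)
  n_skipped <- sum(!ok)
  if (n_skipped) {
    warning(sprintf("dedup_seed_table: skipped %d malformed row(s)", n_skipped))
  }
  rows <- rows[ok, , drop = FALSE]
  if (!nrow(rows)) {
    out <- data.frame(symbol = character(0), source = character(0),
                      relevance = numeric(0), stringsAsFactors = FALSE)
    out$stages <- list()
    return(structure(out[, c("symbol", "stages", "source", "relevance")],
                     class = c("pbcnet_seeds", "data.frame"),
                     n_input = n_input, n_skipped = n_skipped, n_unmapped = 0L))
  }

  norm <- normalize_symbol(rows$symbol, aliases)
  rows$symbol <- norm$symbol
  n_unmapped <- length(unique(norm$symbol[!norm$mapped & !is.null(aliases)]))

  key <- rows$symbol
  syms <- sort(unique(key))
  stages <- lapply(syms, function(s) {
    sort(unique(rows$stage[key == s]))
  })
  source <- vapply(syms, function(s) {
    if (any(rows$source[key == s] == "disgenet")) "disgenet" else "curated"
  }, "")
  relevance <- vapply(seq_along(syms), function(i) {
    s <- syms[i]
    if (source[i] != "disgenet") return(NA_real_)
    sub <- rows[key == s & rows$source == "disgenet", , drop = FALSE]
    max(gda_score(sub$C, sub$M, sub$I, sub$L))
  }, 0)

  out <- data.frame(symbol = syms, source = source, relevance = relevance,
                    stringsAsFactors = FALSE)
  out$stages <- stages
  out <- out[, c("symbol", "stages", "source", "relevance")]
  pbc_log("dedup_seed_table", n_in = n_input, n_out = nrow(out),
          skipped = n_skipped)
  structure(out, class = c("pbcnet_seeds", "data.frame"),
            n_input = n_input, n_skipped = n_skipped,
            n_unmapped = n_unmapped)
}

#' Score manually curated seed genes by the stage-maximum rule
#'
#' A curated gene's relevance is the maximum database (disgenet) GDA score
#' observed in its stage; a gene labelled with several stages takes the
#' maximum across those stage maxima. A stage with no database genes falls
#' back to 1.0, so curated genes always carry at least as much diffusion
#' weight as database genes -- they are the better-vetted evidence.
#'
#' @param seeds a `pbcnet_seeds` table (from [dedup_seed_table()]).
#' @return the same table with `relevance` filled for curated rows.
#' @export
assign_curated_scores <- function(seeds) {
  stopifnot(inherits(seeds, "pbcnet_seeds"))
  stage_max <- vapply(STAGES, function(st) {
    in_stage <- vapply(seeds$stages, function(ss) st %in% ss, TRUE)
    v <- seeds$relevance[in_stage & seeds$source == "disgenet"]
    v <- v[!is.na(v)]
    if (length(v)) max(v) else 1.0
  }, 0)
  cur <- which(seeds$source == "curated")
  for (i in cur) {
    if (!length(seeds$stages[[i]])) {
      stop_validation(sprintf("curated gene %s has no stage label", seeds$symbol[i]))
    }
    seeds$relevance[i] <- max(stage_max[seeds$stages[[i]]])
  }
  seeds
}

#' Subset seed genes for one stage run
#'
#' @param seeds scored `pbcnet_seeds` table.
#' @param stage one of `"early"`, `"late"`, `"unspecified"`.
#' @param include_us also include unspecified-stage seeds in an early/late
#'   run (default FALSE: each stage run uses only its own stage's seeds).
#' @return `pbcnet_seeds` subset.
#' @export
stage_seeds <- function(seeds, stage, include_us = FALSE) {
  check_stages(stage)
  want <- stage
  if (include_us && stage != "unspecified") want <- c(stage, "unspecified")
  keep <- vapply(seeds$stages, function(ss) any(want %in% ss), TRUE)
  out <- seeds[keep, , drop = FALSE]
  class(out) <- class(seeds)
  out
}

#' Read a seeds CSV
#'
#' Expects columns `symbol, stage, source, C, M, I, L` (score columns
#' optional); the dialect written by [write_fixture_bundle()].
#'
#' @param path CSV path.
#' @return raw data.frame suitable for [dedup_seed_table()].
#' @export
read_seed_csv <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("seed file not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write the canonical scored seed table as CSV
#'
#' Stage sets are serialized semicolon-joined, one row per gene.
#'
#' @param seeds scored `pbcnet_seeds`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_seed_csv <- function(seeds, path) {
  flat <- data.frame(
    symbol = seeds$symbol,
    stages = vapply(seeds$stages, paste, "", collapse = ";"),
    source = seeds$source,
    relevance = seeds$relevance,
    stringsAsFactors = FALSE
  )
  write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
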