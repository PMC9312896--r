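# Over-representation analysis: query gene sets (seeds or LP genes) are
# tested against GMT annotation collections (drug-gene and pathway sets)
# with a one-sided Fisher exact test on the protein-coding background,
# followed by Benjamini-Hochberg FDR across all size-filtered sets in the
# collection. Significance bound: FDR < 0.05.

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member symbols, tab-separated.
#' Duplicate members within a line are deduplicated; duplicate set ids are
#' an error.
#'
#' @param path GMT file.
#' @param category tag attached to every set (`"drug"` or `"pathway"`); if
#'   NULL, taken from a `category=` token in the description field when
#'   present, otherwise `"pathway"`.
#' @return object of class `pbcnet_collection`: named list of sets, each a
#'   list with `id`, `name`, `category`, `members`.
#' @export
read_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_validation(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    }
    desc <- f[2]
    cat_i <- category
    name_i <- desc
    m <- regmatches(desc, regexec("^(.*?)\\|?category=(\\w+)$", desc))[[1]]
    if (length(m) == 3) {
      name_i <- if (nzchar(m[2])) m[2] else f[1]
      if (is.null(cat_i)) cat_i <- m[3]
    }
    if (is.null(cat_i)) cat_i <- "pathway"
    ids[i] <- f[1]
    sets[[i]] <- list(id = f[1], name = name_i, category = cat_i,
                      members = unique(toupper(f[-(1:2)])))
  }
  if (anyDuplicated(ids)) {
    stop_validation(sprintf("duplicate set id(s) in GMT: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(setNames(sets, ids), class = "pbcnet_collection")
}

#' Build an annotation collection in memory
#'
#' @param sets named list of character vectors (names = set ids).
#' @param category `"drug"` or `"pathway"` (recycled).
#' @param names_ display names; default the ids.
#' @return `pbcnet_collection`.
#' @export
annotation_collection <- function(sets, category = "pathway", names_ = names(sets)) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_validation("sets must be uniquely named")
  }
  category <- rep_len(category, length(sets))
  out <- lapply(seq_along(sets), function(i) {
    list(id = names(sets)[i], name = names_[i], category = category[i],
         members = unique(toupper(sets[[i]])))
  })
  structure(setNames(out, names(sets)), class = "pbcnet_collection")
}

#' Write a collection as GMT
#'
#' @param collection `pbcnet_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    desc <- sprintf("%s|category=%s", s$name, s$category)
    paste(c(s$id, desc, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Size-filter a collection against a background
#'
#' Members are intersected with the background; sets whose mapped size falls
#' outside `[min_ids, max_ids]` are removed. Defaults follow the standard
#' ORA practice of testing only sets with 5-2000 mapped IDs.
#'
#' @param collection `pbcnet_collection`.
#' @param background character vector of background symbols.
#' @param min_ids,max_ids inclusive mapped-size bounds (defaults 5, 2000).
#' @return filtered `pbcnet_collection` with attribute `n_removed`.
#' @export
filter_sets <- function(collection, background, min_ids = 5, max_ids = 2000) {
  if (!length(background)) stop_validation("background is empty")
  background <- unique(toupper(background))
  mapped <- lapply(collection, function(s) {
    s$members <- intersect(s$members, background)
    s
  })
  sizes <- vapply(mapped, function(s) length(s$members), 0L)
  keep <- sizes >= min_ids & sizes <= max_ids
  pbc_log("filter_sets", n_in = length(collection), n_kept = sum(keep))
  structure(setNames(mapped[keep], names(collection)[keep]),
            class = "pbcnet_collection", n_removed = sum(!keep))
}

#' Upper-tail Fisher exact p-value for set over-representation
#'
#' Probability of observing `k` or more query genes inside a set of
#' background-mapped size `K_set`, when `n_query` genes are drawn without
#' replacement from a background of `N`: the hypergeometric upper tail
#' \eqn{P(X \ge k)}. One-sided by design -- ORA tests enrichment only.
#'
#' @param k overlap count.
#' @param K_set background-mapped set size.
#' @param n_query background-mapped query size.
#' @param N background size.
#' @return p-value in \[0, 1\] (vectorized over the arguments).
#' @export
fisher_upper_tail <- function(k, K_set, n_query, N) {
  args <- cbind(k, K_set, n_query, N)
  k <- args[, 1]; K_set <- args[, 2]; n_query <- args[, 3]; N <- args[, 4]
  bad <- k < 0 | k > K_set | k > n_query | K_set > N | n_query > N
  if (any(bad)) stop_validation("inconsistent hypergeometric counts")
  as.numeric(stats::phyper(k - 1, K_set, N - K_set, n_query, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH FDR adjustment (with the enforced monotonicity of the
#' step-up procedure), aligned to the input order and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run over-representation analysis
#'
#' Query and set members are mapped to the background; size-filtered sets
#' are tested with [fisher_upper_tail()]; BH adjustment spans all tested
#' sets in the collection (the per-database testing family). Rows sorted by
#' p, ties by set id.
#'
#' @param query character vector of query gene symbols.
#' @param collection `pbcnet_collection`.
#' @param background background symbols.
#' @param min_ids,max_ids size filter bounds (defaults 5, 2000).
#' @param fdr_cut significance bound on the adjusted value (default 0.05).
#' @return data.frame of class `pbcnet_ora`: columns `set_id`, `name`,
#'   `category`, `k`, `K_set`, `n_query`, `N`, `p`, `fdr`, `significant`,
#'   `overlap_genes` (semicolon-joined, sorted).
#' @export
run_ora <- function(query, collection, background, min_ids = 5, max_ids = 2000,
                    fdr_cut = 0.05) {
  background <- unique(toupper(background))
  query <- unique(toupper(query))
  n_dropped <- sum(!(query %in% background))
  query <- intersect(query, background)
  if (!length(query)) stop_validation("query is empty after background mapping")
  pbc_log("run_ora", n_query = length(query), dropped = n_dropped)

  coll <- filter_sets(collection, background, min_ids, max_ids)
  N <- length(background)
  if (!length(coll)) {
    out <- data.frame(set_id = character(0), name = character(0),
                      category = character(0), k = integer(0), K_set = integer(0),
                      n_query = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0),
                      overlap_genes = character(0), stringsAsFactors = FALSE)
    class(out) <- c("pbcnet_ora", "data.frame")
    return(out)
  }
  rows <- lapply(coll, function(s) {
    ov <- sort(intersect(query, s$members))
    data.frame(set_id = s$id, name = s$name, category = s$category,
               k = length(ov), K_set = length(s$members),
               n_query = length(query), N = N,
               p = fisher_upper_tail(length(ov), length(s$members),
                                     length(query), N),
               overlap_genes = paste(ov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_cut
  out <- out[order(out$p, out$set_id), c("set_id", "name", "category", "k",
                                         "K_set", "n_query", "N", "p", "fdr",
                                         "significant", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("pbcnet_ora", "data.frame")
  out
}

#' Write an ORA result table as CSV
#'
#' Fixed column order for diffability.
#'
#' @param ora `pbcnet_ora` table.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ora_csv <- function(ora, path) {
  write.csv(as.data.frame(ora), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a background gene list
#'
#' One symbol per line; uppercased, deduplicated.
#'
#' @param path text file.
#' @return character vector.
#' @export
read_background <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("background file not found: %s", path))
  x <- trimws(readLines(path))
  unique(toupper(x[nzchar(x)]))
}
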