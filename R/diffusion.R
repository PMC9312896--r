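# Network propagation: seed relevance is injected as "heat" and spread by a
# random walk with restart until the stationary distribution
# p = r * p0 + (1 - r) * W p is reached. Small restart r lets heat travel
# far; large r keeps it local to the seeds.

#' Diffusion configuration
#'
#' @param restart fraction of heat re-injected at the seeds each step, in
#'   (0, 1]. Controls locality; default 0.3.
#' @param tol max-norm convergence threshold (default 1e-8).
#' @param max_iter iteration cap (default 10000).
#' @param normalization operator normalization mode.
#' @return list of class `pbcnet_diffusion_config`.
#' @export
diffusion_config <- function(restart = 0.3, tol = 1e-8, max_iter = 10000,
                             normalization = c("column-stochastic",
                                               "symmetric-degree")) {
  if (!is.numeric(restart) || restart <= 0 || restart > 1) {
    stop_config("restart must be in (0, 1]", "restart")
  }
  if (!is.numeric(tol) || tol <= 0) stop_config("tol must be positive", "tol")
  if (max_iter < 1) stop_config("max_iter must be positive", "max_iter")
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter),
                 normalization = match.arg(normalization)),
            class = "pbcnet_diffusion_config")
}

#' Initial heat vector from scored seed genes
#'
#' Each in-network seed receives heat proportional to its relevance score;
#' entries sum to 1. Seeds absent from the interactome are dropped from the
#' diffusion (they cannot emit or receive heat) but the dropped count is
#' recorded, since they remain disease genes for enrichment purposes.
#'
#' @param seeds scored `pbcnet_seeds`.
#' @param net `pbcnet_interactome`.
#' @return named numeric vector over `net$nodes` with attributes
#'   `seed_symbols` (in-network) and `n_dropped`.
#' @export
make_seed_vector <- function(seeds, net) {
  stopifnot(inherits(net, "pbcnet_interactome"))
  if (any(is.na(seeds$relevance))) {
    stop_validation("seeds must be scored before diffusion (see assign_curated_scores)")
  }
  if (any(seeds$relevance < 0 | seeds$relevance > 1)) {
    stop_validation("seed relevance must lie in [0, 1]")
  }
  in_net <- seeds$symbol %in% net$nodes
  if (!any(in_net)) stop_validation("no seed gene is present in the interactome")
  p0 <- setNames(numeric(length(net$nodes)), net$nodes)
  w <- seeds$relevance[in_net]
  if (sum(w) <= 0) stop_validation("total in-network seed relevance is zero")
  p0[seeds$symbol[in_net]] <- w / sum(w)
  pbc_log("make_seed_vector", seeds_in = sum(in_net), dropped = sum(!in_net))
  structure(p0, seed_symbols = seeds$symbol[in_net], n_dropped = sum(!in_net))
}

#' Propagate heat to the random-walk-with-restart fixed point
#'
#' Iterates \eqn{p \leftarrow r p_0 + (1-r) W p} from `p0` until the
#' max-norm update falls below `tol`. With a column-stochastic operator the
#' total heat mass of 1 is conserved exactly.
#'
#' @param W propagation operator from [build_operator()].
#' @param p0 initial heat vector (sums to 1), e.g. [make_seed_vector()].
#' @param cfg [diffusion_config()].
#' @return heat vector of class `pbcnet_heat`: named numeric with
#'   attributes `iterations`, `residual`, `restart`, `seed_symbols`.
#' @export
propagate <- function(W, p0, cfg = diffusion_config()) {
  if (length(p0) != nrow(W)) stop_validation("p0 length does not match operator")
  if (abs(sum(p0) - 1) > 1e-8) stop_validation("p0 must sum to 1")
  r <- cfg$restart
  p <- p0
  it <- 0L
  res <- Inf
  while (it < cfg$max_iter) {
    it <- it + 1L
    p_new <- as.numeric(r * p0 + (1 - r) * (W %*% p))
    res <- max(abs(p_new - p))
    p <- p_new
    if (res < cfg$tol) break
  }
  if (res >= cfg$tol) {
    stop(sprintf("diffusion did not converge in %d iterations (residual %.3e)",
                 cfg$max_iter, res))
  }
  pbc_log("propagate", iterations = it, residual = res)
  structure(setNames(p, names(p0)), class = "pbcnet_heat",
            iterations = it, residual = res, restart = r,
            seed_symbols = attr(p0, "seed_symbols"))
}

#' Proximity ranking of non-seed genes
#'
#' Genes sorted by converged heat, descending; ties broken lexicographically
#' by symbol so rankings are reproducible.
#'
#' @param heat heat vector from [propagate()].
#' @param exclude symbols to leave out (typically the seed set).
#' @return data.frame `symbol`, `heat`, `rank`.
#' @export
proximity_ranking <- function(heat, exclude = attr(heat, "seed_symbols")) {
  syms <- names(heat)
  keep <- !(syms %in% exclude)
  syms <- syms[keep]
  h <- as.numeric(heat)[keep]
  o <- order(-h, syms)
  data.frame(symbol = syms[o], heat = h[o],
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Write a per-stage heat table
#'
#' @param heat heat vector from [propagate()].
#' @param path output CSV (`symbol, heat, rank, is_seed`).
#' @return `path`, invisibly.
#' @export
write_heat_csv <- function(heat, path) {
  syms <- names(heat)
  h <- as.numeric(heat)
  o <- order(-h, syms)
  out <- data.frame(symbol = syms[o], heat = h[o], rank = seq_along(o),
                    is_seed = syms[o] %in% attr(heat, "seed_symbols"),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
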