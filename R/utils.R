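#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbeta runif setNames predict
#' @importFrom utils read.delim write.csv read.csv
NULL

# Internal: consistent condition helpers so callers can distinguish
# user/configuration errors from internal ones.
stop_config <- function(msg, field = NULL) {
  stop(structure(
    class = c("pbcnet_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  ))
}

stop_validation <- function(msg) {
  stop(structure(
    class = c("pbcnet_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Structured one-line step logging: "step | k=v k=v".
pbc_log <- function(step, ..., verbose = getOption("pbcnet.verbose", FALSE)) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  kv <- list(...)
  txt <- if (length(kv)) {
    paste(names(kv), vapply(kv, format, ""), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[pbcnet] %s | %s", step, txt))
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score vector against binary labels.
#' Used to quantify how well diffusion or PU scores separate planted disease
#' module genes from the rest of the synthetic interactome.
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector, same length; TRUE/1 = positive.
#' @return AUROC in \[0, 1\]; ties handled by midranks.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop_validation("scores and labels must have equal length")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_validation("auroc needs at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stage vocabulary shared across modules.
STAGES <- c("early", "late", "unspecified")

check_stages <- function(stages) {
  bad <- setdiff(stages, STAGES)
  if (length(bad)) {
    stop_validation(sprintf(
      "invalid stage label(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(STAGES, collapse = ", ")
    ))
  }
  invisible(stages)
}
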