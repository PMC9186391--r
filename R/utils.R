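# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table as TSV
#'
#' Plain-text TSV writer used for all tabular outputs (no quoting, no row
#' names), so that emitted files round-trip through [read_tsv()].
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#'
#' @param path input file path.
#' @return data.frame with character columns left as character.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Deterministic per-stage seeds derived from one master seed, so a single
# stage can be regenerated in isolation. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stages <- c(truth = 1L, genome = 2L, counts = 3L, junctions = 4L,
              clip = 5L, generic = 6L)
  if (!stage %in% names(stages)) stop("unknown substream: ", stage)
  (as.integer(seed) %% 1000003L) + 1000003L * stages[[stage]]
}

with_substream <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, stage))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
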