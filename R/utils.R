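#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All randomness in the pipeline flows from one root seed through named
#' substreams, so that each stage is independently reproducible: re-running
#' only the eQTL stage with the same root seed uses the same stream it saw
#' in a full run.
#'
#' @param seed integer root seed.
#' @param stream character stream name (e.g. "simulate", "folds").
#' @return an integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # polynomial rolling hash of the stream name, mixed with the root seed;
  # kept below 2^31 (R integers are 32-bit)
  h <- 17
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic content hash of an R object
#'
#' FNV-1a over the deparsed object; used to stamp output files with the
#' configuration they came from, and to compare run bundles bit-for-bit.
#'
#' @param x any R object.
#' @return character hex digest.
#' @export
content_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
             collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Write a table as TSV with a provenance header comment
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @param comment named character vector written as `# key: value` lines.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  dt <- data.table::as.data.table(x, keep.rownames = FALSE)
  if (!is.null(comment)) {
    writeLines(sprintf("# %s: %s", names(comment), as.character(comment)), path)
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n",
                       append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Read a TSV written by [write_tsv()], skipping `#` comment lines
#'
#' @param path input path.
#' @return data.table.
#' @export
read_tsv <- function(path) {
  head_lines <- readLines(path, n = 200L)
  n_comment <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                    skip = n_comment)
}

# ceil-style nearest-rank index for a lower-tail quantile
nearest_rank <- function(n, q) max(1L, as.integer(ceiling(n * q)))
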