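# Seed substreams: a single master seed is split into named substreams so
# that adding a stage does not shift the draws of existing stages, and a
# stage rerun in isolation reproduces its in-pipeline draws.

#' Derive a deterministic substream seed from a master seed and a name
#'
#' @param seed integer master seed.
#' @param name character substream name.
#' @return an integer seed < 2^31.
#' @export
substreamSeed <- function(seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  ch <- utf8ToInt(name)
  h <- sum(ch * seq_along(ch)) %% 65521L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2011L + h)
}

# Run code under a named substream without disturbing the global RNG state.
withSubstream <- function(seed, name, code) {
  withr::with_seed(substreamSeed(seed, name), code)
}

#' Write a data.frame as a TSV file
#'
#' Plain tab-separated output with a header and no quoting or row names;
#' the format used for every tabular artifact of the package.
#' @param df data.frame to write.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read a TSV file written by \code{writeTsv}
#' @param path input file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

.logMsg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}
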