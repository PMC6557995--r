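# Shared internals: alphabets, condition classes, seed plumbing, TSV I/O.

#' @keywords internal
"_PACKAGE"

# PSI-BLAST column order for the 20 canonical amino acids.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

NONSILENT_CLASSES  <- c("missense", "frameshift", "stopgain", "splicing")
SILENT_CLASSES     <- c("synonymous", "intronic")
CONSEQUENCE_CLASSES <- c(NONSILENT_CLASSES, SILENT_CLASSES, "other")
# Classes counted toward the truncating (tumor-suppressor) fraction.
TRUNCATING_CLASSES <- c("frameshift", "stopgain", "splicing")

stop_config <- function(msg, field = NULL, call. = FALSE) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  stop(errorCondition(msg,
                      class = c("varcoseg_config_error", "varcoseg_error")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg,
                      class = c("varcoseg_data_error", "varcoseg_error")))
}

stop_parse <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s [line %d]", msg, line)
  stop(errorCondition(msg,
                      class = c("varcoseg_parse_error", "varcoseg_error")))
}

is_count <- function(x, min = 0) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

is_fraction <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

# Child streams are derived from one global seed by fixed offsets so that
# adding a generator never perturbs earlier streams.  Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 + 1000003 * offset) %% 2147483647)
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Tab-separated, header row, UTF-8, '.' for missing -- the one tabular dialect
# used for every file this package reads or writes.
read_tsv_ <- function(path, colClasses = NA) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = ".", comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses)
}

write_tsv_ <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (anyNA(out[[j]])) {
      col <- as.character(out[[j]])
      col[is.na(col)] <- "."
      out[[j]] <- col
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}
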