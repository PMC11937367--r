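# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted: symbol identity is deliberately literal so that set operations
#' stay deterministic and auditable.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop_input("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_input("`%s` must be a single value in [0, 1]", name)
  as.numeric(x)
}

# Single-seed-with-substreams policy: one master seed, deterministic
# per-module offsets, so modules can be rerun independently while still
# reproducing a joint run. Offsets keep derived seeds < 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(secretome = 11L, organoid = 23L, ihc = 37L, mask = 41L,
               bootstrap = 53L, report = 67L)
  if (!stream %in% names(offsets))
    stop_input("unknown random substream '%s'", stream)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stream]]
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop_input("file does not exist: %s", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
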