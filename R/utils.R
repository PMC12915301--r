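# Internal helpers. Label sets (families, EC numbers, substrates) travel as
# comma-joined, sorted, de-duplicated strings so every table round-trips
# through TSV unchanged.

split_set <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(strsplit(x, ",", fixed = TRUE)[[1L]]))
}

split_sets <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
  lapply(out, function(v) sort(unique(v[nzchar(v)])))
}

join_set <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  paste(sort(unique(x)), collapse = ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# sprintf-style stop with call suppressed; all user-facing errors go through
# here so messages stay consistent.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
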