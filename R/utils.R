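# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# deterministic 31-bit hash of an arbitrary R object (config stamping,
# per-stage seed derivation); not cryptographic
hash31 <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  v <- utf8ToInt(s)
  h <- 0
  for (b in v) h <- (h * 31 + b) %% 2147483647
  h
}

config_hash <- function(x) sprintf("%08x", hash31(x))

# derive a stage seed from a global seed; stays below 2^31
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + hash31(stage)) %% 2147483629L)
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) <= tol, na.rm = TRUE)
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop2(name, " must be a single probability in [0, 1]")
  invisible(x)
}

upper_tri_vec <- function(m) m[upper.tri(m)]

schema_comment <- function(what) sprintf("# schema: paircomm-%s/1", what)

# write a data.frame as TSV with a leading schema comment line
write_tsv_schema <- function(df, path, what, row_names = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(schema_comment(what), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

# read a TSV written by the package (skips leading "# " comment lines);
# also accepts files without the comment
read_tsv_schema <- function(path, ...) {
  head <- readLines(path, n = 10L)
  skip <- 0L
  while (skip < length(head) && startsWith(head[skip + 1L], "# ")) skip <- skip + 1L
  read.delim(path, skip = skip, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}
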