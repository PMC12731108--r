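# Internal helpers: seed streams, formatting, small assertions.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a deterministic 32-bit sub-seed from a master seed and a stream name.
# Polynomial rolling hash over the stream string, all arithmetic mod 2^31 - 1
# kept exact in doubles, so adding a stream never perturbs another stream's
# draws and per-gene streams are independent of processing order.
derive_seed <- function(master, stream) {
  m <- 2147483647
  h <- as.double(abs(as.integer(master))) %% m
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state on exit so library calls never disturb user-level streams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Canonical numeric formatting for TSV output; parse->format is idempotent so
# written tables round-trip byte-identically.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1)))
  out
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  for (j in which(!num)) out[[j]] <- ifelse(is.na(df[[j]]), "", as.character(df[[j]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop_fmt("schema error in %s: missing column(s) %s",
               path, paste(missing, collapse = ", "))
    }
  }
  df
}
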