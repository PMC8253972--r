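# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the ambient RNG stream" so that callers wrapping a
# whole analysis in one with_seed() get a single reproducible stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stopf("`seed` must be a single finite number")
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Comma-separated preview of a character vector for error messages.
id_preview <- function(x, max = 5L) {
  x <- as.character(x)
  if (length(x) > max)
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  else paste(x, collapse = ", ")
}
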