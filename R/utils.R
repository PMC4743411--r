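# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a reproducible child seed (kept below 2^31) from a parent seed and an
# integer tag, so independent stages never share an RNG stream.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(tag) * 7919) %% 2147483587L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Quiet down OpenBabel's stderr chatter (kekulization warnings and the like)
# without touching R-level conditions.
ob_quiet <- function(expr) {
  tmp <- tempfile()
  con <- file(tmp, open = "wt")
  sink(con, type = "message")
  on.exit({
    sink(type = "message")
    close(con)
    unlink(tmp)
  })
  expr
}
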