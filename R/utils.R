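#' @importFrom withr with_seed
NULL

# Deterministic per-unit seed stream: mixes a global seed with a string id so
# that per-gene fits are order- and parallelism-independent. Kept below 2^31.
deriveSeed <- function(seed, id, offset = 0L) {
  h <- sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + offset) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
  invisible(x)
}
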